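column,units,meaning
time_min,min,simulation time from protocol start
V_ic,L,intracellular water volume
V_is,L,interstitial water volume
V_pl,L,plasma water volume
Na_ec,mmol,extracellular exchangeable sodium pool
Prot_pl,g,plasma protein mass (constant)
Gut_w,L,unabsorbed gastrointestinal water
Gut_Na,mmol,unabsorbed gastrointestinal sodium
avp,pg/mL,plasma arginine vasopressin concentration
avp_store,pg,neurohypophyseal vasopressin store
anp,relative,plasma atrial natriuretic peptide (1 = baseline)
pra,relative,plasma renin activity (1 = baseline)
angii,relative,plasma angiotensin II (1 = baseline)
aldo,relative,plasma aldosterone (1 = baseline)
oro,dimensionless,oropharyngeal secretion-brake state (0 = off)
bladder_v,L,cumulative urine volume
urine_na_cum,mmol,cumulative urinary sodium excretion
cwi,L,cumulative oral water intake
insens,L,cumulative insensible water loss
ivi,L,cumulative intravenous water infused
iv_na,mmol,cumulative intravenous sodium infused
oral_na,mmol,cumulative oral sodium intake
serum_osm,mOsm/kg,serum osmolarity (2x[Na] + fixed non-sodium offset)
serum_na,mmol/L,serum sodium concentration
hct,fraction,hematocrit (red-cell fraction of blood volume)
prot_conc,g/dL,plasma protein concentration
blood_volume,L,plasma water + red-cell volume
icf_osm,mOsm/kg,intracellular osmolarity
map_mmHg,mmHg,mean arterial pressure
p_c,mmHg,capillary hydrostatic pressure
p_i,mmHg,interstitial hydrostatic pressure
p_ra,mmHg,right atrial pressure
gfr,mL/min,glomerular filtration rate (whole kidney)
urine_flow,mL/min,urine flow
urine_na,mmol/min,urinary sodium excretion rate
urine_osm,mOsm/kg,urine osmolarity
na_md,mmol/min,sodium delivery at the macula densa (whole kidney)
tgf_mult,dimensionless,tubuloglomerular feedback multiplier on afferent resistance
cd_perm,fraction,collecting-duct water permeability (AVP-controlled)
avp_secretion,pg/min,effective vasopressin secretion rate
thirst,dimensionless,thirst drive
drink_rate,mL/min,ad-libitum drinking rate
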