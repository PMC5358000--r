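#' Construct a protocol event
#'
#' @param kind One of `oral_load`, `iv_infusion`, `ad_lib_open`,
#'   `ad_lib_close`.
#' @param t_start Start time (min), non-negative.
#' @param volume_ml Total volume delivered (mL) for loads/infusions.
#' @param na_mmol_per_l Sodium concentration of the fluid (mmol/L).
#' @param duration Delivery duration (min); loads and infusions are given at
#'   constant rate `volume_ml / duration` over `[t_start, t_start + duration)`.
#' @return A one-row tibble.
#' @export
protocol_event <- function(kind, t_start, volume_ml = 0, na_mmol_per_l = 0,
                           duration = NA_real_) {
  kind <- match.arg(kind, c("oral_load", "iv_infusion", "ad_lib_open",
                            "ad_lib_close"))
  stopifnot(t_start >= 0, volume_ml >= 0, na_mmol_per_l >= 0)
  if (kind %in% c("oral_load", "iv_infusion") &&
      (is.na(duration) || duration <= 0)) {
    stop("loads and infusions need duration > 0")
  }
  tibble::tibble(kind = kind, t_start = t_start, volume_ml = volume_ml,
                 na_mmol_per_l = na_mmol_per_l, duration = duration)
}

new_protocol <- function(id, subject, events, t_end, sample_times,
                         controlled_intake, description) {
  events <- dplyr::arrange(events, .data$t_start)
  for (k in c("oral_load", "iv_infusion")) {
    e <- events[events$kind == k, ]
    if (nrow(e) > 1) {
      ends <- e$t_start + e$duration
      if (any(e$t_start[-1] < ends[-nrow(e)] - 1e-9)) {
        stop("schedule error: overlapping ", k, " events in protocol ", id)
      }
    }
  }
  opens <- events$t_start[events$kind == "ad_lib_open"]
  closes <- events$t_start[events$kind == "ad_lib_close"]
  if (length(opens) != length(closes) || any(closes <= opens)) {
    stop("schedule error: ad-lib windows must pair an open with a later close")
  }
  if (any(sample_times < 0 | sample_times > t_end)) {
    stop("sample_times must lie in [0, t_end]")
  }
  structure(
    list(id = id, subject = subject, events = events, t_end = t_end,
         sample_times = sort(unique(sample_times)),
         controlled_intake = controlled_intake, description = description),
    class = c("osmo_protocol", "list")
  )
}

#' Build one of the packaged dehydration/rehydration protocols
#'
#' Event schedules for the six classic human water-balance studies the model
#' is validated against, all on a 74 kg virtual subject by default:
#' \describe{
#'   \item{A}{20 mL/kg oral water over 20 min from the basal state; samples
#'     pre-load and one hour after the load.}
#'   \item{B}{36 h water deprivation, then 15 mL/kg oral water over 3.5 min;
#'     samples 5, 10, 15, 30, 60 min post-drink. `B1`: 1 mL/kg over 3 min.}
#'   \item{C}{24 h deprivation with a "pill" of 1 mL water + 80 mmol NaCl in
#'     the twelfth hour, then 10 mL/kg tap water over 2 min; same sample
#'     grid.}
#'   \item{D}{as C but the drink is 10 mL/kg of 180 mmol/L saline.}
#'   \item{E}{10 h fast, 120 min infusion of 5\% NaCl (855 mmol/L) at
#'     0.06 mL/kg/min, 15 min equilibration, then a 30 min ad-libitum
#'     drinking window; samples every 30 min from infusion start.}
#'   \item{F}{as E with no drinking window.}
#' }
#' Protocol A keeps the basal maintenance intake running (a water load from
#' the basal state); the controlled-intake studies (B-F) suspend it for the
#' whole run, so deprivation is simply the absence of intake.
#'
#' @param id Protocol id, one of `"A"`, `"B"`, `"B1"`, `"C"`, `"D"`, `"E"`,
#'   `"F"`.
#' @param subject The virtual subject; doses scale with `body_mass`.
#' @return An `osmo_protocol` object.
#' @examples
#' build_protocol("A")$events
#' @export
build_protocol <- function(id, subject = default_subject()) {
  valid <- c("A", "B", "B1", "C", "D", "E", "F")
  if (!id %in% valid) {
    stop("unknown protocol id '", id, "'; valid ids: ",
         paste(valid, collapse = ", "))
  }
  m <- subject$body_mass
  ev <- switch(
    id,
    A = protocol_event("oral_load", 0, 20 * m, 0, 20),
    B = protocol_event("oral_load", 2160, 15 * m, 0, 3.5),
    B1 = protocol_event("oral_load", 2160, 1 * m, 0, 3),
    C = dplyr::bind_rows(
      protocol_event("oral_load", 720, 1, 80 * 1000, 1),  # 1 mL, 80 mmol NaCl
      protocol_event("oral_load", 1440, 10 * m, 0, 2)
    ),
    D = dplyr::bind_rows(
      protocol_event("oral_load", 720, 1, 80 * 1000, 1),
      protocol_event("oral_load", 1440, 10 * m, 180, 2)
    ),
    E = dplyr::bind_rows(
      protocol_event("iv_infusion", 600, 0.06 * m * 120, 855, 120),
      protocol_event("ad_lib_open", 735),
      protocol_event("ad_lib_close", 765)
    ),
    F = protocol_event("iv_infusion", 600, 0.06 * m * 120, 855, 120)
  )
  spec <- switch(
    id,
    A = list(t_end = 180, samples = c(0, 80),
             desc = "acute 20 mL/kg oral water load from the basal state",
             controlled = FALSE),
    B = list(t_end = 2220, samples = c(0, 2160, 2160 + c(5, 10, 15, 30, 60)),
             desc = "36 h water deprivation + 15 mL/kg oral water",
             controlled = TRUE),
    B1 = list(t_end = 2220, samples = c(0, 2160, 2160 + c(5, 10, 15, 30, 60)),
              desc = "36 h water deprivation + 1 mL/kg oral water (sham drink)",
              controlled = TRUE),
    C = list(t_end = 1500, samples = c(0, 1440, 1440 + c(5, 10, 15, 30, 60)),
             desc = "24 h deprivation + 80 mmol NaCl pill + 10 mL/kg water",
             controlled = TRUE),
    D = list(t_end = 1500, samples = c(0, 1440, 1440 + c(5, 10, 15, 30, 60)),
             desc = "24 h deprivation + 80 mmol NaCl pill + 10 mL/kg 180 mmol/L saline",
             controlled = TRUE),
    E = list(t_end = 780, samples = seq(600, 780, by = 30),
             desc = "10 h fast + 2 h 5% NaCl at 0.06 mL/kg/min + 30 min ad-lib water",
             controlled = TRUE),
    F = list(t_end = 780, samples = seq(600, 780, by = 30),
             desc = "10 h fast + 2 h 5% NaCl at 0.06 mL/kg/min, no water",
             controlled = TRUE)
  )
  new_protocol(id, subject, ev, spec$t_end, spec$samples, spec$controlled,
               spec$desc)
}

#' @export
print.osmo_protocol <- function(x, ...) {
  cat(sprintf("<osmo_protocol %s> %s\n  subject %.0f kg, t_end %g min, %d event(s), %d sample time(s)\n",
              x$id, x$description, x$subject$body_mass, x$t_end,
              nrow(x$events), length(x$sample_times)))
  invisible(x)
}

#' Serialize a protocol to YAML / read it back
#'
#' @param protocol An `osmo_protocol`.
#' @param path File path.
#' @return `write_protocol_yaml` returns `path` invisibly;
#'   `read_protocol_yaml` returns the `osmo_protocol`.
#' @export
write_protocol_yaml <- function(protocol, path) {
  obj <- list(
    id = protocol$id,
    description = protocol$description,
    subject = protocol$subject[c("body_mass", "tbw_fraction", "icf_fraction",
                                 "nephron_multiplier")],
    t_end = protocol$t_end,
    sample_times = protocol$sample_times,
    controlled_intake = protocol$controlled_intake,
    events = purrr::transpose(as.list(protocol$events))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  subj <- do.call(default_subject, obj$subject)
  events <- dplyr::bind_rows(lapply(obj$events, function(e) {
    e$duration <- if (is.null(e$duration) || is.na(e$duration)) NA_real_ else
      as.numeric(e$duration)
    tibble::as_tibble(e)
  }))
  new_protocol(obj$id, subj, events, obj$t_end,
               as.numeric(obj$sample_times), obj$controlled_intake,
               obj$description)
}
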