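test_that("SEM-to-SD conversion and z-scores match hand arithmetic", {
  expect_equal(sem_to_sd(2, 9), 6)
  expect_equal(sem_to_sd(0.5, 16), 2)
  expect_equal(sem_to_sd(3, 1), 3)
  expect_error(sem_to_sd(2, 0), "integer")
  expect_error(sem_to_sd(2, 2.5), "integer")

  expect_equal(z_score(285, 285, 5), 0)
  expect_equal(z_score(290, 285, 5), 1)
  expect_equal(z_score(280, 285, 5), z_score(290, 285, 5))  # symmetric
  expect_error(z_score(290, 285, 0), "positive")
})

test_that("RMSE matches closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(rmse(c(11, 12, 13), c(10, 11, 12)), 1)  # constant offset
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("reference CSVs round-trip losslessly and are validated", {
  refs <- tibble::tibble(
    protocol = c("A", "A", "B"), variable = c("serum_osm", "avp", "avp"),
    units = c("mOsm/kg", "pg/mL", "pg/mL"), time_min = c(0, 80, 2165),
    mean = c(288.31, 1.257, 4.9), sd = c(4.2, NA, 1.1),
    sem = c(NA, 0.3, NA), n = c(NA, 9, NA)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(refs, path)
  back <- read_reference_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(refs))

  bad <- refs
  bad$sd[1] <- NA
  expect_error(write_reference_csv(bad, path), "without sd")
  expect_error(validate_refs(refs[, -4]), "lacks column")
})

test_that("a fixture displaced by 1.5 SD lands entirely in the middle bin", {
  sim <- protocol_run("A", dt = 0.05)
  refs <- make_reference_fixture(list(A = sim),
                                 variables = c("serum_osm", "avp", "hct"),
                                 times = c(0, 20, 40, 60, 80),
                                 offset_sd = 1.5)
  rep <- build_report(list(A = sim), refs)
  expect_equal(rep$n_comparisons, 15)
  expect_equal(rep$tallies$count[rep$tallies$bin == "1<=Z<=2"], 15L)
  expect_true(all(abs(rep$points$z - 1.5) < 1e-9))
  expect_equal(sum(rep$tallies$count), rep$n_comparisons)
})

test_that("bins follow the documented convention, boundaries in the middle", {
  sim <- protocol_run("A", dt = 0.05)
  cases <- list(c(0.99, "Z<1"), c(1, "1<=Z<=2"), c(2, "1<=Z<=2"),
                c(2.01, "Z>2"), c(0, "Z<1"))
  for (cs in cases) {
    refs <- make_reference_fixture(list(A = sim), variables = "serum_osm",
                                   times = 0, offset_sd = as.numeric(cs[1]))
    rep <- build_report(list(A = sim), refs)
    expect_equal(rep$points$bin, cs[2])
  }
})

test_that("SEM-style fixtures validate identically after conversion", {
  sim <- protocol_run("A", dt = 0.05)
  refs_sd <- make_reference_fixture(list(A = sim), variables = "avp",
                                    times = c(0, 40, 80), offset_sd = 0.7)
  refs_sem <- make_reference_fixture(list(A = sim), variables = "avp",
                                     times = c(0, 40, 80), offset_sd = 0.7,
                                     as_sem = TRUE, n = 9)
  z_sd <- build_report(list(A = sim), refs_sd)$points$z
  z_sem <- build_report(list(A = sim), refs_sem)$points$z
  expect_equal(z_sd, z_sem, tolerance = 1e-9)
})

test_that("tallies are invariant under monotone relabeling of time", {
  sim <- protocol_run("A", dt = 0.05)
  refs <- make_reference_fixture(list(A = sim),
                                 variables = c("serum_osm", "avp"),
                                 times = c(0, 30, 60), offset_sd = 1.2)
  base_tallies <- build_report(list(A = sim), refs)$tallies
  # relabel: shift all times by a constant inside the run and move the model
  # with them (same model values at the relabeled times)
  shifted <- refs
  shifted$time_min <- refs$time_min + 1e-9  # infinitesimal monotone map
  expect_equal(build_report(list(A = sim), shifted)$tallies$count,
               base_tallies$count, tolerance = 0)
})

test_that("unmatched reference points fail loudly", {
  sim <- protocol_run("A", dt = 0.05)
  refs <- make_reference_fixture(list(A = sim), variables = "serum_osm",
                                 times = 0)
  refs$protocol <- "Q"
  expect_error(build_report(list(A = sim), refs), "protocol Q")
  refs2 <- make_reference_fixture(list(A = sim), variables = "serum_osm",
                                  times = 0)
  refs2$time_min <- 9999
  expect_error(build_report(list(A = sim), refs2), "outside")
  refs3 <- make_reference_fixture(list(A = sim), variables = "serum_osm",
                                  times = 0)
  refs3$variable <- "no_such_column"
  expect_error(build_report(list(A = sim), refs3), "no_such_column")
})

test_that("an empty reference set yields an empty report with zero tallies", {
  sim <- protocol_run("A", dt = 0.05)
  refs <- make_reference_fixture(list(A = sim), variables = "avp", times = 0)
  rep <- build_report(list(A = sim), refs[0, ])
  expect_equal(rep$n_comparisons, 0)
  expect_equal(sum(rep$tallies$count), 0)
})

test_that("report accessors, score matrix, JSON and plot work", {
  sim <- protocol_run("A", dt = 0.05)
  refs <- make_reference_fixture(list(A = sim),
                                 variables = c("serum_osm", "avp"),
                                 times = c(0, 40, 80), offset_sd = 1.5)
  rep <- build_report(list(A = sim), refs)
  expect_equal(nrow(tidy(rep)), 6)
  expect_equal(glance(rep)$n_1to2, 6L)
  lines <- score_matrix(rep)
  expect_true(any(grepl("oooo?", lines)))
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_comparisons, 6L)
})
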