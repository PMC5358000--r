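#' Convert a standard error of the mean to a standard deviation
#'
#' Experimental tables often report mean +/- SEM; z-scores are computed
#' against the standard deviation, `sd = sem * sqrt(n)`.
#'
#' @param sem Standard error(s) of the mean, positive.
#' @param n Number(s) of subjects, integer >= 1.
#' @return Standard deviation(s).
#' @examples
#' sem_to_sd(2, 9)  # 6
#' @export
sem_to_sd <- function(sem, n) {
  if (any(n < 1) || any(n != round(n))) stop("n must be an integer >= 1")
  stopifnot(all(sem > 0))
  sem * sqrt(n)
}

#' Z-score of a model value against an experimental point
#'
#' The magnitude of the model-experiment difference in units of the
#' experimental standard deviation: `|model - mean| / sd`.
#'
#' @param model_value Simulated value(s).
#' @param exp_mean Experimental mean(s).
#' @param exp_sd Experimental standard deviation(s), positive.
#' @return Non-negative z value(s).
#' @examples
#' z_score(290, 285, 5)  # 1
#' @export
z_score <- function(model_value, exp_mean, exp_sd) {
  if (any(exp_sd <= 0)) stop("exp_sd must be positive")
  abs(model_value - exp_mean) / exp_sd
}

#' Root-mean-square error between matched series
#'
#' @param model_series,exp_means Equal-length numeric vectors at matched
#'   sample times.
#' @return RMSE in the variable's units.
#' @examples
#' rmse(c(3, 4), c(0, 0))  # sqrt(25/2)
#' @export
rmse <- function(model_series, exp_means) {
  if (length(model_series) != length(exp_means) || !length(model_series)) {
    stop("series must have equal length >= 1")
  }
  sqrt(mean((model_series - exp_means)^2))
}

ref_cols <- c("protocol", "variable", "units", "time_min", "mean",
              "sd", "sem", "n")

#' Read / write a reference-series CSV
#'
#' The reference table schema is one row per experimental point:
#' `protocol, variable, units, time_min, mean, sd, sem, n`, with either `sd`
#' or both `sem` and `n` present per row.
#'
#' @param path CSV file path.
#' @param refs Reference tibble.
#' @return `read_reference_csv` returns the validated tibble;
#'   `write_reference_csv` returns `path` invisibly.
#' @export
read_reference_csv <- function(path) {
  refs <- readr::read_csv(path, col_types = readr::cols(
    protocol = "c", variable = "c", units = "c", time_min = "d",
    mean = "d", sd = "d", sem = "d", n = "d"
  ))
  validate_refs(refs)
}

#' @rdname read_reference_csv
#' @export
write_reference_csv <- function(refs, path) {
  readr::write_csv(validate_refs(refs), path)
  invisible(path)
}

validate_refs <- function(refs) {
  missing <- setdiff(ref_cols, names(refs))
  if (length(missing)) {
    stop("reference table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- is.na(refs$sd) & (is.na(refs$sem) | is.na(refs$n))
  if (any(bad)) {
    stop("reference rows without sd or (sem, n): rows ",
         paste(which(bad), collapse = ", "))
  }
  if (any(!is.na(refs$sd) & refs$sd <= 0) ||
      any(!is.na(refs$sem) & refs$sem <= 0)) {
    stop("dispersion must be positive")
  }
  tibble::as_tibble(refs[ref_cols])
}

# model value at a reference time, linear interpolation on the recorded grid
interp_model <- function(sim, variable, time_min) {
  d <- sim$data
  if (!variable %in% names(d)) {
    stop("variable '", variable, "' is not a simulated output column")
  }
  rng <- range(d$time_min)
  if (time_min < rng[1] || time_min > rng[2]) {
    stop(sprintf("reference time %g outside the simulated range [%g, %g]",
                 time_min, rng[1], rng[2]))
  }
  stats::approx(d$time_min, d[[variable]], xout = time_min)$y
}

#' Compare simulations with experimental reference tables
#'
#' For every reference point, interpolates the matching protocol's simulated
#' variable at the reference time, converts SEM to SD where needed, computes
#' the z-score and assigns it to one of the three bins used in the validation
#' heat map (`Z<1`, `1<=Z<=2`, `Z>2`; boundary values fall in the middle bin
#' by convention). RMSE is computed per protocol/variable across matched
#' times.
#'
#' @param runs A named list of `osmo_sim` objects (names = protocol ids), or
#'   a single `osmo_sim`.
#' @param refs A reference tibble ([read_reference_csv()] schema).
#' @return An object of class `osmo_validation` with tibbles `points`
#'   (per-point z and bin), `rmse` (per protocol/variable) and `tallies`
#'   (counts per bin; sums to the number of comparisons).
#' @examples
#' \donttest{
#' sim <- simulate_protocol(build_protocol("A"), dt = 0.25)
#' refs <- make_reference_fixture(list(A = sim), offset_sd = 1.5)
#' build_report(list(A = sim), refs)$tallies
#' }
#' @export
build_report <- function(runs, refs) {
  if (inherits(runs, "osmo_sim")) {
    runs <- stats::setNames(list(runs), runs$protocol$id)
  }
  refs <- validate_refs(refs)
  points <- purrr::pmap_dfr(refs, function(protocol, variable, units,
                                           time_min, mean, sd, sem, n) {
    sim <- runs[[protocol]]
    if (is.null(sim)) {
      stop("no simulation supplied for reference point: protocol ", protocol,
           ", variable ", variable, ", t = ", time_min)
    }
    sd_eff <- if (!is.na(sd)) sd else sem_to_sd(sem, n)
    model <- interp_model(sim, variable, time_min)
    z <- z_score(model, mean, sd_eff)
    # boundary values belong to the middle bin; comparisons carry a relative
    # guard so a z constructed to sit exactly on a boundary is not knocked
    # into the wrong bin by floating-point rounding
    eps <- 1e-9
    tibble::tibble(protocol = protocol, variable = variable, units = units,
                   time_min = time_min, exp_mean = mean, exp_sd = sd_eff,
                   model = model, z = z,
                   bin = if (z < 1 - eps) "Z<1"
                         else if (z <= 2 + eps) "1<=Z<=2" else "Z>2")
  })
  bins <- c("Z<1", "1<=Z<=2", "Z>2")
  if (nrow(points)) {
    rmse_tbl <- points |>
      dplyr::group_by(.data$protocol, .data$variable, .data$units) |>
      dplyr::summarise(
        n_points = dplyr::n(),
        rmse = rmse(.data$model, .data$exp_mean),
        .groups = "drop"
      )
    tallies <- tibble::tibble(
      bin = bins,
      count = vapply(bins, function(b) sum(points$bin == b), integer(1),
                     USE.NAMES = FALSE)
    )
  } else {
    rmse_tbl <- tibble::tibble(protocol = character(), variable = character(),
                               units = character(), n_points = integer(),
                               rmse = double())
    tallies <- tibble::tibble(bin = bins, count = c(0L, 0L, 0L))
  }
  structure(
    list(points = points, rmse = rmse_tbl, tallies = tallies,
         n_comparisons = nrow(points)),
    class = c("osmo_validation", "list")
  )
}

#' @export
print.osmo_validation <- function(x, ...) {
  cat(sprintf("<osmo_validation> %d comparison(s)\n", x$n_comparisons))
  cat("  tallies:", paste(sprintf("%s: %d", x$tallies$bin, x$tallies$count),
                          collapse = ", "), "\n")
  if (nrow(x$rmse)) {
    cat("  RMSE per protocol/variable:\n")
    print(x$rmse, n = 20)
  }
  invisible(x)
}

#' Plain-text score matrix of a validation report
#'
#' Protocol-by-variable matrix of binned z-scores, one cell per comparison
#' point (time-ordered symbols: `.` for Z<1, `o` for 1<=Z<=2, `X` for Z>2).
#'
#' @param report An `osmo_validation`.
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
score_matrix <- function(report) {
  pts <- report$points
  if (!nrow(pts)) {
    lines <- "(no comparisons)"
  } else {
    sym <- c("Z<1" = ".", "1<=Z<=2" = "o", "Z>2" = "X")
    lines <- pts |>
      dplyr::arrange(.data$protocol, .data$variable, .data$time_min) |>
      dplyr::group_by(.data$protocol, .data$variable) |>
      dplyr::summarise(cells = paste(sym[.data$bin], collapse = ""),
                       .groups = "drop") |>
      (\(d) sprintf("%-9s %-14s %s", d$protocol, d$variable, d$cells))()
    lines <- c(sprintf("%-9s %-14s %s", "protocol", "variable",
                       "z bins (.<1 o:1-2 X>2)"), lines)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
tidy.osmo_validation <- function(x, ...) x$points

#' @export
glance.osmo_validation <- function(x, ...) {
  tibble::tibble(
    n_comparisons = x$n_comparisons,
    n_lt1 = x$tallies$count[x$tallies$bin == "Z<1"],
    n_1to2 = x$tallies$count[x$tallies$bin == "1<=Z<=2"],
    n_gt2 = x$tallies$count[x$tallies$bin == "Z>2"]
  )
}

#' Heat-map plot of a validation report
#'
#' @param object An `osmo_validation`.
#' @param ... Unused.
#' @return A ggplot tile map of z bins over protocol/variable/time.
#' @export
autoplot.osmo_validation <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = factor(.data$time_min),
                                    y = .data$variable,
                                    fill = .data$bin)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(~protocol, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c("Z<1" = "grey90",
                                          "1<=Z<=2" = "grey60",
                                          "Z>2" = "grey20")) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = "z bin") +
    ggplot2::theme_minimal()
}

#' Write a validation report to JSON
#'
#' @param report An `osmo_validation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(points = report$points, rmse = report$rmse,
         tallies = report$tallies, n_comparisons = report$n_comparisons),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Generate a synthetic reference fixture
#'
#' Builds a reference table from simulated runs with a chosen mean/SD
#' structure: the experimental "mean" is the model value displaced by
#' `offset_sd` standard deviations, so the z-score of every point against
#' the generating run is exactly `|offset_sd|` and the binned tallies are
#' known analytically. No experimental figure values are packaged; this
#' fixture generator exists so the validation harness can be exercised
#' end-to-end against ground truth constructed from the model itself.
#'
#' @param runs Named list of `osmo_sim` objects.
#' @param variables Simulated columns to reference.
#' @param times Reference times per run (default: the protocol sample
#'   times).
#' @param sd_frac Dispersion as a fraction of |mean| (floored at `sd_min`).
#' @param sd_min Dispersion floor.
#' @param offset_sd Displacement of the reference mean in SD units.
#' @param as_sem Report dispersion as SEM with `n` subjects instead of SD.
#' @param n Subject count used when `as_sem = TRUE`.
#' @return A reference tibble in the [read_reference_csv()] schema.
#' @export
make_reference_fixture <- function(runs,
                                   variables = c("serum_osm", "serum_na",
                                                 "avp", "hct"),
                                   times = NULL, sd_frac = 0.05,
                                   sd_min = 0.5, offset_sd = 0,
                                   as_sem = FALSE, n = 9) {
  purrr::imap_dfr(runs, function(sim, id) {
    tt <- if (is.null(times)) sim$protocol$sample_times else times
    purrr::map_dfr(variables, function(v) {
      model <- vapply(tt, function(x) interp_model(sim, v, x), double(1))
      disp <- pmax(sd_min, sd_frac * abs(model))
      tibble::tibble(
        protocol = id, variable = v, units = sim_units(v), time_min = tt,
        mean = model + offset_sd * disp,
        sd = if (as_sem) NA_real_ else disp,
        sem = if (as_sem) disp / sqrt(n) else NA_real_,
        n = if (as_sem) n else NA_real_
      )
    })
  })
}

sim_units <- function(v) {
  u <- c(serum_osm = "mOsm/kg", serum_na = "mmol/L", avp = "pg/mL",
         hct = "fraction", urine_flow = "mL/min", urine_osm = "mOsm/kg",
         prot_conc = "g/dL", cwi = "L", anp = "relative")
  if (v %in% names(u)) unname(u[v]) else "unknown"
}
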