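#' @export
print.osmo_sim <- function(x, ...) {
  cat(sprintf(
    "<osmo_sim> protocol %s (%s)\n  dt %g min, %d recorded rows over %g min\n",
    x$protocol$id, x$protocol$description, x$dt, nrow(x$data),
    x$protocol$t_end
  ))
  print(utils::head(dplyr::select(
    x$data, "time_min", "serum_osm", "serum_na", "avp", "urine_flow",
    "urine_osm", "cwi"
  ), 5))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.osmo_sim <- function(x, ...) x$data

#' Rows of a simulation at the protocol sample times
#'
#' @param sim An `osmo_sim`.
#' @param times Sample times (min); defaults to the protocol's.
#' @return Tibble with one row per sample time (linear interpolation is not
#'   needed: sample times are on the recording grid).
#' @export
sample_rows <- function(sim, times = sim$protocol$sample_times) {
  i <- match(times, sim$data$time_min)
  if (anyNA(i)) stop("sample time(s) not on the recording grid: ",
                     paste(times[is.na(i)], collapse = ", "))
  sim$data[i, ]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into long form
#'
#' @param x An `osmo_sim`.
#' @param variables Optional character vector of columns to keep.
#' @param ... Unused.
#' @return A long tibble with `protocol`, `time_min`, `variable`, `value`.
#' @export
tidy.osmo_sim <- function(x, variables = NULL, ...) {
  d <- x$data
  if (!is.null(variables)) {
    d <- dplyr::select(d, "time_min", dplyr::all_of(variables))
  }
  out <- tidyr::pivot_longer(d, -"time_min", names_to = "variable",
                             values_to = "value")
  dplyr::mutate(out, protocol = x$protocol$id, .before = 1)
}

#' One-row summary of a simulation
#'
#' @param x An `osmo_sim`.
#' @param ... Unused.
#' @return Tibble with the protocol id, run length, peak urine flow, serum
#'   osmolarity range, peak AVP and total water intake.
#' @export
glance.osmo_sim <- function(x, ...) {
  d <- x$data
  tibble::tibble(
    protocol = x$protocol$id,
    t_end = x$protocol$t_end,
    dt = x$dt,
    urine_flow_peak = max(d$urine_flow),
    serum_osm_min = min(d$serum_osm),
    serum_osm_max = max(d$serum_osm),
    avp_peak = max(d$avp),
    cwi_total = d$cwi[nrow(d)] - d$cwi[1],
    urine_total = d$bladder_v[nrow(d)] - d$bladder_v[1]
  )
}

#' Plot simulated trajectories
#'
#' @param object An `osmo_sim`.
#' @param variables Columns to plot (default: the classic endpoints).
#' @param ... Unused.
#' @return A ggplot with one facet per variable; protocol sample times are
#'   marked with points.
#' @export
autoplot.osmo_sim <- function(object,
                              variables = c("serum_osm", "serum_na", "avp",
                                            "urine_flow", "urine_osm", "hct"),
                              ...) {
  long <- tidy(object, variables = variables)
  samp <- dplyr::filter(long,
                        .data$time_min %in% object$protocol$sample_times)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_point(data = samp, size = 1.2, colour = "firebrick") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(
      x = "time (min)", y = NULL,
      title = sprintf("Protocol %s", object$protocol$id),
      subtitle = object$protocol$description
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.osmo_sim <- function(x, ...) print(autoplot(x, ...))

#' Write a simulated time series to CSV
#'
#' One row per recorded time, all state, observable and ledger columns; see
#' [data_dictionary()] for units.
#'
#' @param sim An `osmo_sim`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  readr::write_csv(sim$data, path)
  invisible(path)
}
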