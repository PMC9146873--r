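#' Tidy a frequency sweep
#'
#' @param x A `cpg_sweep` from [alpha_sweep()].
#' @param ... Ignored.
#' @return A plain tibble of per-run results.
#' @exportS3Method generics::tidy
tidy.cpg_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a frequency sweep
#'
#' Per-topology least-squares slope of mean frequency against the
#' excitation parameter over oscillatory grid points, plus the
#' monotonicity flag and (when both topologies are present) the fraction of
#' shared oscillatory grid points where the intact frequency exceeds the
#' hemicord frequency.
#'
#' @param x A `cpg_sweep`.
#' @param ... Ignored.
#' @return A one-row tibble: `slope_intact`, `slope_hemicord`,
#'   `monotone_intact`, `monotone_hemicord`, `frac_intact_faster`,
#'   `n_shared_alpha`.
#' @exportS3Method generics::glance
glance.cpg_sweep <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  means <- dplyr::summarise(
    dplyr::group_by(tb, .data$alpha, .data$topology),
    frequency_hz = mean(.data$frequency_hz),
    oscillatory = all(.data$oscillatory), .groups = "drop")
  stats_for <- function(topo) {
    m <- means[means$topology == topo & means$oscillatory, ]
    if (nrow(m) < 2) return(list(slope = NA_real_, mono = NA))
    list(slope = unname(stats::coef(stats::lm(frequency_hz ~ alpha, m))[2]),
         mono = all(diff(m$frequency_hz) >= -1e-9))
  }
  si <- stats_for("intact"); sh <- stats_for("hemicord")
  shared <- tidyr::pivot_wider(means[means$oscillatory, ],
                               names_from = "topology",
                               values_from = "frequency_hz",
                               id_cols = "alpha")
  frac <- NA_real_; nshared <- 0L
  if (all(c("intact", "hemicord") %in% names(shared))) {
    ok <- stats::complete.cases(shared[, c("intact", "hemicord")])
    nshared <- sum(ok)
    if (nshared > 0)
      frac <- mean(shared$intact[ok] > shared$hemicord[ok])
  }
  tibble::tibble(slope_intact = si$slope, slope_hemicord = sh$slope,
                 monotone_intact = si$mono, monotone_hemicord = sh$mono,
                 frac_intact_faster = frac, n_shared_alpha = nshared)
}

#' Tidy spike recordings
#'
#' @param x A `cpg_recordings`.
#' @param ... Ignored.
#' @return The spike tibble.
#' @exportS3Method generics::tidy
tidy.cpg_recordings <- function(x, ...) x$spikes

#' One-row summary of spike recordings
#'
#' @param x A `cpg_recordings`.
#' @param ... Ignored.
#' @return A one-row tibble: totals, duration and model flags.
#' @exportS3Method generics::glance
glance.cpg_recordings <- function(x, ...) {
  tibble::tibble(n_spikes = nrow(x$spikes),
                 n_neurons = sum(x$pop_sizes$N),
                 n_populations = nrow(x$pop_sizes),
                 duration_s = max(x$epochs$end_ms) / 1000,
                 variant = x$meta$variant, topology = x$meta$topology,
                 alpha = x$meta$alpha, d = x$meta$d)
}
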