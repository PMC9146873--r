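#' Population activity histogram
#'
#' Average population firing-rate histogram in spikes/(N x s): per time bin,
#' spike count divided by population size and bin width in seconds. Total
#' spikes are conserved: `sum(rate * N * bin_s)` equals the raw spike count.
#'
#' @param recordings A `cpg_recordings` object.
#' @param population Population name.
#' @param side `"left"` or `"right"`.
#' @param bin_ms Bin width, ms (default 100).
#' @param window Optional `c(start_ms, end_ms)` restriction (defaults to the
#'   whole recording); an epoch label is also accepted.
#' @return A `cpg_histogram` tibble: `population`, `side`, `bin_start`,
#'   `bin_mid` (ms), `rate` (spikes/(N x s)), with attributes `N`, `bin_ms`.
#' @export
population_histogram <- function(recordings, population, side = "left",
                                 bin_ms = 100, window = NULL) {
  stopifnot(inherits(recordings, "cpg_recordings"))
  win <- resolve_window(recordings, window)
  if (diff(win) <= 0)
    rlang::abort("empty recording window", class = "spinalcpg_config_error")
  ps <- recordings$pop_sizes
  N <- ps$N[ps$population == population & ps$side == side]
  if (length(N) != 1)
    rlang::abort(paste0("population not present in raster: ", population,
                        " (", side, ")"), class = "spinalcpg_config_error")
  sp <- recordings$spikes
  t <- sp$time_ms[sp$population == population & sp$side == side &
                    sp$time_ms > win[1] & sp$time_ms <= win[2]]
  breaks <- seq(win[1], win[2], by = bin_ms)
  if (breaks[length(breaks)] < win[2]) breaks <- c(breaks, win[2])
  counts <- graphics::hist(t, breaks = breaks, plot = FALSE)$counts
  widths <- diff(breaks)
  out <- tibble::tibble(
    population = population, side = side,
    bin_start = breaks[-length(breaks)],
    bin_mid = breaks[-length(breaks)] + widths / 2,
    rate = counts / (N * widths / 1000))
  structure(out, N = N, bin_ms = bin_ms, window = win,
            class = c("cpg_histogram", class(out)))
}

resolve_window <- function(recordings, window) {
  if (is.null(window))
    return(c(min(recordings$epochs$start_ms), max(recordings$epochs$end_ms)))
  if (is.character(window)) {
    ep <- recordings$epochs[recordings$epochs$epoch == window, ]
    if (nrow(ep) != 1)
      rlang::abort(paste0("unknown epoch: ", window),
                   class = "spinalcpg_config_error")
    return(c(ep$start_ms, ep$end_ms))
  }
  stopifnot(is.numeric(window), length(window) == 2)
  window
}

#' Segment a rate histogram into bursts
#'
#' Maximal runs of bins whose rate exceeds `threshold_frac` times a robust
#' maximum (the 95th percentile of the rate series). Runs separated by gaps
#' shorter than `min_gap_ms` are merged; runs shorter than `min_burst_ms`
#' are dropped. The relative threshold makes segmentation invariant to
#' rescaling of the rate.
#'
#' @param hist A `cpg_histogram` (or tibble with `bin_start`, `rate`).
#' @param threshold_frac Fraction of the robust maximum (default 0.3).
#' @param min_burst_ms Minimal burst duration, ms.
#' @param min_gap_ms Minimal gap between bursts, ms.
#' @return A burst-train tibble: `onset`, `offset` (ms), `peak_rate`. Empty
#'   (zero rows) when nothing crosses threshold.
#' @export
detect_bursts <- function(hist, threshold_frac = 0.3,
                          min_burst_ms = 300, min_gap_ms = 200) {
  if (nrow(hist) == 0)
    rlang::abort("empty histogram", class = "spinalcpg_config_error")
  bin_ms <- attr(hist, "bin_ms") %||% diff(hist$bin_start[1:2])
  robust_max <- stats::quantile(hist$rate, 0.95, names = FALSE)
  if (robust_max <= 0)
    return(tibble::tibble(onset = numeric(), offset = numeric(),
                          peak_rate = numeric()))
  thr <- threshold_frac * robust_max
  above <- hist$rate >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0)
    return(tibble::tibble(onset = numeric(), offset = numeric(),
                          peak_rate = numeric()))
  # merge runs separated by short gaps
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      gap_ms <- (runs$start[i] - last$end - 1) * bin_ms
      if (gap_ms < min_gap_ms) {
        merged[[length(merged)]]$end <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
  }
  runs <- dplyr::bind_rows(merged)
  onset <- hist$bin_start[runs$start]
  offset <- hist$bin_start[runs$end] + bin_ms
  keep <- (offset - onset) >= min_burst_ms
  runs <- runs[keep, , drop = FALSE]
  tibble::tibble(
    onset = onset[keep], offset = offset[keep],
    peak_rate = purrr::map2_dbl(runs$start, runs$end,
                                ~max(hist$rate[.x:.y])))
}

#' Oscillation frequency from a burst train
#'
#' Burst count divided by the window length; a window holding fewer than 3
#' bursts is flagged non-oscillatory.
#'
#' @param bursts Burst-train tibble from [detect_bursts()].
#' @param window_s Window length, s.
#' @return List: `frequency_hz`, `n_bursts`, `oscillatory`.
#' @export
oscillation_frequency <- function(bursts, window_s) {
  stopifnot(window_s > 0)
  n <- nrow(bursts)
  list(frequency_hz = n / window_s, n_bursts = n, oscillatory = n >= 3)
}

#' Phase difference between two burst trains
#'
#' Circular mean of train `b`'s burst-onset latencies within the cycles of
#' train `a` (cycle = interval between consecutive `a` onsets). A phase near
#' 0.5 is alternation; a phase near 0 (or 1) is synchrony; a low mean
#' resultant length marks irregular coupling.
#'
#' @param a,b Burst-train tibbles (reference train `a` defines the cycle).
#' @param resultant_min Minimal mean resultant length for a coordination
#'   label other than `"irregular"`.
#' @return List: `phase` in `[0, 1)` (NA when undefined), `resultant`
#'   (circular concentration in `[0, 1]`), `n` cycles used, `label`
#'   (`"alternating"`, `"synchronous"`, `"irregular"`, or `"undefined"`).
#' @export
phase_difference <- function(a, b, resultant_min = 0.6) {
  if (nrow(a) < 3 || nrow(b) < 3)
    return(list(phase = NA_real_, resultant = NA_real_, n = 0L,
                label = "undefined"))
  on_a <- sort(a$onset)
  on_b <- sort(b$onset)
  idx <- findInterval(on_b, on_a)
  keep <- idx >= 1 & idx < length(on_a)
  if (!any(keep))
    return(list(phase = NA_real_, resultant = NA_real_, n = 0L,
                label = "undefined"))
  i <- idx[keep]
  ph <- (on_b[keep] - on_a[i]) / (on_a[i + 1] - on_a[i])
  z <- exp(2i * pi * ph)
  mz <- mean(z)
  phase <- (Arg(mz) / (2 * pi)) %% 1
  resultant <- Mod(mz)
  label <- if (resultant < resultant_min) "irregular"
  else if (phase >= 0.4 && phase <= 0.6) "alternating"
  else if (phase <= 0.1 || phase >= 0.9) "synchronous"
  else "intermediate"
  list(phase = phase, resultant = resultant, n = length(ph), label = label)
}

#' Normalise frequencies to a reference value
#'
#' @param values Numeric frequencies.
#' @param reference Positive reference frequency (maps to 1).
#' @return `values / reference`.
#' @export
normalize_frequency <- function(values, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0)
    rlang::abort("reference frequency must be a single positive number",
                 class = "spinalcpg_config_error")
  values / reference
}

#' Rhythm metrics per population and epoch
#'
#' Histograms, burst segmentation and frequency estimation for each
#' requested population/side within each recording epoch.
#'
#' @param recordings A `cpg_recordings`.
#' @param populations Population names (default: flexor and extensor
#'   half-centers).
#' @param sides Sides to analyse (defaults to those present).
#' @param bin_ms,threshold_frac,min_burst_ms,min_gap_ms Passed to
#'   [population_histogram()] and [detect_bursts()].
#' @return Tibble: `epoch`, `population`, `side`, `frequency_hz`,
#'   `n_bursts`, `oscillatory`, `mean_rate`.
#' @export
rhythm_metrics <- function(recordings, populations = c("F", "E"),
                           sides = NULL, bin_ms = 100, threshold_frac = 0.3,
                           min_burst_ms = 300, min_gap_ms = 200) {
  stopifnot(inherits(recordings, "cpg_recordings"))
  if (is.null(sides)) sides <- unique(recordings$pop_sizes$side)
  grid <- tidyr::expand_grid(epoch = recordings$epochs$epoch,
                             population = populations, side = sides)
  purrr::pmap(grid, function(epoch, population, side) {
    h <- population_histogram(recordings, population, side,
                              bin_ms = bin_ms, window = epoch)
    b <- detect_bursts(h, threshold_frac, min_burst_ms, min_gap_ms)
    ep <- recordings$epochs[recordings$epochs$epoch == epoch, ]
    f <- oscillation_frequency(b, (ep$end_ms - ep$start_ms) / 1000)
    tibble::tibble(epoch = epoch, population = population, side = side,
                   frequency_hz = f$frequency_hz, n_bursts = f$n_bursts,
                   oscillatory = f$oscillatory, mean_rate = mean(h$rate))
  }) |> dplyr::bind_rows()
}

#' Flexor-extensor and left-right coordination of a recording
#'
#' Computes the burst trains of the flexor (F) and extensor (E) half-centers
#' and returns the phase relations that characterise the locomotor pattern:
#' F vs E on each available side, and left vs right F when both sides exist.
#'
#' @param recordings A `cpg_recordings`.
#' @param window Epoch label or `c(start_ms, end_ms)`; default whole record.
#' @param ... Burst segmentation settings passed to [detect_bursts()].
#' @return Tibble: `pair`, `phase`, `resultant`, `n`, `label`.
#' @export
coordination_summary <- function(recordings, window = NULL, ...) {
  sides <- unique(recordings$pop_sizes$side)
  train <- function(pop, side) {
    detect_bursts(population_histogram(recordings, pop, side,
                                       window = window), ...)
  }
  rows <- list()
  for (s in sides) {
    pd <- phase_difference(train("F", s), train("E", s))
    rows[[length(rows) + 1]] <- tibble::tibble(
      pair = paste0("F-E (", s, ")"), phase = pd$phase,
      resultant = pd$resultant, n = pd$n, label = pd$label)
  }
  if (all(c("left", "right") %in% sides)) {
    pd <- phase_difference(train("F", "left"), train("F", "right"))
    rows[[length(rows) + 1]] <- tibble::tibble(
      pair = "F left-right", phase = pd$phase,
      resultant = pd$resultant, n = pd$n, label = pd$label)
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
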