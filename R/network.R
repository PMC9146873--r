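#' Population parameter table
#'
#' The twelve interneuron/half-center population types of the bilateral
#' locomotor network, with sizes, maximal conductances and leak-reversal
#' distributions. `scale` shrinks population sizes (rounding, minimum 1)
#' for reduced test models; connection probabilities are rescaled elsewhere
#' to preserve expected in-degree.
#'
#' @param scale Size scaling factor in `(0, 1]`.
#' @return A tibble with one row per population type: `population`, `N`,
#'   `gNa`, `gNaP_mean`, `gNaP_sd`, `gK`, `gL` (mS/cm^2), `EL_mean`,
#'   `EL_sd` (mV), `has_inap`, `photo` (0/1/2), `commissural`.
#' @export
population_table <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  tab <- tibble::tribble(
    ~population, ~N,  ~gNa, ~gNaP_mean, ~gNaP_sd, ~gK, ~gL,  ~EL_mean, ~EL_sd,
    "F",         200, 25,   0.75,       0.00375,  2,   0.07, -76.8,    0.77,
    "E",         100, 25,   0.75,       0.00375,  2,   0.07, -72,      0.72,
    "V2b",       100, 10,   0,          0,        5,   0.1,  -80.4,    1.68,
    "V1-1",      100, 10,   0,          0,        5,   0.1,  -90,      1.8,
    "V1",        100, 10,   0,          0,        5,   0.1,  -90,      1.8,
    "Ini",       50,  10,   0,          0,        5,   0.1,  -60,      1.2,
    "Ini1",      50,  10,   0,          0,        5,   0.1,  -76.8,    1.57,
    "V2a",       50,  40,   0,          0,        5,   0.8,  -72.6,    1.45,
    "V0V",       50,  10,   0,          0,        5,   0.1,  -74.4,    1.5,
    "V0D",       50,  10,   0,          0,        5,   0.1,  -81.6,    2.45,
    "V3",        100, 10,   0,          0,        5,   0.1,  -81.6,    2.45,
    "CINe",      100, 10,   0,          0,        5,   0.1,  -60,      2.04
  )
  tab$has_inap <- tab$gNaP_mean > 0
  tab$photo <- ifelse(tab$population == "V1", 1L,
                      ifelse(tab$population == "V1-1", 2L, 0L))
  tab$commissural <- tab$population %in% c("V0V", "V0D", "V3", "CINe")
  tab$N <- pmax(1L, as.integer(round(tab$N * scale)))
  tab
}

#' Connection specification table
#'
#' Mean weights and connection probabilities between population types.
#' `laterality` is `"ipsi"` (within a side) or `"contra"` (crossing the
#' midline). The descending commissural excitatory population (CINe)
#' projects contralaterally onto the V1 populations: this crossing pathway
#' is what silences V1 after midsagittal hemisection.
#'
#' @param scale Size scaling factor; probabilities are multiplied by
#'   `1/scale` (capped at 1) so expected in-degree is preserved when
#'   population sizes shrink.
#' @return A tibble: `source`, `target`, `laterality`, `weight`
#'   (signed, dimensionless), `prob`.
#' @export
connection_table <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  tab <- tibble::tribble(
    ~source, ~target, ~laterality, ~weight,  ~prob,
    "F",     "F",     "ipsi",      0.0075,   0.1,
    "F",     "V2b",   "ipsi",      0.5,      0.1,
    "F",     "V2a",   "ipsi",      0.3,      0.1,
    "F",     "V0D",   "ipsi",      0.6,      0.1,
    "E",     "E",     "ipsi",      0.018,    0.1,
    "E",     "V1-1",  "ipsi",      0.57,     0.1,
    "E",     "V3",    "ipsi",      0.5,      0.05,
    "V2b",   "E",     "ipsi",     -0.3,      0.1,
    "V1-1",  "F",     "ipsi",     -0.0165,   0.1,
    "V1",    "E",     "ipsi",     -0.05,     0.1,
    "V1",    "Ini",   "ipsi",     -0.06,     0.1,
    "Ini",   "F",     "ipsi",     -0.005,    0.1,
    "Ini1",  "F",     "ipsi",     -0.0025,   0.1,
    "V2a",   "V0V",   "ipsi",      0.1,      0.1,
    "V0V",   "Ini",   "contra",    0.1,      0.1,
    "V0D",   "F",     "contra",   -0.02,     0.1,
    "V0D",   "V1",    "contra",   -0.07,     0.1,
    "V3",    "E",     "contra",    0.05,     0.05,
    "V3",    "V1-1",  "contra",    0.3,      0.05,
    "CINe",  "V1",    "contra",    0.14,     0.1,
    "CINe",  "V1-1",  "contra",    0.03,     0.1
  )
  tab$prob <- pmin(1, tab$prob / scale)
  tab
}

#' Default brainstem drive weights
#'
#' Drive weights of the brainstem-evoked variant: the rhythm generators
#' (F, E), the descending commissural CINe populations, and the inhibitory
#' Ini populations receive tonic excitatory drive on both sides.
#'
#' @return Named numeric vector of per-population drive weights.
#' @export
default_drive_weights <- function() {
  c(F = 0.4, E = 0.48, CINe = 0.75, Ini = 2)
}

#' Build one neuron population
#'
#' Samples per-neuron leak reversal potentials `EL ~ N(EL_mean * (1 - alpha),
#' EL_sd)` (the drug-excitation parameter `alpha` depolarises the mean since
#' baseline means are negative) and, where applicable, per-neuron persistent
#' sodium conductances. Samples beyond 6 SD of the mean are redrawn.
#'
#' @param population Population type name (row of [population_table()]).
#' @param side `"left"` or `"right"`.
#' @param alpha Drug-excitation parameter in `[0, 1)`.
#' @param scale Size scaling factor.
#' @param seed Integer seed (required; sampling is deterministic given it).
#' @return Tibble of per-neuron parameters.
#' @export
build_population <- function(population, side = "left", alpha = 0,
                             scale = 1, seed) {
  spec <- population_table(scale)
  spec <- spec[spec$population == population, ]
  if (nrow(spec) != 1)
    rlang::abort(paste0("unknown population: ", population),
                 class = "spinalcpg_config_error")
  if (spec$N < 1 || spec$EL_sd < 0)
    rlang::abort("population size must be >= 1 and EL SD >= 0",
                 class = "spinalcpg_config_error")
  check_alpha(alpha)
  withr::with_seed(seed, sample_population(spec, side, alpha))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1)
    rlang::abort("alpha must be a single value in [0, 1)",
                 class = "spinalcpg_config_error")
  invisible(alpha)
}

# 6-SD-truncated normal sampling (resample beyond the bound)
rnorm_trunc <- function(n, mean, sd, k = 6) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

# sample one population row; assumes RNG state is set by the caller
sample_population <- function(spec, side, alpha) {
  n <- spec$N
  el_eps <- rnorm_trunc(n, 0, spec$EL_sd)
  gnap <- if (spec$has_inap) {
    x <- rnorm_trunc(n, spec$gNaP_mean, spec$gNaP_sd)
    pmax(x, 0)
  } else rep(0, n)
  tibble::tibble(
    population = spec$population, side = side, index = seq_len(n),
    C = 1, gNa = spec$gNa, gNaP = gnap, gK = spec$gK, gL = spec$gL,
    EL_mean0 = spec$EL_mean, EL_eps = el_eps,
    EL = spec$EL_mean * (1 - alpha) + el_eps,
    has_inap = spec$has_inap, photo = spec$photo
  )
}

#' Sample the stochastic connectome
#'
#' For each connection specification and each ordered (source neuron, target
#' neuron) pair, a synapse exists independently with probability `prob`
#' (all pairs for `prob = 1`). Sampled weights are
#' `N(w, 0.05 |w|)` for excitatory and `N(w, 0.10 |w|)` for inhibitory
#' connections, resampled if the draw would cross zero (sign preserved).
#'
#' @param specs Connection specification tibble (see [connection_table()])
#'   with columns `source`, `target`, `laterality`, `weight`, `prob`.
#' @param neurons Per-neuron parameter tibble with global `id` column.
#' @param seed Integer seed.
#' @return Tibble of sampled synapses: `src`, `tgt` (global neuron ids),
#'   `weight`, `source_pop`, `target_pop`, `source_side`, `target_side`,
#'   `laterality`.
#' @export
build_connectome <- function(specs, neurons, seed) {
  sides <- unique(neurons$side)
  withr::with_seed(seed, {
    out <- purrr::pmap(specs, function(source, target, laterality, weight, prob) {
      purrr::map(sides, function(s) {
        tgt_side <- if (laterality == "ipsi") s else setdiff(c("left", "right"), s)
        if (length(tgt_side) == 0 || !(tgt_side %in% sides)) return(NULL)
        src_ids <- neurons$id[neurons$population == source & neurons$side == s]
        tgt_ids <- neurons$id[neurons$population == target & neurons$side == tgt_side]
        if (length(src_ids) == 0 || length(tgt_ids) == 0)
          rlang::abort(paste0("dangling population in connection spec: ",
                              source, " -> ", target),
                       class = "spinalcpg_config_error")
        pairs <- expand.grid(src = src_ids, tgt = tgt_ids)
        if (prob < 1) pairs <- pairs[stats::runif(nrow(pairs)) < prob, , drop = FALSE]
        if (nrow(pairs) == 0) return(NULL)
        sd <- if (weight > 0) 0.05 * weight else 0.10 * abs(weight)
        w <- stats::rnorm(nrow(pairs), weight, sd)
        flip <- sign(w) != sign(weight)
        while (any(flip)) {
          w[flip] <- stats::rnorm(sum(flip), weight, sd)
          flip <- sign(w) != sign(weight)
        }
        tibble::tibble(src = pairs$src, tgt = pairs$tgt, weight = w,
                       source_pop = source, target_pop = target,
                       source_side = s, target_side = tgt_side,
                       laterality = laterality)
      }) |> purrr::compact() |> dplyr::bind_rows()
    })
    dplyr::bind_rows(out)
  })
}

#' Assemble the default bilateral locomotor network
#'
#' Builds all populations on both sides, samples the connectome, and applies
#' the variant transformations: the drug variant depolarises leak reversals
#' via `alpha`; the brainstem variant attaches tonic drives (level `d`) with
#' the default drive-weight map. A hemicord model is built intact and then
#' hemisected (left side kept).
#'
#' @param variant `"drug"` or `"brainstem"`.
#' @param topology `"intact"` or `"hemicord"`.
#' @param alpha Drug-excitation parameter (drug variant; ignored otherwise).
#' @param d Drive level (brainstem variant).
#' @param drive_weights Named per-population drive weights.
#' @param scale Size scaling factor (1 = full-size model, 0.25 = the
#'   quarter-scale test model with in-degree-preserving rescaling).
#' @param seed Integer build seed (structural randomness only).
#' @return A `cpg_network` object: list with `neurons` (tibble), `edges`
#'   (tibble), `syn` (synaptic parameters), `meta` (variant flags, alpha,
#'   d, drive map, seed, scale).
#' @export
default_model <- function(variant = c("drug", "brainstem"),
                          topology = c("intact", "hemicord"),
                          alpha = 0, d = if (variant == "brainstem") 1 else 0,
                          drive_weights = default_drive_weights(),
                          scale = 1, seed = 1) {
  variant <- match.arg(variant)
  topology <- match.arg(topology)
  if (variant == "drug") check_alpha(alpha)
  seeds <- derive_seeds(seed, 2L)
  ptab <- population_table(scale)
  neurons <- withr::with_seed(seeds[1], purrr::map2(
    rep(ptab$population, 2), rep(c("left", "right"), each = nrow(ptab)),
    function(p, s) {
      spec <- ptab[ptab$population == p, ]
      sample_population(spec, s, if (variant == "drug") alpha else 0)
    }))
  neurons <- dplyr::bind_rows(neurons)
  neurons$id <- seq_len(nrow(neurons))
  neurons <- dplyr::relocate(neurons, "id")
  edges <- build_connectome(connection_table(scale), neurons, seeds[2])
  net <- structure(list(
    neurons = neurons, edges = edges, syn = synaptic_parameters(),
    meta = list(variant = variant, topology = "intact",
                alpha = if (variant == "drug") alpha else 0,
                d = 0, drive_weights = NULL,
                seed = seed, scale = scale)
  ), class = "cpg_network")
  if (variant == "brainstem")
    net <- attach_brainstem_drive(net, drive_weights, d)
  if (topology == "hemicord") net <- apply_hemisection(net)
  net
}

# deterministic child seeds below 2^31 from one parent seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Set the drug-excitation level of a built network
#'
#' Shifts every neuron's leak reversal so that the population mean equals
#' `EL_mean0 * (1 - alpha)` while preserving each neuron's sampled deviation
#' from the mean. Only meaningful for the drug variant.
#'
#' @param network A `cpg_network`.
#' @param alpha New drug-excitation parameter in `[0, 1)`.
#' @return The network with updated leak reversals.
#' @export
apply_drug_excitation <- function(network, alpha) {
  stopifnot(inherits(network, "cpg_network"))
  if (network$meta$variant != "drug")
    rlang::abort("drug excitation applies to the drug variant only",
                 class = "spinalcpg_config_error")
  check_alpha(alpha)
  network$neurons$EL <- network$neurons$EL_mean0 * (1 - alpha) +
    network$neurons$EL_eps
  network$meta$alpha <- alpha
  network
}

#' Midsagittal hemisection of an intact network
#'
#' Removes one side's populations, every crossing (contralateral) synapse,
#' and any drive attachment on the removed side. Kept-side internal wiring
#' is untouched.
#'
#' @param network An intact `cpg_network`.
#' @param keep Side to keep, `"left"` (default) or `"right"`.
#' @return The hemicord network.
#' @export
apply_hemisection <- function(network, keep = c("left", "right")) {
  stopifnot(inherits(network, "cpg_network"))
  keep <- match.arg(keep)
  if (network$meta$topology == "hemicord")
    rlang::abort("network is already hemisected", class = "spinalcpg_config_error")
  network$neurons <- network$neurons[network$neurons$side == keep, ]
  network$edges <- network$edges[network$edges$source_side == keep &
                                   network$edges$target_side == keep, ]
  # re-index neuron ids compactly
  old <- network$neurons$id
  remap <- stats::setNames(seq_along(old), old)
  network$neurons$id <- seq_along(old)
  network$edges$src <- unname(remap[as.character(network$edges$src)])
  network$edges$tgt <- unname(remap[as.character(network$edges$tgt)])
  if (!is.null(network$meta$drive_weights))
    network$meta$drive_sides <- keep
  network$meta$topology <- "hemicord"
  network$meta$kept_side <- keep
  network
}

#' Attach tonic brainstem drive to a network
#'
#' Adds the second, drive term of the excitatory synaptic conductance for
#' the populations named in `drive_weights` on every present side:
#' `g_drive = gEd * max(wd * d, 0)` per neuron.
#'
#' @param network A `cpg_network` (brainstem variant).
#' @param drive_weights Named numeric vector `population -> wd`.
#' @param d Drive level.
#' @return The network with the drive map recorded.
#' @export
attach_brainstem_drive <- function(network, drive_weights = default_drive_weights(),
                                   d = 1) {
  stopifnot(inherits(network, "cpg_network"))
  if (network$meta$variant != "brainstem")
    rlang::abort("drive attaches to the brainstem variant only",
                 class = "spinalcpg_config_error")
  unknown <- setdiff(names(drive_weights), unique(network$neurons$population))
  if (length(unknown))
    rlang::abort(paste0("drive map names unknown population(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "spinalcpg_config_error")
  network$meta$drive_weights <- drive_weights
  network$meta$d <- d
  network
}

#' Per-neuron tonic drive conductance vector of a network
#'
#' @param network A `cpg_network`.
#' @return Numeric vector, one value per neuron (mS/cm^2).
#' @export
network_drive <- function(network) {
  g <- rep(0, nrow(network$neurons))
  dw <- network$meta$drive_weights
  if (is.null(dw) || network$meta$d == 0) return(g)
  for (p in names(dw)) {
    sel <- network$neurons$population == p
    g[sel] <- drive_conductance(dw[[p]], network$meta$d, network$syn$gEd)
  }
  g
}

#' @export
print.cpg_network <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<cpg_network> %s variant, %s topology\n", m$variant, m$topology))
  cat(sprintf("  %d neurons in %d populations, %d synapses\n",
              nrow(x$neurons),
              nrow(dplyr::distinct(x$neurons, .data$population, .data$side)),
              nrow(x$edges)))
  if (m$variant == "drug") cat(sprintf("  alpha = %g\n", m$alpha))
  else cat(sprintf("  d = %g; drive on: %s\n", m$d,
                   paste(names(m$drive_weights), collapse = ", ")))
  cat(sprintf("  build seed %s, scale %g\n", format(m$seed), m$scale))
  invisible(x)
}
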