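test_that("population construction samples the tabulated leak distribution", {
  pop <- build_population("F", alpha = 0, seed = 5)
  expect_equal(nrow(pop), 200)
  # sample mean within 3 standard errors of the tabulated mean
  se <- 0.77 / sqrt(200)
  expect_lt(abs(mean(pop$EL) - (-76.8)), 3 * se)
  expect_true(all(abs(pop$EL_eps) <= 6 * 0.77))
  # determinism: same seed, identical vectors
  pop2 <- build_population("F", alpha = 0, seed = 5)
  expect_identical(pop$EL, pop2$EL)
  # persistent-sodium conductance is sampled only for the half-centers
  expect_true(all(pop$gNaP > 0))
  expect_true(all(build_population("V1", seed = 1)$gNaP == 0))
  expect_error(build_population("nope", seed = 1),
               class = "spinalcpg_config_error")
})

test_that("drug excitation rescales every population mean leak reversal", {
  expect_equal(-76.8 * (1 - 0.17), -63.744)
  net0 <- default_model("drug", "intact", alpha = 0, scale = 0.25, seed = 3)
  net <- apply_drug_excitation(net0, 0.17)
  ms <- dplyr::summarise(
    dplyr::group_by(net$neurons, population),
    m0 = mean(EL_mean0), shift = mean(EL - EL_eps), .groups = "drop")
  expect_equal(ms$shift, ms$m0 * (1 - 0.17))
  # alpha = 0 leaves the network unchanged
  expect_identical(apply_drug_excitation(net0, 0)$neurons$EL, net0$neurons$EL)
  # monotone: larger alpha strictly depolarizes every population mean
  net2 <- apply_drug_excitation(net0, 0.25)
  expect_true(all(net2$neurons$EL > net$neurons$EL))
  expect_error(apply_drug_excitation(net0, 1.2), class = "spinalcpg_config_error")
})

test_that("connectome sampling matches binomial expectation and edge-count bounds", {
  neurons <- dplyr::bind_rows(
    withr::with_seed(1, spinalcpg:::sample_population(
      population_table()[population_table()$population == "V1", ], "left", 0)),
    withr::with_seed(2, spinalcpg:::sample_population(
      population_table()[population_table()$population == "E", ], "left", 0)))
  neurons$id <- seq_len(nrow(neurons))
  spec <- tibble::tibble(source = "V1", target = "E", laterality = "ipsi",
                         weight = -0.05, prob = 0.1)
  ed <- build_connectome(spec, neurons, seed = 9)
  # 100 x 100 pairs at p = 0.1: expect ~1000 within 4 binomial SD
  sd4 <- 4 * sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(nrow(ed) - 1000), sd4)
  # p = 1 gives the full bipartite graph
  spec$prob <- 1
  expect_equal(nrow(build_connectome(spec, neurons, seed = 9)), 10000)
})

test_that("sampled weights keep their sign and tabulated dispersion", {
  neurons <- dplyr::bind_rows(
    withr::with_seed(1, spinalcpg:::sample_population(
      population_table()[population_table()$population == "CINe", ], "left", 0)),
    withr::with_seed(2, spinalcpg:::sample_population(
      population_table()[population_table()$population == "V1", ], "left", 0)))
  neurons$id <- seq_len(nrow(neurons))
  # 100x100 pairs at p = 1: 1e4 draws of each weight class
  exc <- build_connectome(
    tibble::tibble(source = "CINe", target = "V1", laterality = "ipsi",
                   weight = 0.14, prob = 1), neurons, seed = 2)
  expect_true(all(exc$weight > 0))
  expect_equal(sd(exc$weight) / 0.14, 0.05, tolerance = 0.05)
  inh <- build_connectome(
    tibble::tibble(source = "V1", target = "CINe", laterality = "ipsi",
                   weight = -0.06, prob = 1), neurons, seed = 2)
  expect_true(all(inh$weight < 0))
  expect_equal(sd(inh$weight) / 0.06, 0.10, tolerance = 0.05)
})

test_that("default bilateral model realizes the full population and wiring plan", {
  net <- cached("net_full", function()
    default_model("drug", "intact", alpha = 0.17, scale = 1, seed = 4))
  pops <- dplyr::distinct(net$neurons, population, side)
  expect_equal(nrow(pops), 24)
  per_side <- dplyr::count(net$neurons, side)
  expect_equal(per_side$n, c(1050, 1050))
  # every connection-table row realized on each side
  spec <- connection_table()
  realized <- dplyr::distinct(net$edges, source_pop, target_pop, source_side)
  for (i in seq_len(nrow(spec))) {
    expect_equal(sum(realized$source_pop == spec$source[i] &
                       realized$target_pop == spec$target[i]), 2,
                 info = paste(spec$source[i], "->", spec$target[i]))
  }
  # photocurrent capability on the two V1 classes only
  expect_setequal(unique(net$neurons$population[net$neurons$photo > 0]),
                  c("V1", "V1-1"))
})

test_that("outgoing weight signs follow the connection table (sign audit)", {
  net <- cached("net_full", function()
    default_model("drug", "intact", alpha = 0.17, scale = 1, seed = 4))
  inhib <- c("V1", "V1-1", "V2b", "Ini", "Ini1", "V0D")
  excit <- c("F", "E", "V2a", "V0V", "V3", "CINe")
  w_by_src <- split(net$edges$weight, net$edges$source_pop)
  for (p in inhib) expect_true(all(w_by_src[[p]] < 0), info = p)
  for (p in excit) expect_true(all(w_by_src[[p]] > 0), info = p)
})

test_that("left and right wiring statistics mirror each other", {
  net <- cached("net_full", function()
    default_model("drug", "intact", alpha = 0.17, scale = 1, seed = 4))
  counts <- dplyr::count(net$edges, source_pop, target_pop, source_side)
  wide <- tidyr::pivot_wider(counts, names_from = source_side, values_from = n)
  # same expected count per spec: sides agree within 8 binomial SD
  spec <- connection_table()
  for (i in seq_len(nrow(spec))) {
    row <- wide[wide$source_pop == spec$source[i] &
                  wide$target_pop == spec$target[i], ]
    n_exp <- mean(c(row$left, row$right))
    tol <- 8 * sqrt(n_exp * (1 - spec$prob[i])) + 1
    expect_lt(abs(row$left - row$right), tol,
              label = paste(spec$source[i], "->", spec$target[i]))
  }
})

test_that("rebuilding with the same seed reproduces the connectome exactly", {
  a <- default_model("drug", "intact", alpha = 0.1, scale = 0.25, seed = 77)
  b <- default_model("drug", "intact", alpha = 0.1, scale = 0.25, seed = 77)
  expect_identical(a$edges, b$edges)
  expect_identical(a$neurons, b$neurons)
  c <- default_model("drug", "intact", alpha = 0.1, scale = 0.25, seed = 78)
  expect_false(identical(a$edges$weight, c$edges$weight))
})

test_that("hemisection removes one side and every crossing influence", {
  net <- default_model("drug", "intact", alpha = 0.2, scale = 0.25, seed = 6)
  left_ids <- net$neurons$id[net$neurons$side == "left"]
  n_left_internal <- sum(net$edges$source_side == "left" &
                           net$edges$target_side == "left")
  hemi <- apply_hemisection(net, keep = "left")
  expect_equal(unique(hemi$neurons$side), "left")
  expect_equal(nrow(hemi$neurons), length(left_ids))
  expect_equal(sum(hemi$edges$laterality == "contra"), 0)
  # kept-side internal wiring untouched (count bookkeeping)
  expect_equal(nrow(hemi$edges), n_left_internal)
  expect_error(apply_hemisection(hemi), class = "spinalcpg_config_error")
  # no dangling neuron references after re-indexing
  expect_true(all(hemi$edges$src %in% hemi$neurons$id))
  expect_true(all(hemi$edges$tgt %in% hemi$neurons$id))
})

test_that("brainstem drive attaches to the four target populations per side", {
  net <- default_model("brainstem", "intact", d = 1, scale = 0.25, seed = 8)
  g <- network_drive(net)
  driven <- dplyr::distinct(net$neurons[g > 0, ], population, side)
  expect_equal(nrow(driven), 8)
  expect_setequal(unique(driven$population), c("F", "E", "CINe", "Ini"))
  # the Ini attachment conductance follows the drive arithmetic
  expect_equal(unique(g[net$neurons$population == "Ini"]), 0.05 * 2 * 1)
  # d = 0 removes all drive
  net0 <- attach_brainstem_drive(net, default_drive_weights(), d = 0)
  expect_true(all(network_drive(net0) == 0))
  expect_error(attach_brainstem_drive(net, c(Foo = 1)),
               class = "spinalcpg_config_error")
  # drug variant carries no drive
  expect_true(all(network_drive(default_model("drug", "intact", alpha = 0.1,
                                              scale = 0.25, seed = 8)) == 0))
})

test_that("in-degree is preserved under model downscaling", {
  spec1 <- connection_table(1)
  spec4 <- connection_table(0.25)
  pt1 <- population_table(1); pt4 <- population_table(0.25)
  n1 <- stats::setNames(pt1$N, pt1$population)
  n4 <- stats::setNames(pt4$N, pt4$population)
  indeg1 <- n1[spec1$source] * spec1$prob
  indeg4 <- n4[spec4$source] * spec4$prob
  # equal up to integer rounding of the scaled population sizes
  expect_equal(unname(indeg4), unname(indeg1), tolerance = 0.05)
})
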