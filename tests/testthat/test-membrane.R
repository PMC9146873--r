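test_that("gate steady states match their tabulated sigmoids", {
  # half-(in)activation at each channel's half-voltage
  expect_equal(gate_steady_state("Na", "m", -34), 0.5)
  expect_equal(gate_steady_state("NaP", "h", -60), 0.5)
  expect_equal(gate_steady_state("NaP", "m", -47.1), 0.5)
  expect_equal(gate_steady_state("K", "m", -28), 0.5)
  expect_equal(gate_steady_state("Na", "h", -55), 0.5)
  # potassium does not inactivate
  expect_equal(gate_steady_state("K", "h", c(-120, -40, 40)), rep(1, 3))
  # monotone in V for sigmoidal gates, values stay in [0,1]
  v <- seq(-120, 60, by = 0.5)
  for (cg in list(c("Na", "m"), c("Na", "h"), c("NaP", "m"),
                  c("NaP", "h"), c("K", "m"))) {
    g <- gate_steady_state(cg[1], cg[2], v)
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(diff(g) > 0) || all(diff(g) < 0))
  }
  expect_error(gate_steady_state("Ca", "m", -50), class = "spinalcpg_config_error")
})

test_that("gate time constants match their tabulated forms", {
  expect_equal(gate_time_constant("NaP", "h", -60), 18000)  # cosh(0) = 1
  expect_equal(gate_time_constant("K", "m", -40), 3.5)
  expect_equal(gate_time_constant("Na", "h", -50), 10)      # 20/(1+1)
  # sodium activation is instantaneous
  expect_equal(gate_time_constant("Na", "m", c(-80, 0)), c(0, 0))
  expect_equal(gate_time_constant("NaP", "m", -47.1), 0)
  # non-negative everywhere
  v <- seq(-120, 60, by = 1)
  expect_true(all(gate_time_constant("Na", "h", v) >= 0))
  expect_true(all(gate_time_constant("NaP", "h", v) >= 0))
  expect_true(all(gate_time_constant("K", "m", v) >= 0))
})

test_that("ionic currents evaluate term by term", {
  p <- neuron_parameters("F")
  # zero driving force at the sodium reversal
  I <- ionic_currents(55, p)
  expect_equal(unname(I["INa"]), 0)
  expect_equal(unname(I["INaP"]), 0)
  # leak reversal
  I <- ionic_currents(p$EL, p)
  expect_equal(unname(I["IL"]), 0)
  # direct evaluation of the leak term
  p2 <- neuron_parameters("F", EL = -76.8)
  I2 <- ionic_currents(-66.8, p2)
  expect_equal(unname(I2["IL"]), 0.07 * 10)
  # INaP identically 0 without the current
  ps <- neuron_parameters("Ini")
  expect_equal(unname(ionic_currents(-40, ps)["INaP"]), 0)
  # photocurrents zero at zero conductance, nonzero otherwise
  expect_equal(unname(ionic_currents(-40, ps)["IAr"]), 0)
  expect_equal(unname(ionic_currents(-40, ps, gAr = 7)["IAr"]), 7 * (-40 + 80))
  expect_error(ionic_currents(-40, ps, gAr = -1), class = "spinalcpg_config_error")
})

test_that("exponential-Euler step reduces to RC relaxation for pure leak", {
  p <- neuron_parameters(gNa = 0, gK = 0, gL = 0.07, EL = -70, C = 1)
  st <- list(V = -60, hNa = 0, hNaP = 0, mK = 0)
  tau <- p$C / p$gL  # 14.29 ms
  v <- st$V
  for (i in 1:100) { st <- exp_euler_step(st, p, dt = 0.1); }
  expect_equal(st$V, -70 + 10 * exp(-10 / tau), tolerance = 1e-10)
})

test_that("gates converge to steady state when V is held", {
  p <- neuron_parameters("F")
  st <- list(V = -34, hNa = 0.9, hNaP = 0.9, mK = 0.1)
  # hold V at the Na activation half-voltage far longer than tau
  for (i in 1:20000) {
    st2 <- exp_euler_step(st, p, dt = 1)
    st2$V <- -34
    st <- st2
  }
  expect_equal(st$hNa, gate_steady_state("Na", "h", -34), tolerance = 1e-6)
  expect_equal(st$mK, gate_steady_state("K", "m", -34), tolerance = 1e-6)
})

test_that("engine trajectory matches repeated exact-formula R steps", {
  # stable subthreshold relaxation (no NaP positive feedback): trajectories
  # agree to interpolation-table precision
  p <- neuron_parameters("Ini", EL = -60)
  r <- run_single_neuron(p, duration_s = 0.1, settle_s = 0, dt = 0.1,
                         V0 = -70, trace = TRUE)
  st <- init_state(-70)
  v_r <- numeric(nrow(r$trace))
  v_r[1] <- -70
  for (i in 2:length(v_r)) {
    st <- exp_euler_step(st, p, dt = 0.1)
    v_r[i] <- st$V
  }
  expect_lt(max(abs(r$trace$V - v_r)), 1e-6)
  # spiking trajectory: identical spike count over 1 s of tonic firing
  p2 <- neuron_parameters("F", EL = -56)
  r2 <- run_single_neuron(p2, duration_s = 1, settle_s = 0, dt = 0.1,
                          V0 = p2$EL)
  st <- init_state(p2$EL)
  v_r2 <- numeric(10000)
  for (i in seq_along(v_r2)) {
    st <- exp_euler_step(st, p2, dt = 0.1)
    v_r2[i] <- st$V
  }
  expect_equal(length(r2$spike_times), length(detect_spikes(v_r2)))
})

test_that("isolated F-type neuron passes silence -> bursting -> tonic with depolarization", {
  regimes <- vapply(c(-72, -64, -56), function(el) {
    p <- neuron_parameters("F", EL = el)
    r <- run_single_neuron(p, duration_s = 15, settle_s = 5)
    neuron_regime(r$spike_times, 15000)$regime
  }, character(1))
  expect_equal(regimes, c("silent", "bursting", "tonic"))
})

test_that("simple spiking neurons never burst intrinsically", {
  for (el in c(-70, -60, -50, -45)) {
    p <- neuron_parameters("Ini", EL = el)
    r <- run_single_neuron(p, duration_s = 10, settle_s = 2)
    reg <- neuron_regime(r$spike_times, 10000)$regime
    expect_true(reg %in% c("silent", "tonic"),
                info = sprintf("EL = %g gave %s", el, reg))
  }
})

test_that("spike detection is edge-triggered and matches a brute-force scan", {
  # constant subthreshold trace
  expect_length(detect_spikes(rep(-50, 100)), 0)
  # synthetic double crossing
  v <- c(-50, -20, 5, 10, -30, -60, -15, 20, -40)
  expect_length(detect_spikes(v), 2)
  # no re-trigger while above threshold
  expect_length(detect_spikes(c(-50, 0, 5, 8, 2, -50)), 1)
  # engine spike count equals an independent per-sample scan of the trace
  p <- neuron_parameters("Ini", EL = -48)
  r <- run_single_neuron(p, duration_s = 2, settle_s = 0, trace = TRUE)
  scan <- sum(r$trace$V >= -10 & c(FALSE, r$trace$V[-nrow(r$trace)] < -10))
  expect_equal(length(r$spike_times), scan)
})

test_that("gates remain in [0,1] along simulated trajectories", {
  p <- neuron_parameters("F", EL = -60)
  net_trace <- run_single_neuron(p, duration_s = 5, settle_s = 0, trace = TRUE)
  expect_true(all(is.finite(net_trace$trace$V)))
  # gate bounds along the trajectory, via exact R stepping on the same input
  st <- init_state(-60)
  ok <- TRUE
  for (i in 1:5000) {
    st <- exp_euler_step(st, p, dt = 0.1)
    ok <- ok && all(unlist(st[c("hNa", "hNaP", "mK")]) >= 0) &&
      all(unlist(st[c("hNa", "hNaP", "mK")]) <= 1)
  }
  expect_true(ok)
})
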