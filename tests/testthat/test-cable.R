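## Solver verification against closed-form passive solutions and an
## independent adaptive-ODE reference.

passive_densities <- function(grid) {
  d <- matrix(0, nrow = nrow(grid$compartments),
              ncol = length(nigradev:::CHANNEL_NAMES),
              dimnames = list(NULL, nigradev:::CHANNEL_NAMES))
  d[, "leak"] <- 0.1
  d
}

soma_only <- function(volume = 1000) {
  neuron_morphology(
    data.frame(id = 1L, label = "soma", parent = NA_integer_,
               length = 10, diam_prox = 10, diam_dist = 10),
    soma_volume = volume)
}

test_that("discretization respects the rule and conserves area", {
  m <- toy_neuron()
  g10 <- discretize(m, rule = 10)
  cp <- g10$compartments
  expect_equal(sum(cp$section == 4), 10L)       # 100 um / 10 um
  expect_true(all(cp$length <= 10 + 1e-9))
  g5 <- discretize(m, rule = 5)
  expect_equal(sum(g5$compartments$area), sum(cp$area), tolerance = 1e-3)
  ## soma replaced by its equivalent cylinder
  ec <- equivalent_cylinder(m$soma_volume)
  soma_cp <- cp[cp$region == "soma", ]
  expect_equal(sum(soma_cp$length), ec$length, tolerance = 1e-9)
})

test_that("axial conductance matches the closed form on a uniform cylinder", {
  ## 100 um, d = 2 um cylinder in 10 um compartments:
  ## g = pi d^2 / (4 Ra L) between adjacent compartment centres
  m <- neuron_morphology(
    data.frame(id = 1:2, label = c("soma", "dendrite"), parent = c(NA, 1),
               length = c(10, 100), diam_prox = c(10, 2),
               diam_dist = c(10, 2)),
    soma_volume = 1000)
  grid <- discretize(m, rule = 10, Ra = 150)
  cp <- grid$compartments
  dend <- cp[cp$region == "nabd", ]
  g_expected <- pi * (2e-4)^2 / (4 * 150 * 10e-4) * 1e6  # uS
  inner <- dend$g_axial_uS[dend$parent %in% dend$idx]
  expect_equal(inner, rep(g_expected, length(inner)), tolerance = 1e-9)
})

test_that("passive membrane relaxes to the leak reversal", {
  grid <- discretize(toy_neuron(), rule = 10)
  cfg <- sim_config(dt = 0.05, duration = 600, steady_state_discard = 0,
                    method = "be", record_every = 10L)
  tr <- integrate_grid(grid, passive_densities(grid), cfg,
                       record_sites = c(1, nrow(grid$compartments)))
  expect_equal(unname(tail(tr$v[, 1], 1)), -50, tolerance = 1e-3)
  expect_equal(unname(tail(tr$v[, 2], 1)), -50, tolerance = 1e-3)
})

test_that("isolated compartment charges with tau = Rm * Cm = 75 ms", {
  grid <- discretize(soma_only(), rule = 20)
  expect_equal(nrow(grid$compartments), 1L)
  cfg <- sim_config(dt = 0.01, duration = 900, steady_state_discard = 0,
                    method = "cn", record_every = 1L)
  tr <- integrate_grid(grid, passive_densities(grid), cfg,
                       stimuli = list(list(comp = 1, amp_nA = 0.05,
                                           t0 = 300, t1 = 900)))
  t <- tr$time
  v <- tr$v[, 1]
  v0 <- v[t == 300]
  vinf <- v[length(v)]
  ## time to reach 1 - 1/e of the step response
  target <- v0 + (vinf - v0) * (1 - exp(-1))
  idx <- which(t > 300 & v >= target)[1]
  tau_est <- t[idx] - 300
  expect_equal(tau_est, 75, tolerance = 0.01)
})

test_that("steady-state attenuation follows exp(-x/lambda)", {
  ## semi-infinite uniform cable: lambda = sqrt(Rm d / (4 Ra))
  d_um <- 2
  lambda_um <- sqrt(1e5 * (d_um * 1e-4) / (4 * 150)) * 1e4
  L <- 4 * lambda_um
  m <- neuron_morphology(
    data.frame(id = 1:2, label = c("soma", "dendrite"), parent = c(NA, 1),
               length = c(1, L), diam_prox = c(1, d_um),
               diam_dist = c(1, d_um)),
    soma_volume = 0.8)
  grid <- discretize(m, rule = 25)
  cp <- grid$compartments
  dend_idx <- cp$idx[cp$region == "nabd"]
  probe <- dend_idx[seq(4, 110, by = 10)]
  cfg <- sim_config(dt = 0.05, duration = 900, steady_state_discard = 0,
                    method = "be", record_every = 100L)
  tr <- integrate_grid(grid, passive_densities(grid), cfg,
                       record_sites = probe,
                       stimuli = list(list(comp = dend_idx[1], amp_nA = 0.02,
                                           t0 = 10, t1 = 900)))
  v_end <- tr$v[nrow(tr$v), ] + 50        # deviation from rest
  x <- (cp$arc0[probe] + cp$arc1[probe]) / 2
  ratio <- v_end / v_end[1]
  expected <- exp(-(x - x[1]) / lambda_um)
  expect_equal(unname(ratio), expected, tolerance = 0.01)
})

test_that("single-compartment model matches an adaptive-ODE reference", {
  skip_if_not_installed("deSolve")
  ch <- nigradev:::sim_channels()
  area <- 678; vol <- 2489
  dens <- c(Na = 120, KDR = 100, A = 0, Asoma = 6, CaL = 2.2, KCa = 3,
            H = 1, leak = 0.1)
  g_abs <- dens * area * 1e-6       # uS
  cap <- area * 0.75 * 1e-5         # nF
  cfg <- sim_config(dt = 0.0005, duration = 1000, steady_state_discard = 0,
                    method = "cn", record_every = 200L,
                    ca_tau = 150, ca_influx_scale = 0.15)
  grid <- list(compartments = data.frame(
    idx = 1, section = 1, region = "soma", arc0 = 0, arc1 = 1, length = 1,
    area = area, volume = vol, r_half = 1, parent = 0, c_nF = cap,
    g_axial_uS = 0), rule = 1, Ra = 150, Cm = 0.75)
  class(grid) <- "compartment_grid"
  dmat <- matrix(dens, nrow = 1, dimnames = list(NULL, names(dens)))
  tr <- integrate_grid(grid, dmat, cfg, record_sites = 1)

  ## independent reference: same equations via deSolve::lsoda
  gi <- nigradev:::gate_inf; gt <- nigradev:::gate_tau
  rhs <- function(t, y, parms) {
    v <- y[1]; ca <- y[10]
    gNa <- g_abs[["Na"]] * y[2]^3 * y[3]
    gK <- g_abs[["KDR"]] * y[4]^3
    gA <- g_abs[["Asoma"]] * y[5] * y[6]
    gCa <- g_abs[["CaL"]] * y[7]^2
    gSK <- g_abs[["KCa"]] * y[8]
    gH <- g_abs[["H"]] * y[9]
    gL <- g_abs[["leak"]]
    i_total <- gNa * (v - 60) + gK * (v + 90) + gA * (v + 90) +
      gCa * (v - 60) + gSK * (v + 90) + gH * (v + 35) + gL * (v + 50)
    dv <- -i_total / cap
    gate_d <- function(val, gate) (gi(gate, v) - val) / gt(gate, v)
    ica <- gCa * (v - 60)
    ca_target <- 5e-5 - 0.15 * 5.1821 * ica * 150 / vol
    c(dv,
      gate_d(y[2], ch$Na$act), gate_d(y[3], ch$Na$inact),
      gate_d(y[4], ch$KDR$act),
      gate_d(y[5], ch$Asoma$act), gate_d(y[6], ch$Asoma$inact),
      gate_d(y[7], ch$CaL$act),
      (gi(ch$KCa$act, v, ca) - y[8]) / ch$KCa$act$tau,
      gate_d(y[9], ch$H$act),
      (ca_target - ca) / 150)
  }
  v0 <- -70
  y0 <- c(v0,
          gi(ch$Na$act, v0), gi(ch$Na$inact, v0), gi(ch$KDR$act, v0),
          gi(ch$Asoma$act, v0), gi(ch$Asoma$inact, v0), gi(ch$CaL$act, v0),
          gi(ch$KCa$act, v0, 5e-5), gi(ch$H$act, v0), 5e-5)
  times <- tr$time
  ref <- deSolve::ode(y = unname(y0), times = times,
                      func = function(t, y, p) list(rhs(t, y, p)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  rms <- sqrt(mean((tr$v[, 1] - ref[, 2])^2))
  expect_lt(rms, 0.5)
})

test_that("charge balance holds in the passive model", {
  grid <- discretize(toy_neuron(), rule = 20)
  n <- nrow(grid$compartments)
  cfg <- sim_config(dt = 0.01, duration = 200, steady_state_discard = 0,
                    method = "cn", record_every = 1L)
  amp <- 0.04
  tr <- integrate_grid(grid, passive_densities(grid), cfg,
                       record_sites = seq_len(n),
                       stimuli = list(list(comp = 1, amp_nA = amp,
                                           t0 = 20, t1 = 150)))
  cp <- grid$compartments
  dt <- tr$dt
  v <- tr$v
  injected <- amp * 130                                    # nA * ms = pC
  cap_charge <- sum(cp$c_nF * (v[nrow(v), ] - v[1, ]))     # nF * mV = pC
  g_leak <- 0.1 * cp$area * 1e-6                           # uS
  ## trapezoid in time over all compartments (uS * mV * ms = pC)
  leak_per_t <- drop((v + 50) %*% g_leak)
  w <- rep(dt, length(leak_per_t)); w[1] <- w[length(w)] <- dt / 2
  leak_charge <- sum(leak_per_t * w)
  expect_equal((cap_charge + leak_charge) / injected, 1, tolerance = 5e-3)
})

test_that("pacemaking run is stationary and numerically converged", {
  run <- cached_p21_run()
  res <- run$res
  spikes <- res$spike_times[res$spike_times > 1800]
  expect_gt(length(spikes), 3)
  isi <- diff(spikes)
  ## stationarity: first vs second half of the analysis window
  h1 <- mean(head(isi, floor(length(isi) / 2)))
  h2 <- mean(tail(isi, floor(length(isi) / 2)))
  expect_equal(h1 / h2, 1, tolerance = 0.01)
  ## spatial refinement changes the somatic half-width by < 2%
  cfg_fine <- fast_config()
  cfg_fine$comp_rule <- 5
  res_fine <- run_protocol(run$m, build_scheme("model2"), cfg_fine)
  hw <- function(r) {
    late <- r$spike_times[r$spike_times > 1800]
    ap_shape(average_ap(r$traces$v[, 1], r$traces$dt, late))$half_width
  }
  expect_equal(hw(res_fine) / hw(res), 1, tolerance = 0.02)
})
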