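## Analytic and constructed-waveform checks of the AP analyzer.

## triangular AP rising from base to peak and back, on a baseline
triangle_ap <- function(dt = 0.01, base = -60, peak = 20, rise = 1,
                        fall = 1, pad = 2) {
  t_up <- seq(0, rise, by = dt)
  t_dn <- seq(dt, fall, by = dt)
  v <- c(rep(base, pad / dt),
         base + (peak - base) * t_up / rise,
         peak - (peak - base) * t_dn / fall,
         rep(base, pad / dt))
  list(v = v, dt = dt, t = (seq_along(v) - 1) * dt)
}

## the sigmoids are separated widely enough that each second-derivative
## peak is uncontaminated by the other component's curvature
two_sigmoid_upstroke <- function(dt = 0.01, a1 = 40, t1 = 3, s1 = 0.15,
                                 a2 = 50, t2 = 5, s2 = 0.25, base = -65) {
  t <- seq(0, 10.5, by = dt)
  v <- base + a1 / (1 + exp(-(t - t1) / s1)) + a2 / (1 + exp(-(t - t2) / s2))
  ## linear repolarization well after both sigmoids saturate, so that
  ## half-width is defined without touching the rising-phase analytics
  dn <- t > 7
  v[dn] <- pmax(base, v[dn] - (a1 + a2) * (t[dn] - 7) / 2)
  list(v = v, dt = dt, t = t)
}

test_that("spike detection finds constructed spikes and nothing else", {
  dt <- 0.02
  expect_identical(detect_spikes(rep(-60, 5000), dt), numeric(0))
  t <- seq(0, 1500, by = dt)
  v <- rep(-60, length(t))
  for (ts in c(100, 600, 1100)) {
    idx <- which(t >= ts & t <= ts + 1.2)
    v[idx] <- 20 - 80 * abs(t[idx] - ts - 0.6)
  }
  st <- detect_spikes(v, dt)
  expect_length(st, 3)
  expect_equal(st, c(100, 600, 1100) + 0.3, tolerance = 0.05)
  ## periodic pacemaking: n = duration x rate (+- 1)
  t <- seq(0, 10000, by = dt)
  v <- -55 + 60 * pmax(0, sin(2 * pi * t / 250))^40
  expect_lte(abs(length(detect_spikes(v, dt)) - 40), 1)
})

test_that("spike-triggered average reproduces identical spikes", {
  dt <- 0.02
  t <- seq(0, 3000, by = dt)
  v <- rep(-60, length(t))
  ## identical spikes defined on exact sample offsets
  template <- pmax(-60, 20 - 90 * abs((0:80) * dt - 0.8))
  for (ts in seq(200, 2800, by = 400)) {
    v[round(ts / dt) + 1 + (0:80)] <- template
  }
  st <- detect_spikes(v, dt)
  wf <- average_ap(v, dt, st, window = c(2, 3))
  expect_equal(max(wf$v), 20, tolerance = 0.01)
  single <- average_ap(v, dt, st[3], window = c(2, 3))
  expect_equal(wf$v, single$v, tolerance = 1e-9)
  ## averaging suppresses zero-mean noise
  set.seed(5)
  vn <- v + rnorm(length(v), sd = 2)
  wfn <- average_ap(vn, dt, detect_spikes(vn, dt), window = c(2, 3))
  expect_lt(sd(wfn$v - wf$v), 2 / sqrt(5) * 1.5)
  ## windows beyond the trace bounds are trimmed with a warning
  expect_warning(average_ap(v, dt, c(0.5, st[2]), window = c(2, 3)),
                 "trimmed")
})

test_that("threshold is the interpolated 20 mV/ms crossing", {
  dt <- 0.01
  ## piecewise-linear: slope 5 mV/ms up to -45 mV, then 40 mV/ms
  t <- seq(0, 12, by = dt)
  v <- ifelse(t <= 8, -85 + 5 * t, -45 + 40 * (t - 8))
  v <- pmin(v, 30)
  wf <- list(v = v, dt = dt, t = t)
  thr <- ap_threshold(wf, slope = 20)
  expect_equal(thr$threshold, -45, tolerance = 0.15)
  ## a ramp below the criterion slope has no threshold
  ramp <- list(v = -80 + 10 * t, dt = dt, t = t)
  expect_true(is.na(ap_threshold(ramp, slope = 20)$threshold))
  ## analytic sigmoid upstroke: V(t) = -60 + 80/(1+exp(-(t-5)/0.8));
  ## V'(t) = 20 solved in closed form
  tt <- seq(0, 10, by = dt)
  vv <- -60 + 80 / (1 + exp(-(tt - 5) / 0.8))
  ## V' = 80/(0.8) s(1-s) = 20 -> s(1-s) = 0.2 -> s = (1 - sqrt(0.2))/2
  s_cross <- (1 - sqrt(1 - 4 * 0.2)) / 2
  v_cross <- -60 + 80 * s_cross
  thr2 <- ap_threshold(list(v = vv, dt = dt, t = tt), slope = 20)
  expect_equal(thr2$threshold, v_cross, tolerance = 0.1)
})

test_that("triangular AP geometry gives half_width = half the base width", {
  ## from threshold (where slope jumps) to peak and symmetric descent, the
  ## width at half amplitude of a triangle is half its base width
  tri <- triangle_ap(rise = 1, fall = 1)
  sh <- ap_shape(tri)
  expect_equal(sh$amplitude, 20 - sh$threshold, tolerance = 1e-6)
  base_width <- 2 * (20 - sh$threshold) / 80  # slope 80 mV/ms up and down
  expect_equal(sh$half_width, base_width / 2, tolerance = 0.02)
})

test_that("two-sigmoid upstroke yields two second-derivative peaks", {
  w <- two_sigmoid_upstroke()
  sh <- ap_shape(w)
  ## analytic maxima of d2V/dt2 of a logistic a/(1+exp(-(t-t0)/s)) sit at
  ## t0 - s * log(2 + sqrt(3)), with value a/s^2 * f''' max
  d2max <- function(a, s) {
    x <- log(2 + sqrt(3))   # location (in s units) of the inflection peak
    sig <- 1 / (1 + exp(x))
    a / s^2 * sig * (1 - sig) * (1 - 2 * sig)
  }
  expect_equal(sh$is_peak, abs(d2max(40, 0.15)), tolerance = 0.05)
  expect_equal(sh$sd_peak, abs(d2max(50, 0.25)), tolerance = 0.05)
  expect_equal(sh$sd_is_ratio, sh$sd_peak / sh$is_peak)
  ## doubling the waveform amplitude doubles both derivative peaks and the
  ## amplitude; the half-width barely moves (the 20 mV/ms threshold
  ## criterion itself is not scale-invariant, so exact equality is not
  ## expected)
  w2 <- w; w2$v <- (w$v + 65) * 2 - 65
  sh2 <- ap_shape(w2)
  expect_equal(sh2$is_peak / sh$is_peak, 2, tolerance = 0.01)
  expect_equal(sh2$sd_peak / sh$sd_peak, 2, tolerance = 0.01)
  expect_equal(sh2$amplitude / sh$amplitude, 2, tolerance = 0.02)
  expect_equal(sh2$half_width, sh$half_width, tolerance = 0.05)
})

test_that("metrics are invariant to time shifts", {
  w <- two_sigmoid_upstroke()
  pad <- rep(w$v[1], 200)
  w_shift <- list(v = c(pad, w$v), dt = w$dt,
                  t = (seq_len(length(w$v) + 200) - 1) * w$dt)
  sh <- ap_shape(w); shs <- ap_shape(w_shift)
  expect_equal(shs$threshold, sh$threshold, tolerance = 1e-9)
  expect_equal(shs$half_width, sh$half_width, tolerance = 1e-9)
  expect_equal(shs$is_peak, sh$is_peak, tolerance = 1e-9)
  tri <- triangle_ap()
  tri_shift <- list(v = c(rep(tri$v[1], 150), tri$v), dt = tri$dt)
  expect_equal(ap_shape(tri_shift)$half_width, ap_shape(tri)$half_width,
               tolerance = 1e-9)
})

test_that("experimental-style resampling changes smooth metrics < 2%", {
  w1 <- two_sigmoid_upstroke(dt = 0.01)
  w2 <- two_sigmoid_upstroke(dt = 0.02)   # 50 kHz acquisition
  s1 <- ap_shape(w1); s2 <- ap_shape(w2)
  expect_equal(s2$half_width / s1$half_width, 1, tolerance = 0.02)
  expect_equal(s2$is_peak / s1$is_peak, 1, tolerance = 0.02)
  expect_equal(s2$sd_peak / s1$sd_peak, 1, tolerance = 0.02)
})

test_that("firing summary: rate and regularity", {
  periodic <- seq(0, 10000, by = 1000)   # 11 spikes over 10 s
  fs <- firing_summary(periodic)
  expect_equal(fs$mean_rate, 1)
  expect_equal(fs$isi_cv, 0)
  expect_equal(fs$n_spikes, 11)
  expect_error(firing_summary(c(1, 2)), "at least 3")
  set.seed(9)
  pois <- cumsum(rexp(3000, rate = 1 / 100))
  expect_equal(firing_summary(pois)$isi_cv, 1, tolerance = 0.05)
})

test_that("initiation lead: zero for identical traces, delay recovered", {
  dt <- 0.02
  t <- seq(0, 2000, by = dt)
  v <- -55 + 50 * pmax(0, sin(2 * pi * t / 400))^30
  expect_equal(initiation_site(v, v, dt), rep(0, 5), tolerance = 1e-9)
  shift <- round(0.2 / dt)
  v_soma <- c(rep(v[1], shift), head(v, -shift))
  lead <- initiation_site(v, v_soma, dt)
  expect_equal(lead, rep(0.2, 5), tolerance = 0.01)
})
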