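## AP waveform analysis: spike detection, spike-triggered averaging,
## threshold at the 20 mV/ms crossing of dV/dt, amplitude and half-width,
## and the initial-segment (IS) / somatodendritic (SD) decomposition as the
## first and second local maxima of the second time derivative on the
## rising phase.

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a detection level with a refractory separation.
#'
#' @param v voltage trace, mV.
#' @param dt sample interval, ms.
#' @param level detection level, mV.
#' @param refractory minimum spike separation, ms.
#' @return spike times, ms (crossing times).
#' @export
detect_spikes <- function(v, dt, level = -20, refractory = 2) {
  stopifnot(all(is.finite(v)))
  up <- which(v[-1] >= level & v[-length(v)] < level)
  if (!length(up)) return(numeric(0))
  t <- up * dt   # time of the first sample at/above level
  keep <- c(TRUE, diff(t) > refractory)
  while (!all(keep)) {
    t <- t[keep]
    keep <- c(TRUE, diff(t) > refractory)
  }
  t
}

#' Spike-triggered average AP waveform
#'
#' Aligns spikes on the AP peak and averages them over a window. Windows
#' extending beyond the trace are dropped (with a warning) rather than
#' zero-padded.
#'
#' @param v voltage trace, mV.
#' @param dt sample interval, ms.
#' @param spike_times spike times from [detect_spikes()], ms.
#' @param window `c(before, after)` around the peak, ms.
#' @return list of class `ap_waveform`: `t` (ms, 0 at the peak), `v` (mV),
#'   `n` spikes averaged, `dt`.
#' @export
average_ap <- function(v, dt, spike_times, window = c(3, 6)) {
  if (!length(spike_times)) stop("no spikes to average")
  nb <- round(window[1] / dt); na <- round(window[2] / dt)
  peaks <- vapply(spike_times, function(ts) {
    i0 <- max(1, round(ts / dt))
    i1 <- min(length(v), i0 + round(5 / dt))
    i0 + which.max(v[i0:i1]) - 1L
  }, numeric(1))
  ok <- peaks - nb >= 1 & peaks + na <= length(v)
  if (!all(ok)) {
    warning(sum(!ok), " spike(s) trimmed: window exceeds trace bounds")
    peaks <- peaks[ok]
  }
  if (!length(peaks)) stop("no spike fits the averaging window")
  mat <- vapply(peaks, function(p) v[(p - nb):(p + na)],
                numeric(nb + na + 1))
  structure(list(t = seq(-nb, na) * dt, v = rowMeans(mat),
                 n = length(peaks), dt = dt), class = "ap_waveform")
}

## centered finite-difference derivative (forward/backward at ends)
fdiff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' AP threshold from the dV/dt criterion
#'
#' The threshold is the voltage at which dV/dt first crosses `slope`
#' (20 mV/ms) before the AP peak, with linear sub-sample interpolation of
#' the crossing.
#'
#' @param wf an `ap_waveform` (or list with `v`, `dt`).
#' @param slope threshold slope, mV/ms.
#' @return list: `threshold` (mV; `NA` if the slope is never reached),
#'   `t_threshold` (ms on the waveform time base), `i` (sample index).
#' @export
ap_threshold <- function(wf, slope = 20) {
  v <- wf$v; dt <- wf$dt
  ipk <- which.max(v)
  dv <- fdiff(v, dt)
  pre <- dv[1:ipk]
  cross <- which(pre[-1] >= slope & pre[-length(pre)] < slope)
  if (!length(cross))
    return(list(threshold = NA_real_, t_threshold = NA_real_,
                i = NA_integer_))
  i <- cross[1]   # crossing between samples i and i+1
  f <- (slope - dv[i]) / (dv[i + 1] - dv[i])
  thr <- v[i] + f * (v[i + 1] - v[i])
  tt <- if (!is.null(wf$t)) wf$t[i] + f * dt else (i - 1 + f) * dt
  list(threshold = thr, t_threshold = tt, i = i)
}

#' AP shape metrics
#'
#' Amplitude is threshold-to-peak (configurable to a fixed baseline);
#' half-width is the duration at 50% of that amplitude above threshold.
#' The IS and SD components are the amplitudes of the first and second
#' local maxima of d2V/dt2 between threshold and peak (finite differences,
#' optional moving-average smoothing of the second derivative).
#'
#' @param wf an `ap_waveform`.
#' @param slope threshold slope, mV/ms.
#' @param smooth odd moving-average width (samples) for d2V/dt2; 1 = none.
#' @param amplitude_ref `"threshold"` (default) or `"baseline"` (first
#'   sample of the window).
#' @return one-row data.frame of class `ap_metrics`: `threshold`,
#'   `amplitude` (mV), `half_width` (ms), `is_peak`, `sd_peak` (mV/ms^2),
#'   `sd_is_ratio`.
#' @export
ap_shape <- function(wf, slope = 20, smooth = 1L,
                     amplitude_ref = c("threshold", "baseline")) {
  amplitude_ref <- match.arg(amplitude_ref)
  v <- wf$v; dt <- wf$dt
  thr <- ap_threshold(wf, slope)
  if (is.na(thr$threshold)) stop("threshold undefined: dV/dt never reaches ",
                                 slope, " mV/ms")
  ipk <- which.max(v)
  ref <- if (amplitude_ref == "threshold") thr$threshold else v[1]
  amplitude <- v[ipk] - ref
  ## half-width at 50% amplitude above the reference
  half <- ref + amplitude / 2
  iup <- which(v[1:ipk] >= half)[1]
  f_up <- if (iup > 1) (half - v[iup - 1]) / (v[iup] - v[iup - 1]) else 0
  t_up <- (iup - 1 - 1 + f_up) * dt
  post <- v[ipk:length(v)]
  idn <- which(post <= half)[1]
  if (is.na(idn)) stop("waveform does not repolarize to half height")
  f_dn <- (v[ipk + idn - 2] - half) / (v[ipk + idn - 2] - v[ipk + idn - 1])
  t_dn <- (ipk + idn - 2 - 1 + f_dn) * dt
  half_width <- t_dn - t_up
  ## second derivative on the rising phase
  d2 <- fdiff(fdiff(v, dt), dt)
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    d2 <- stats::filter(d2, k, sides = 2)
    d2[is.na(d2)] <- 0
  }
  lo <- max(2L, thr$i); hi <- ipk
  seg <- d2[lo:hi]
  locmax <- which(diff(sign(diff(seg))) < 0) + 1L
  if (length(locmax) >= 1 && length(seg) >= 2) {
    ## boundary maxima count too (peak of d2 can sit at the segment edge)
    if (seg[1] > seg[2]) locmax <- union(1L, locmax)
    if (seg[length(seg)] > seg[length(seg) - 1])
      locmax <- union(locmax, length(seg))
  }
  ## IS/SD peaks are depolarizing accelerations: only positive maxima count
  locmax <- sort(locmax[seg[locmax] > 0])
  is_t <- sd_t <- NA_real_
  if (length(locmax) >= 2) {
    ## the two largest maxima, in time order: first = IS, second = SD
    top2 <- sort(locmax[order(seg[locmax], decreasing = TRUE)][1:2])
    is_peak <- seg[top2[1]]; sd_peak <- seg[top2[2]]
    is_t <- (lo + top2[1] - 2) * dt; sd_t <- (lo + top2[2] - 2) * dt
  } else if (length(locmax) == 1) {
    is_peak <- seg[locmax[1]]; sd_peak <- NA_real_
    is_t <- (lo + locmax[1] - 2) * dt
  } else {
    is_peak <- NA_real_; sd_peak <- NA_real_
  }
  out <- data.frame(threshold = thr$threshold, amplitude = amplitude,
                    half_width = half_width, is_peak = is_peak,
                    sd_peak = sd_peak,
                    sd_is_ratio = if (is.na(is_peak) || is.na(sd_peak))
                      NA_real_ else sd_peak / is_peak,
                    is_peak_t = is_t, sd_peak_t = sd_t)
  class(out) <- c("ap_metrics", class(out))
  out
}

#' Firing-rate and regularity summary
#'
#' @param spike_times spike times, ms (at least 3 spikes).
#' @return list of class `firing_summary`: `mean_rate` (Hz), `isi_cv`,
#'   `n_spikes`.
#' @export
firing_summary <- function(spike_times) {
  if (length(spike_times) < 3)
    stop("firing summary requires at least 3 spikes")
  isi <- diff(spike_times)
  structure(list(mean_rate = 1000 / mean(isi),
                 isi_cv = sd(isi) / mean(isi),
                 n_spikes = length(spike_times)),
            class = "firing_summary")
}

#' Per-spike AIS-vs-soma initiation lead
#'
#' Compares threshold-crossing times of matched spikes in an AIS and a
#' somatic trace on the same time base; positive lead = AIS first.
#'
#' @param v_ais,v_soma voltage traces, mV.
#' @param dt sample interval, ms.
#' @param level crossing level, mV (default -20).
#' @return numeric vector of per-spike lead times, ms.
#' @export
initiation_site <- function(v_ais, v_soma, dt, level = -20) {
  stopifnot(length(v_ais) == length(v_soma))
  cross_times <- function(v) {
    up <- which(v[-1] >= level & v[-length(v)] < level)
    f <- (level - v[up]) / (v[up + 1] - v[up])
    tt <- (up - 1 + f) * dt
    keep <- c(TRUE, diff(tt) > 2)
    tt[keep]
  }
  ta <- cross_times(v_ais); ts <- cross_times(v_soma)
  if (!length(ts)) stop("alignment error: no somatic spikes")
  if (!length(ta)) stop("alignment error: no AIS spikes")
  ## pair each somatic spike with the earliest AIS crossing in a short
  ## window around it: the initiating AIS spike precedes the somatic
  ## upstroke, and the AIS may fire again (re-excitation) as the somatic
  ## spike develops
  vapply(ts, function(t0) {
    cand <- ta[ta >= t0 - 5 & ta <= t0 + 1]
    if (!length(cand)) return(NA_real_)
    t0 - min(cand)
  }, numeric(1))
}
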