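## Stage-typed generator parameters. Means/SDs are per-stage population
## summaries of SNc DA neuron morphology and AP shape at postnatal days
## P3/P7/P14/P21; the somatic-axon probabilities are the printed per-stage
## fractions 2/10, 4/23, 1/13 and 4/38. Only mean and SD are tabulated with
## lower truncation at natural bounds (published ranges are widths, not
## endpoints). Primary-dendrite diameters are configuration defaults, not
## measured values.

STAGES <- c("P3", "P7", "P14", "P21")

.morph_params <- local({
  f <- function(...) c(...)
  ## field, then mean/sd per stage in P3,P7,P14,P21 order; lo = lower bound
  tab <- list(
    n_segments_abd     = list(m = f(6.88, 7.32, 13.33, 12.06),
                              s = f(5.06, 4.45, 7.24, 6.09),   lo = 1),
    n_segments_nabd    = list(m = f(27.90, 16.83, 12.15, 16.24),
                              s = f(18.49, 9.35, 5.38, 6.76),  lo = 1),
    n_primary_nabd     = list(m = f(3.70, 3.61, 3.15, 3.34),
                              s = f(1.34, 1.23, 0.99, 1.28),   lo = 1),
    len_abd            = list(m = f(259, 345, 1106, 1008),
                              s = f(175, 214, 656, 495),       lo = 20),
    len_nabd_total     = list(m = f(1090, 940, 1306, 1712),
                              s = f(505, 456, 327, 881),       lo = 50),
    axon_soma_distance = list(m = f(15.38, 19.73, 33.59, 33.25),
                              s = f(17.33, 18.47, 27.64, 27.54), lo = 1),
    axon_start_length  = list(m = f(3.20, 9.68, 14.72, 21.61),
                              s = f(2.73, 4.87, 6.54, 6.70),   lo = 0.3),
    ais_length         = list(m = f(25.85, 28.74, 28.31, 32.14),
                              s = f(7.98, 7.60, 8.58, 7.14),   lo = 5),
    soma_volume        = list(m = f(1103, 1328, 2845, 2489),
                              s = f(480, 448, 789, 846),       lo = 200))
  tab
})

.electro_params <- local({
  f <- function(...) c(...)
  list(
    ap_threshold  = list(m = f(-44.57, -44.59, -43.97, -44.68),
                         s = f(3.60, 3.92, 5.24, 3.53),  lo = -Inf),
    ap_amplitude  = list(m = f(51.47, 53.69, 58.70, 62.43),
                         s = f(4.71, 7.22, 7.33, 7.18),  lo = 10),
    ap_half_width = list(m = f(2.69, 2.34, 1.59, 1.30),
                         s = f(0.47, 0.51, 0.30, 0.19),  lo = 0.3),
    is_peak       = list(m = f(122.47, 123.06, 311.96, 178.28),
                         s = f(42.52, 33.54, 109.61, 54.72), lo = 10),
    sd_peak       = list(m = f(47.86, 78.27, 221.71, 204.94),
                         s = f(33.73, 68.73, 155.65, 105.09), lo = 5),
    sd_is_ratio   = list(m = f(0.44, 0.62, 0.73, 1.26),
                         s = f(0.32, 0.47, 0.48, 0.83),  lo = 0.02))
})

.p_somatic <- c(P3 = 2 / 10, P7 = 4 / 23, P14 = 1 / 13, P21 = 4 / 38)
.primary_diam <- c(P3 = 1.2, P7 = 1.5, P14 = 2.0, P21 = 2.0)

#' Default generator parameters for a developmental stage
#'
#' Returns the per-stage population parameters (mean, SD, lower bound) of the
#' morphometric and AP-shape fields, the somatic-axon probability, and the
#' geometry configuration used by [sample_neuron()].
#'
#' @param stage one of "P3", "P7", "P14", "P21".
#' @return list of class `stage_params` with elements `stage`, `morph` and
#'   `electro` (data.frames field/mean/sd/lo), `p_somatic_axon`,
#'   `primary_dendrite_diam`, `axon_diam`, `terminal_diam`,
#'   `axon_distal_length`.
#' @export
default_stage_params <- function(stage) {
  if (!stage %in% STAGES)
    stop("unknown stage '", stage, "'; must be one of ",
         paste(STAGES, collapse = ", "))
  k <- match(stage, STAGES)
  tab <- function(lst) {
    data.frame(field = names(lst),
               mean = vapply(lst, function(e) e$m[k], numeric(1)),
               sd = vapply(lst, function(e) e$s[k], numeric(1)),
               lo = vapply(lst, function(e) e$lo, numeric(1)),
               row.names = NULL)
  }
  structure(list(
    stage = stage,
    morph = tab(.morph_params),
    electro = tab(.electro_params),
    p_somatic_axon = unname(.p_somatic[stage]),
    primary_dendrite_diam = unname(.primary_diam[stage]),
    axon_diam = 0.7,
    terminal_diam = 0.5,
    axon_distal_length = 100), class = "stage_params")
}

#' Pooled somatic-axon fraction across stages
#'
#' Pools the per-stage somatic-axon counts (2/10, 4/23, 1/13, 4/38) into a
#' single fraction of neurons whose axon arises from the soma.
#'
#' @return fraction in `[0, 1]`.
#' @export
pooled_somatic_axon_fraction <- function() {
  counts <- c(2, 4, 1, 4)
  totals <- c(10, 23, 13, 38)
  sum(counts) / sum(totals)
}

## Mean-matched truncated normal: draws from a normal truncated below at `lo`
## whose location is solved so that the truncated mean equals `mean`.
rtnorm_mean <- function(n, mean, sd, lo = -Inf) {
  if (sd <= 0) return(rep(mean, n))
  if (!is.finite(lo) || (mean - lo) / sd > 6) return(rnorm(n, mean, sd))
  tmean <- function(mu) {
    a <- (lo - mu) / sd
    mu + sd * exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE,
                                               log.p = TRUE))
  }
  mu <- uniroot(function(mu) tmean(mu) - mean,
                lower = mean - 10 * sd, upper = mean + sd,
                extendInt = "upX", tol = 1e-10)$root
  p_lo <- pnorm(lo, mu, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mu, sd)
}
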