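## Sodium-conductance screening: sweep the somatodendritic gNa of a model
## neuron over a grid, measure the somatic AP half-width at each value, find
## by interpolation/extrapolation the gNa whose half-width best matches a
## target ("biological") half-width, and quantify half-width sensitivity as
## a CV over a fixed (threefold) gNa range. The mature (P21) screen varies
## gNa in the ABD only on the heterogeneous model (50-150 pS/um^2, step 10,
## gCa fixed at 2.2); the immature (P7) screen varies gNa in ABD and nABDs
## together on the homogeneous model (25-165 pS/um^2, step 10).

#' Default gNa grids (pS/um^2)
#'
#' @param variant `"model2"` (P21-style: 50-150 by 10) or `"model1"`
#'   (P7-style: 25-165 by 10).
#' @return numeric grid.
#' @export
default_gna_grid <- function(variant = c("model2", "model1")) {
  variant <- match.arg(variant)
  if (variant == "model2") seq(50, 150, by = 10) else seq(25, 165, by = 10)
}

#' Sweep gNa and measure AP half-width
#'
#' Runs one pacemaking simulation per grid value and measures the averaged
#' somatic AP half-width. Under `"model2"` only the ABD density is varied
#' (gCa fixed); under `"model1"` ABD and nABD densities move together.
#' Grid points where the model is silent (or no threshold is defined) get
#' `NA` half-width and are recorded.
#'
#' @param m a `neuron_morphology`.
#' @param variant `"model2"` or `"model1"`.
#' @param grid gNa grid, pS/um^2 (default [default_gna_grid()]).
#' @param config a `sim_config`.
#' @param scheme_overrides extra density overrides applied at every grid
#'   point.
#' @return object of class `sweep_result`: data.frame `gna`, `half_width`,
#'   plus `variant`.
#' @export
sweep_gna <- function(m, variant = c("model2", "model1"), grid = NULL,
                      config = sim_config(), scheme_overrides = list()) {
  variant <- match.arg(variant)
  if (is.null(grid)) grid <- default_gna_grid(variant)
  if (!length(grid)) stop("empty gNa grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  hw <- vapply(grid, function(g) {
    ov <- scheme_overrides
    ov$abd <- c(ov$abd, Na = unname(g))
    if (variant == "model1") ov$nabd <- c(ov$nabd, Na = unname(g))
    sch <- build_scheme(variant, overrides = ov)
    res <- run_protocol(m, sch, config)
    late <- res$spike_times[res$spike_times > config$steady_state_discard]
    if (length(late) < 3) return(NA_real_)
    wf <- average_ap(res$traces$v[, 1], res$traces$dt, late)
    sh <- try(ap_shape(wf), silent = TRUE)
    if (inherits(sh, "try-error")) NA_real_ else sh$half_width
  }, numeric(1))
  structure(list(table = data.frame(gna = grid, half_width = hw),
                 variant = variant), class = "sweep_result")
}

#' Optimal gNa for a target half-width
#'
#' Inverts the piecewise-linear half-width-vs-gNa relation at the target.
#' An exact grid hit returns that grid value; a target inside a bracketing
#' interval is linearly interpolated; a target outside the achieved
#' half-width range is linearly extrapolated from the two nearest grid
#' points. When more than one interval brackets the target (non-monotone
#' sweep) the bracket closest to the target in half-width is used, with a
#' warning.
#'
#' @param sweep a `sweep_result`.
#' @param target_half_width target (biological) half-width, ms.
#' @return list of class `screen_outcome`: `optimal_gna` (pS/um^2),
#'   `target_half_width`, `achieved_half_width` (interpolated at the
#'   optimum), `variant`.
#' @export
optimal_gna <- function(sweep, target_half_width) {
  tab <- sweep$table[!is.na(sweep$table$half_width), ]
  if (nrow(tab) < 2) stop("need at least 2 non-missing grid points")
  g <- tab$gna; h <- tab$half_width
  exact <- which(h == target_half_width)
  if (length(exact)) {
    gopt <- g[exact[1]]
  } else {
    brackets <- which((h[-nrow(tab)] - target_half_width) *
                        (h[-1] - target_half_width) < 0)
    if (length(brackets) >= 1) {
      if (length(brackets) > 1) {
        mid <- abs((h[brackets] + h[brackets + 1]) / 2 - target_half_width)
        warning("non-monotone sweep: ", length(brackets),
                " intervals bracket the target; using the closest")
        brackets <- brackets[which.min(mid)]
      }
      i <- brackets
      gopt <- g[i] + (target_half_width - h[i]) /
        (h[i + 1] - h[i]) * (g[i + 1] - g[i])
    } else {
      ## extrapolate from the two grid points nearest in half-width
      i <- if (abs(h[1] - target_half_width) < abs(h[length(h)] -
                                                     target_half_width))
        1L else length(h) - 1L
      gopt <- g[i] + (target_half_width - h[i]) /
        (h[i + 1] - h[i]) * (g[i + 1] - g[i])
    }
  }
  achieved <- approx(g, h, xout = gopt, rule = 2)$y
  structure(list(optimal_gna = gopt, target_half_width = target_half_width,
                 achieved_half_width = achieved, variant = sweep$variant),
            class = "screen_outcome")
}

#' Half-width coefficient of variation over a gNa range
#'
#' CV (percent) of the AP half-widths at the grid points falling inside
#' `[lo, hi]`; the sensitivity index of the screen (sample SD, n - 1
#' convention). The comparison ranges are 50-150 pS/um^2 for the mature
#' screen and 55-165 pS/um^2 for the immature screen - a threefold range in
#' both cases.
#'
#' @param sweep a `sweep_result`.
#' @param range `c(lo, hi)` in pS/um^2.
#' @return CV in percent.
#' @export
halfwidth_cv <- function(sweep, range) {
  tab <- sweep$table
  sel <- tab$gna >= range[1] & tab$gna <= range[2] & !is.na(tab$half_width)
  if (sum(sel) < 3)
    stop("fewer than 3 usable grid points inside the CV range")
  h <- tab$half_width[sel]
  100 * sd(h) / mean(h)
}
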