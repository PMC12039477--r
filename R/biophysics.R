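## Channel complement and conductance schemes.
##
## The model carries seven membrane mechanisms: fast sodium (Na) and
## delayed-rectifier potassium (KDR) following the Migliore / Schild model
## lineage, an A-type potassium current (A) with a somatic kinetic variant
## (higher density, depolarized and slower inactivation in the soma), an
## L-type calcium current (CaL), a small-conductance calcium-activated
## potassium current (KCa/SK, activated solely by calcium), an H current, and
## leak. Rate equations are not published for this cell-type model as a
## closed set, so the default kinetics below are a reconstructed
## Boltzmann/bell-tau parameterization of that lineage, tuned to the model's
## qualitative constraints (spontaneous regular pacemaking, AIS-first
## initiation, broad AP); they are data, not transcription.

CHANNEL_NAMES <- c("Na", "KDR", "A", "Asoma", "CaL", "KCa", "H", "leak")

v_gate <- function(expo, vhalf, k, tau_base, tau_amp, tau_vmax,
                   tau_sig1, tau_sig2 = tau_sig1) {
  list(type = "voltage", expo = expo, vhalf = vhalf, k = k,
       tau_base = tau_base, tau_amp = tau_amp, tau_vmax = tau_vmax,
       tau_sig1 = tau_sig1, tau_sig2 = tau_sig2)
}

ca_gate <- function(expo, kd, hill, tau) {
  list(type = "calcium", expo = expo, kd = kd, hill = hill, tau = tau)
}

#' Default channel specifications
#'
#' Returns the channel set of the multicompartment model. `Asoma` is the
#' somatic kinetic variant of the A current (inactivation depolarized and
#' slower than in the dendrites); the density map decides where each variant
#' applies. Steady states are Boltzmann functions of voltage (of calcium for
#' KCa), time constants are bell-shaped in voltage. Reversal potentials
#' (mV): Na +60, K -90, Ca +60 (fixed, no GHK flux), H -35, leak -50.
#'
#' @return named list of the seven channel specs (fields `name`, `erev`,
#'   `ca_source`, `act`, `inact`); the somatic A variant is applied through
#'   the density map (see [assign_densities()]).
#' @export
default_channels <- function() {
  ch <- sim_channels()
  ch[setdiff(names(ch), "Asoma")]
}

## full channel set used by the simulator: the A current appears twice, as
## the dendritic kinetics (A) and the somatic variant (Asoma)
sim_channels <- function() {
  list(
    Na = list(name = "Na", erev = 60, ca_source = FALSE,
              act = v_gate(3, -34, 6.5, 0.03, 0.25, -38, 14),
              inact = v_gate(1, -50, -6.5, 0.35, 7, -58, 13)),
    KDR = list(name = "KDR", erev = -90, ca_source = FALSE,
               act = v_gate(3, -20, 9, 0.8, 4.5, -30, 22),
               inact = NULL),
    A = list(name = "A", erev = -90, ca_source = FALSE,
             act = v_gate(1, -28, 5, 0.4, 1.2, -50, 16),
             inact = v_gate(1, -73, -7, 6, 20, -70, 16)),
    Asoma = list(name = "Asoma", erev = -90, ca_source = FALSE,
                 act = v_gate(1, -28, 5, 0.4, 1.2, -50, 16),
                 inact = v_gate(1, -63, -7, 15, 40, -60, 16)),
    CaL = list(name = "CaL", erev = 60, ca_source = TRUE,
               act = v_gate(2, -35, 5, 0.4, 1.6, -45, 13),
               inact = NULL),
    KCa = list(name = "KCa", erev = -90, ca_source = FALSE,
               act = ca_gate(1, kd = 3.5e-4, hill = 4, tau = 5),
               inact = NULL),
    H = list(name = "H", erev = -35, ca_source = FALSE,
             act = v_gate(1, -85, -9, 100, 200, -85, 20),
             inact = NULL),
    leak = list(name = "leak", erev = -50, ca_source = FALSE,
                act = NULL, inact = NULL))
}

REGIONS <- c("soma", "abd", "nabd", "axon_start", "ais", "axon")

## default densities in pS/um^2 (1 pS/um^2 = 1e-4 S/cm^2); leak corresponds
## to Rm = 100,000 Ohm.cm^2 (1e-5 S/cm^2 = 0.1 pS/um^2)
.base_densities <- function() {
  d <- matrix(0, nrow = length(REGIONS), ncol = length(CHANNEL_NAMES),
              dimnames = list(REGIONS, CHANNEL_NAMES))
  leak <- 0.1
  #              Na  KDR    A Asoma CaL KCa    H  leak
  d["soma", ]       <- c(120, 100,   0,   6, 2.2, 3, 1.0, leak)
  d["abd", ]        <- c(120, 100,   2,   0, 2.2, 3, 1.0, leak)
  d["nabd", ]       <- c( 50, 100,   2,   0, 1.0, 3, 1.0, leak)
  d["axon_start", ] <- c( 50, 100,   2,   0, 1.0, 3, 1.0, leak)
  d["ais", ]        <- c(  0,   0,   0,   0,   0, 0,   0, leak)
  d["axon", ]       <- c(  0,   0,   0,   0,   0, 0,   0, leak)
  d
}

#' Build a conductance-density scheme
#'
#' Two variants are supported. Model 2 (heterogeneous) enriches the
#' axon-bearing dendrite: gNa 120 vs 50 pS/um^2 and gCa 2.2 vs 1 pS/um^2 in
#' ABD vs nABDs. Model 1 (homogeneous) uses identical ABD and nABD
#' densities (default gNa 50, gCa 1 pS/um^2). AIS sodium/potassium densities
#' are multiples of the highest somatodendritic density (default 15x Na,
#' 4x KDR), keeping AP initiation in the AIS; the distal axon carries Na/KDR
#' at lower density. All compartments keep the global leak
#' (Rm = 100,000 Ohm.cm^2, E = -50 mV); AIS and axon carry only Na, KDR and
#' leak.
#'
#' @param variant `"model2"` (heterogeneous, default for P21) or `"model1"`
#'   (homogeneous, default for P7).
#' @param overrides named list `region = c(channel = density)` of density
#'   overrides in pS/um^2, applied after variant defaults.
#' @param ais_na_multiplier,ais_kdr_multiplier AIS densities as multiples of
#'   the maximum somatodendritic Na/KDR density.
#' @return object of class `conductance_scheme` (fields `variant`,
#'   `densities` in pS/um^2, multipliers).
#' @export
build_scheme <- function(variant = c("model2", "model1"), overrides = list(),
                         ais_na_multiplier = 15, ais_kdr_multiplier = 4) {
  variant <- match.arg(variant)
  d <- .base_densities()
  if (variant == "model1") {
    d["abd", c("Na", "CaL")] <- c(50, 1.0)
    d["nabd", c("Na", "CaL")] <- c(50, 1.0)
  }
  for (region in names(overrides)) {
    if (!region %in% REGIONS) stop("unknown region '", region, "'")
    ov <- overrides[[region]]
    if (any(!names(ov) %in% CHANNEL_NAMES))
      stop("unknown channel in overrides for region '", region, "'")
    if (any(ov < 0)) stop("conductance densities must be non-negative")
    d[region, names(ov)] <- ov
  }
  if (variant == "model2" && d["abd", "Na"] < d["nabd", "Na"])
    warning("Model 2 with ABD gNa below nABD gNa inverts the ",
            "ABD-enrichment premise")
  sd_na <- max(d[c("soma", "abd", "nabd", "axon_start"), "Na"])
  sd_kdr <- max(d[c("soma", "abd", "nabd", "axon_start"), "KDR"])
  if (!"ais" %in% names(overrides) || !"Na" %in% names(overrides$ais))
    d["ais", "Na"] <- ais_na_multiplier * sd_na
  if (!"ais" %in% names(overrides) || !"KDR" %in% names(overrides$ais))
    d["ais", "KDR"] <- ais_kdr_multiplier * sd_kdr
  if (!"axon" %in% names(overrides) || !"Na" %in% names(overrides$axon))
    d["axon", "Na"] <- 3 * sd_na
  if (!"axon" %in% names(overrides) || !"KDR" %in% names(overrides$axon))
    d["axon", "KDR"] <- 1.5 * sd_kdr
  if (d["ais", "Na"] <= sd_na)
    stop("AIS gNa density must exceed all somatodendritic gNa")
  structure(list(variant = variant, densities = d,
                 ais_na_multiplier = ais_na_multiplier,
                 ais_kdr_multiplier = ais_kdr_multiplier),
            class = "conductance_scheme")
}

#' @export
print.conductance_scheme <- function(x, ...) {
  cat("<conductance_scheme>", x$variant, "\n")
  print(round(x$densities, 2))
  invisible(x)
}

#' Convert a density in pS/um^2 to S/cm^2
#' @param pS_per_um2 density in pS/um^2.
#' @return density in S/cm^2.
#' @export
density_to_si <- function(pS_per_um2) pS_per_um2 * 1e-4

#' Per-compartment channel density table
#'
#' Assigns region densities from a scheme to the compartments of a
#' discretized morphology. All somatodendritic regions (soma, ABD, nABD,
#' axon start) carry the full channel set; AIS and distal axon carry only
#' Na, KDR and leak. The somatic A-current variant applies in the soma only.
#'
#' @param grid a `compartment_grid` from [discretize()].
#' @param scheme a `conductance_scheme`.
#' @return matrix compartments x channels of densities (pS/um^2).
#' @export
assign_densities <- function(grid, scheme) {
  stopifnot(inherits(grid, "compartment_grid"),
            inherits(scheme, "conductance_scheme"))
  reg <- grid$compartments$region
  if (any(!reg %in% REGIONS))
    stop("unlabelled compartment region: ",
         paste(setdiff(unique(reg), REGIONS), collapse = ", "))
  scheme$densities[reg, , drop = FALSE]
}

#' Serialize / deserialize a conductance scheme as JSON
#' @param scheme a `conductance_scheme`.
#' @param path file path.
#' @return `read_scheme` returns the `conductance_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(
    list(variant = scheme$variant,
         ais_na_multiplier = scheme$ais_na_multiplier,
         ais_kdr_multiplier = scheme$ais_kdr_multiplier,
         densities = as.data.frame(scheme$densities)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.matrix(x$densities)
  rownames(d) <- REGIONS
  structure(list(variant = x$variant, densities = d,
                 ais_na_multiplier = x$ais_na_multiplier,
                 ais_kdr_multiplier = x$ais_kdr_multiplier),
            class = "conductance_scheme")
}

## steady-state / tau evaluation used by tests and the R-side ODE oracle
gate_inf <- function(gate, v, ca = NULL) {
  if (gate$type == "calcium") {
    r <- (ca / gate$kd)^gate$hill
    r / (1 + r)
  } else {
    1 / (1 + exp(-(v - gate$vhalf) / gate$k))
  }
}

gate_tau <- function(gate, v) {
  if (gate$type == "calcium") return(rep(gate$tau, length(v)))
  pmax(1e-4, gate$tau_base + gate$tau_amp /
         (exp((v - gate$tau_vmax) / gate$tau_sig1) +
            exp(-(v - gate$tau_vmax) / gate$tau_sig2)))
}
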