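#' Simulation configuration
#'
#' Passive constants and protocol of the multicompartment model: axial
#' resistivity 150 Ohm.cm, specific capacitance 0.75 uF/cm^2, specific
#' membrane resistance 100,000 Ohm.cm^2 (leak reversal -50 mV); runs start
#' from -70 mV and last 6,000 ms at dt = 0.01 ms, and spike analysis uses
#' only the window after `steady_state_discard` (pacemaking must reach steady
#' state first).
#'
#' @param dt time step, ms.
#' @param duration total simulated time, ms.
#' @param v_init initial potential, mV.
#' @param Ra axial resistivity, Ohm.cm.
#' @param Cm specific capacitance, uF/cm^2.
#' @param Rm specific membrane resistance, Ohm.cm^2 (sets the leak density).
#' @param leak_reversal leak reversal potential, mV.
#' @param steady_state_discard initial window excluded from analysis, ms.
#' @param method voltage update: `"be"` backward Euler (L-stable, robust
#'   default at protocol time steps) or `"cn"` staggered Crank-Nicolson
#'   (second order; preferred for fine-step solver verification).
#' @param record_every store every k-th sample.
#' @param comp_rule maximum compartment length, um.
#' @param ca_rest,ca_tau,ca_influx_scale calcium pool: resting concentration
#'   (mM), decay time constant (ms), influx scaling (dimensionless).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 6000, v_init = -70,
                       Ra = 150, Cm = 0.75, Rm = 1e5, leak_reversal = -50,
                       steady_state_discard = 2000,
                       method = c("be", "cn"), record_every = 1L,
                       comp_rule = 10, ca_rest = 5e-5, ca_tau = 150,
                       ca_influx_scale = 0.15) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > steady_state_discard,
            steady_state_discard >= 0)
  structure(list(dt = dt, duration = duration, v_init = v_init, Ra = Ra,
                 Cm = Cm, Rm = Rm, leak_reversal = leak_reversal,
                 steady_state_discard = steady_state_discard,
                 method = method, record_every = as.integer(record_every),
                 comp_rule = comp_rule, ca_rest = ca_rest, ca_tau = ca_tau,
                 ca_influx_scale = ca_influx_scale),
            class = "sim_config")
}

#' Discretize a morphology into a compartment grid
#'
#' Splits every section into compartments no longer than `rule` (frustum
#' areas and axial resistances follow the tapered diameters) and represents
#' the soma by its volume-equivalent cylinder. Compartments are Hines-ordered
#' (each parent precedes its children) for the tree solver.
#'
#' @param m a `neuron_morphology`.
#' @param rule maximum compartment length, um.
#' @param Ra axial resistivity, Ohm.cm.
#' @param Cm specific capacitance, uF/cm^2.
#' @return object of class `compartment_grid`: `compartments` data.frame
#'   (section, region, arc positions, area um^2, volume um^3, capacitance
#'   nF, axial conductance to parent uS, parent index).
#' @export
discretize <- function(m, rule = 10, Ra = 150, Cm = 0.75) {
  stopifnot(rule > 0)
  s <- m$sections
  abd_root <- if (is.null(m$axon_origin)) NA_integer_ else identify_abd(m)
  abd_ids <- if (is.na(abd_root)) integer(0) else dendrite_subtree(s, abd_root)
  region_of <- function(row) {
    switch(row$label,
           soma = "soma",
           dendrite = if (row$id %in% abd_ids) "abd" else "nabd",
           row$label)
  }
  comp <- list(); n <- 0L
  ## last compartment index of each section (children attach there)
  tail_of <- integer(0)
  emitted <- character(0)
  order_ids <- s$id[order(is.na(s$parent), decreasing = TRUE)]
  ## BFS order so parents are emitted first
  queue <- s$id[is.na(s$parent)]
  seq_ids <- integer(0)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    seq_ids <- c(seq_ids, cur)
    queue <- c(queue, s$id[!is.na(s$parent) & s$parent == cur])
  }
  for (sid in seq_ids) {
    row <- s[s$id == sid, ]
    if (row$label == "soma") {
      ## the soma enters the model as its volume-equivalent cylinder
      ec <- equivalent_cylinder(m$soma_volume)
      row$length <- ec$length
      row$diam_prox <- row$diam_dist <- ec$diameter
    }
    nseg <- max(1L, as.integer(ceiling(row$length / rule)))
    dbound <- row$diam_prox +
      (row$diam_dist - row$diam_prox) * (0:nseg) / nseg
    lseg <- row$length / nseg
    parent_comp <- if (is.na(row$parent)) 0L else tail_of[[as.character(row$parent)]]
    for (k in seq_len(nseg)) {
      d1 <- dbound[k]; d2 <- dbound[k + 1]
      slant <- sqrt(lseg^2 + ((d1 - d2) / 2)^2)
      area <- pi * (d1 + d2) / 2 * slant
      vol <- pi * lseg / 12 * (d1^2 + d1 * d2 + d2^2)
      r_axial <- 4 * Ra * (lseg * 1e-4) / (pi * (d1 * 1e-4) * (d2 * 1e-4))
      n <- n + 1L
      comp[[n]] <- data.frame(
        idx = n, section = sid, region = region_of(row),
        arc0 = (k - 1) * lseg, arc1 = k * lseg,
        length = lseg, area = area, volume = vol,
        r_half = r_axial / 2,         # Ohm, half-compartment resistance
        parent = parent_comp)
      parent_comp <- n
    }
    tail_of[[as.character(sid)]] <- n
  }
  cp <- do.call(rbind, comp)
  cp$c_nF <- cp$area * Cm * 1e-5
  ## axial conductance to parent through the two half-resistances (uS)
  g_ax <- numeric(n)
  for (i in seq_len(n)) {
    p <- cp$parent[i]
    if (p == 0) next
    g_ax[i] <- 1e6 / (cp$r_half[i] + cp$r_half[p])
  }
  cp$g_axial_uS <- g_ax
  structure(list(compartments = cp, rule = rule, Ra = Ra, Cm = Cm),
            class = "compartment_grid")
}

#' @export
print.compartment_grid <- function(x, ...) {
  cp <- x$compartments
  cat("<compartment_grid>", nrow(cp), "compartments;",
      sprintf("total area %.0f um^2\n", sum(cp$area)))
  print(table(cp$region))
  invisible(x)
}

#' Locate the compartment at a (section, arc position) site
#'
#' @param grid a `compartment_grid`.
#' @param section section id, or one of the shorthand labels `"soma"`,
#'   `"ais"` (mid-AIS), `"axon_start"`, `"dendrite"` (first dendrite).
#' @param pos arc position within the section, um (default: midpoint).
#' @return compartment index.
#' @export
site_index <- function(grid, section, pos = NULL) {
  cp <- grid$compartments
  if (is.character(section)) {
    cand <- cp[cp$region == section | (section == "dendrite" &
                                         cp$region %in% c("abd", "nabd")), ]
    if (!nrow(cand)) stop("no compartment in region '", section, "'")
    return(cand$idx[ceiling(nrow(cand) / 2)])
  }
  cand <- cp[cp$section == section, ]
  if (!nrow(cand)) stop("no compartments for section ", section)
  if (is.null(pos)) return(cand$idx[ceiling(nrow(cand) / 2)])
  hit <- cand[cand$arc0 <= pos & pos <= cand$arc1, ]
  if (!nrow(hit)) stop("arc position ", pos, " outside section ", section)
  hit$idx[1]
}

#' Integrate the branched cable equation
#'
#' Solves, per compartment, C dV/dt = -sum_i g_i (V - E_i) - I_axial with
#' Hodgkin-Huxley gating, an implicit (unconditionally stable) voltage
#' update on the branched tree, Rush-Larsen gate updates and a
#' single-exponential calcium pool.
#'
#' @param grid a `compartment_grid`.
#' @param densities compartments x channels density matrix (pS/um^2), e.g.
#'   from [assign_densities()]; its leak column is overridden by `1/Rm`.
#' @param config a `sim_config`.
#' @param record_sites integer compartment indices to record (default soma).
#' @param stimuli optional list of current steps
#'   `list(comp =, amp_nA =, t0 =, t1 =)` (test instrumentation; the standard
#'   protocol is unstimulated).
#' @param channels channel specs (default [sim_channels()] internal set).
#' @param record_ca also record calcium at the sites.
#' @return list of class `trace_set`: `time` (ms), `v` matrix (samples x
#'   sites, mV), optional `ca`, plus the configuration.
#' @export
integrate_grid <- function(grid, densities, config = sim_config(),
                           record_sites = NULL, stimuli = NULL,
                           channels = NULL, record_ca = FALSE) {
  cp <- grid$compartments
  if (is.null(channels)) channels <- sim_channels()
  if (is.null(record_sites)) record_sites <- site_index(grid, "soma")
  stopifnot(nrow(densities) == nrow(cp),
            ncol(densities) == length(channels))
  ## leak density from Rm (S/cm^2 -> pS/um^2: x 1e4)
  if ("leak" %in% colnames(densities))
    densities[, "leak"] <- 1 / config$Rm * 1e4
  ## absolute conductances: pS/um^2 * um^2 = pS -> uS (x 1e-6)
  g_uS <- densities * cp$area * 1e-6
  cfg <- list(dt = config$dt, duration = config$duration,
              v_init = config$v_init, leak_reversal = config$leak_reversal,
              ca_rest = config$ca_rest, ca_tau = config$ca_tau,
              ca_influx_scale = config$ca_influx_scale,
              method = config$method,
              record_idx = as.integer(record_sites - 1L),
              record_every = config$record_every,
              record_ca = record_ca)
  if (!is.null(stimuli)) {
    cfg$stimuli <- lapply(stimuli, function(st)
      list(comp = as.integer(st$comp - 1L), amp_nA = st$amp_nA,
           t0 = st$t0, t1 = st$t1))
  }
  out <- .cable_integrate(as.integer(cp$parent - 1L), cp$c_nF,
                          cp$g_axial_uS, g_uS, unname(channels),
                          cp$volume, cfg)
  res <- list(time = seq(0, config$duration, by = out$dt),
              v = out$v, sites = record_sites, dt = out$dt,
              config = config)
  if (record_ca) res$ca <- out$ca
  structure(res, class = "trace_set")
}

#' Run the default unstimulated pacemaking protocol
#'
#' Discretizes the morphology, assigns the scheme densities, runs the
#' unstimulated protocol from -70 mV, and returns traces at the soma, the
#' AIS midpoint and a dendritic site, together with the firing summary of
#' the post-discard somatic spike train.
#'
#' @param m a `neuron_morphology`.
#' @param scheme a `conductance_scheme` (or variant string).
#' @param config a `sim_config`.
#' @return list: `traces` (`trace_set` with sites soma/ais/dendrite),
#'   `firing` ([firing_summary()] of the steady-state window; `n_spikes = 0`
#'   reported as silent), `spike_times` (ms, full run), `grid`.
#' @export
run_protocol <- function(m, scheme = build_scheme("model2"),
                         config = sim_config()) {
  if (is.character(scheme)) scheme <- build_scheme(scheme)
  grid <- discretize(m, rule = config$comp_rule, Ra = config$Ra,
                     Cm = config$Cm)
  dens <- assign_densities(grid, scheme)
  sites <- c(soma = site_index(grid, "soma"),
             ais = site_index(grid, "ais"),
             dendrite = site_index(grid, "dendrite"))
  tr <- integrate_grid(grid, dens, config, record_sites = sites)
  vsoma <- tr$v[, 1]
  spikes <- detect_spikes(vsoma, tr$dt)
  late <- spikes[spikes > config$steady_state_discard]
  firing <- if (length(late) >= 3) firing_summary(late) else
    list(mean_rate = if (length(late)) length(late) /
           ((config$duration - config$steady_state_discard) / 1000) else 0,
         isi_cv = NA_real_, n_spikes = length(late), silent = TRUE)
  list(traces = tr, firing = firing, spike_times = spikes, grid = grid)
}
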