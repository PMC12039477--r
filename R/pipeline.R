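## End-to-end pipeline stages. Each stage writes its outputs plus a
## `run_config.json` with the resolved configuration and seed, so any run
## can be reproduced from its output directory alone.

write_run_config <- function(out_dir, config) {
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Generate a synthetic population and write SWC files plus a summary CSV
#'
#' @param stage developmental stage.
#' @param n number of neurons.
#' @param seed integer seed.
#' @param out_dir output directory (created if missing).
#' @param write_swc also write per-neuron SWC files.
#' @return the morphometry summary table, invisibly; files written:
#'   `neuron_###.swc` (+ side-cars), `morphometry.csv`, `run_config.json`.
#' @export
pipeline_synth <- function(stage, n, seed, out_dir, write_swc = TRUE) {
  if (n < 1) stop("usage error: n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- sample_population(default_stage_params(stage), n, seed = seed)
  tab <- summarize_population(pop)
  tab <- cbind(neuron = sprintf("neuron_%03d", seq_len(n)), tab)
  if (write_swc)
    for (i in seq_len(n))
      save_morphology(pop[[i]],
                      file.path(out_dir, sprintf("neuron_%03d.swc", i)))
  write.csv(tab, file.path(out_dir, "morphometry.csv"), row.names = FALSE)
  write_run_config(out_dir, list(stage = stage, n = n, seed = seed,
                                 command = "synth"))
  invisible(tab)
}

#' Simulate one morphology and write traces and AP metrics
#'
#' @param m a `neuron_morphology` or path to an SWC file.
#' @param variant conductance scheme variant (or a `conductance_scheme`).
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @return list with `firing` and `ap_metrics`, invisibly; files written:
#'   `trace_soma.csv` (time, soma, AIS, dendrite voltages),
#'   `ap_metrics.csv`, `firing.json`, `run_config.json`.
#' @export
pipeline_simulate <- function(m, variant = "model2", config = sim_config(),
                              out_dir) {
  if (is.character(m)) m <- load_morphology(m)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_protocol(m, variant, config)
  tr <- res$traces
  write.csv(data.frame(time_ms = tr$time, soma_mV = tr$v[, 1],
                       ais_mV = tr$v[, 2], dendrite_mV = tr$v[, 3]),
            file.path(out_dir, "trace_soma.csv"), row.names = FALSE)
  metrics <- NULL
  late <- res$spike_times[res$spike_times > config$steady_state_discard]
  if (length(late) >= 1) {
    wf <- average_ap(tr$v[, 1], tr$dt, late)
    metrics <- try(ap_shape(wf), silent = TRUE)
    if (inherits(metrics, "try-error")) metrics <- NULL
  }
  if (!is.null(metrics))
    write.csv(metrics, file.path(out_dir, "ap_metrics.csv"),
              row.names = FALSE)
  jsonlite::write_json(res$firing, file.path(out_dir, "firing.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_run_config(out_dir, list(
    command = "simulate",
    variant = if (is.character(variant)) variant else variant$variant,
    dt = config$dt, duration = config$duration, v_init = config$v_init,
    steady_state_discard = config$steady_state_discard))
  invisible(list(firing = res$firing, ap_metrics = metrics))
}

#' Screen gNa over a population and write per-neuron outcomes
#'
#' @param pop list of `neuron_morphology` (or a directory of SWC files).
#' @param variant `"model2"` or `"model1"`.
#' @param targets per-neuron target half-widths, ms.
#' @param grid gNa grid (default per variant).
#' @param cv_range range for [halfwidth_cv()] (defaults: 50-150 for
#'   model2, 55-165 for model1).
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @param seed seed recorded in the config.
#' @return data.frame of per-neuron `optimal_gna`, `achieved_half_width`,
#'   `cv_percent`, written to `screen.csv`; sweep curves in `sweeps.csv`.
#' @export
pipeline_screen <- function(pop, variant, targets, grid = NULL,
                            cv_range = NULL, config = sim_config(),
                            out_dir, seed = NULL) {
  if (is.character(pop)) {
    files <- list.files(pop, pattern = "\\.swc$", full.names = TRUE)
    pop <- lapply(files, load_morphology)
  }
  if (!length(pop)) stop("usage error: empty population")
  stopifnot(length(targets) == length(pop))
  if (is.null(cv_range))
    cv_range <- if (variant == "model2") c(50, 150) else c(55, 165)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); curves <- list()
  for (i in seq_along(pop)) {
    sw <- sweep_gna(pop[[i]], variant, grid = grid, config = config)
    oc <- optimal_gna(sw, targets[i])
    cv <- tryCatch(halfwidth_cv(sw, cv_range), error = function(e) NA_real_)
    rows[[i]] <- data.frame(neuron = i, optimal_gna = oc$optimal_gna,
                            target_half_width = targets[i],
                            achieved_half_width = oc$achieved_half_width,
                            cv_percent = cv)
    curves[[i]] <- cbind(neuron = i, sw$table)
  }
  out <- do.call(rbind, rows)
  write.csv(out, file.path(out_dir, "screen.csv"), row.names = FALSE)
  write.csv(do.call(rbind, curves), file.path(out_dir, "sweeps.csv"),
            row.names = FALSE)
  write_run_config(out_dir, list(command = "screen", variant = variant,
                                 seed = seed, cv_range = cv_range,
                                 n_neurons = length(pop)))
  invisible(out)
}

#' Run the full statistics battery on a feature table and write reports
#'
#' @param table feature table (data.frame with `stage`) or path to a CSV.
#' @param out_dir output directory.
#' @param seed seed recorded in the config.
#' @return list with the stacking grid, AHC and LDA results, invisibly;
#'   files: `stacking.csv`, `stacking.json`, `comparisons.csv`,
#'   `ahc_classes.csv`, `lda_scores.csv`, `run_config.json`.
#' @export
pipeline_stats <- function(table, out_dir, seed = NULL) {
  if (is.character(table)) table <- read.csv(table)
  if (!"stage" %in% names(table))
    stop("vocabulary error: feature table must have a 'stage' column")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- intersect(CLUSTER_PARAMS, names(table))
  if (!length(params))
    stop("vocabulary error: no known parameter columns in the table")
  grid <- stacking_matrix(table, params)
  write.csv(as.data.frame(grid), file.path(out_dir, "stacking.csv"))
  jsonlite::write_json(list(bands = as.data.frame(grid)),
                       file.path(out_dir, "stacking.json"),
                       auto_unbox = TRUE, force = TRUE)
  comps <- do.call(rbind, lapply(params, function(p) {
    cr <- try(compare_stages(table, p), silent = TRUE)
    if (inherits(cr, "try-error")) return(NULL)
    cbind(parameter = p, test = cr$test, cr$pairs)
  }))
  write.csv(comps, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  cl <- try(ahc(table, params), silent = TRUE)
  if (!inherits(cl, "try-error"))
    write.csv(data.frame(row = cl$rows, class = cl$classes,
                         stage = table$stage[cl$rows]),
              file.path(out_dir, "ahc_classes.csv"), row.names = FALSE)
  ld <- try(lda_stages(table, intersect(LDA_PARAMS, names(table))),
            silent = TRUE)
  if (!inherits(ld, "try-error"))
    write.csv(data.frame(stage = ld$stage, ld$scores),
              file.path(out_dir, "lda_scores.csv"), row.names = FALSE)
  write_run_config(out_dir, list(command = "stats", seed = seed,
                                 parameters = params))
  invisible(list(stacking = grid,
                 ahc = if (inherits(cl, "try-error")) NULL else cl,
                 lda = if (inherits(ld, "try-error")) NULL else ld))
}
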