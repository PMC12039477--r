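## Synthetic stage-typed morphologies. The generator draws the per-neuron
## summary fields from mean-matched truncated normals, builds a random binary
## dendritic tree realizing the drawn segment counts, partitions the drawn
## lengths over segments (length shares proportional to per-dendrite segment
## counts, so length and complexity co-vary), and places the axon either on
## the soma (with the stage's somatic-axon probability) or on one dendrite at
## the drawn axon-soma distance.

#' Sample one synthetic neuron morphology
#'
#' @param params a `stage_params` object from [default_stage_params()].
#' @param max_retries bound on internal resampling of infeasible draw
#'   combinations (axon-soma distance beyond the ABD).
#' @return a `neuron_morphology` with the stage recorded as an attribute.
#' @export
sample_neuron <- function(params, max_retries = 50L) {
  stopifnot(inherits(params, "stage_params"))
  p <- params$morph
  draw <- function(field, n = 1) {
    r <- p[p$field == field, ]
    rtnorm_mean(n, r$mean, r$sd, r$lo)
  }
  somatic <- runif(1) < params$p_somatic_axon
  n_nabd <- max(1L, as.integer(round(draw("n_primary_nabd"))))
  seg_nabd <- as.integer(round(draw("n_segments_nabd")))
  seg_nabd <- max(seg_nabd, n_nabd)
  ## per-dendrite counts must be odd (binary trees); the total of n_nabd odd
  ## numbers has the parity of n_nabd
  if ((seg_nabd - n_nabd) %% 2L != 0L)
    seg_nabd <- seg_nabd + sample(c(-1L, 1L), 1)
  seg_nabd <- max(seg_nabd, n_nabd)
  if ((seg_nabd - n_nabd) %% 2L != 0L) seg_nabd <- seg_nabd + 1L
  len_nabd <- draw("len_nabd_total")
  soma_volume <- draw("soma_volume")
  axon_start_len <- draw("axon_start_length")
  ais_len <- draw("ais_length")

  ## distribute nABD segments (each odd, >= 1) and lengths (shares ~ counts)
  counts <- rep(1L, n_nabd)
  extra_pairs <- (seg_nabd - n_nabd) %/% 2L
  if (extra_pairs > 0) {
    who <- sample.int(n_nabd, extra_pairs, replace = TRUE)
    for (w in who) counts[w] <- counts[w] + 2L
  }
  g <- rgamma(n_nabd, shape = counts, rate = 1)
  lens <- len_nabd * g / sum(g)

  secs <- data.frame(id = 1L, label = "soma", parent = NA_integer_,
                     length = 1, diam_prox = 1, diam_dist = 1)
  next_id <- 2L
  d0 <- params$primary_dendrite_diam
  for (i in seq_len(n_nabd)) {
    tree <- random_binary_tree(counts[i], lens[i])
    built <- add_dendrite(secs, next_id, tree, d0)
    secs <- built$secs; next_id <- built$next_id
  }

  if (!somatic) {
    seg_abd <- as.integer(round(draw("n_segments_abd")))
    seg_abd <- max(1L, seg_abd)
    if (seg_abd %% 2L == 0L)
      seg_abd <- max(1L, seg_abd + sample(c(-1L, 1L), 1))
    len_abd <- draw("len_abd")
    axon_pos <- draw("axon_soma_distance")
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      if (axon_pos < 0.9 * len_abd) { ok <- TRUE; break }
      axon_pos <- draw("axon_soma_distance")
    }
    if (!ok) stop("could not draw axon_soma_distance within the ABD after ",
                  max_retries, " retries")
    tree <- random_binary_tree(seg_abd, len_abd)
    ## ensure the stem holds the axon origin, preserving total length
    if (tree$lengths[1] <= axon_pos) {
      target_stem <- min(axon_pos + 0.05 * (len_abd - axon_pos),
                         0.95 * len_abd)
      rest <- len_abd - target_stem
      old_rest <- sum(tree$lengths[-1])
      if (length(tree$lengths) > 1 && old_rest > 0)
        tree$lengths[-1] <- tree$lengths[-1] * rest / old_rest
      tree$lengths[1] <- target_stem
    }
    built <- add_dendrite(secs, next_id, tree, d0)
    secs <- built$secs; next_id <- built$next_id
    abd_stem <- built$root_id
    ## split the stem at the axon origin (collinear halves), attach the axon
    i <- which(secs$id == abd_stem)
    L <- secs$length[i]
    frac <- axon_pos / L
    dmid <- secs$diam_prox[i] + frac * (secs$diam_dist[i] - secs$diam_prox[i])
    distal <- secs[i, ]
    distal$id <- next_id; distal$parent <- abd_stem
    distal$length <- L - axon_pos; distal$diam_prox <- dmid
    reattach <- !is.na(secs$parent) & secs$parent == abd_stem
    secs$parent[reattach] <- next_id
    secs$length[i] <- axon_pos; secs$diam_dist[i] <- dmid
    secs <- rbind(secs, distal)
    axon_parent <- abd_stem
    next_id <- next_id + 1L
  } else {
    axon_parent <- 1L
  }
  secs <- rbind(secs, data.frame(
    id = next_id:(next_id + 2L),
    label = c("axon_start", "ais", "axon"),
    parent = c(axon_parent, next_id, next_id + 1L),
    length = c(axon_start_len, ais_len, params$axon_distal_length),
    diam_prox = params$axon_diam, diam_dist = params$axon_diam))

  scyl <- equivalent_cylinder(soma_volume)
  secs$length[1] <- scyl$length
  secs[1, c("diam_prox", "diam_dist")] <- scyl$diameter
  m <- neuron_morphology(secs, soma_volume = soma_volume,
                         stage = params$stage)
  apply_taper(m, terminal_diam = params$terminal_diam,
              axon_diam = params$axon_diam)
}

## random binary tree with n_seg segments (n_seg odd): repeated bifurcation
## of a uniformly chosen terminal segment; lengths partitioned by a
## symmetric Dirichlet draw over segments
random_binary_tree <- function(n_seg, total_len) {
  stopifnot(n_seg %% 2L == 1L)
  parent <- c(0L)                       # segment 1 = stem
  terminals <- 1L
  while (length(parent) < n_seg) {
    t <- terminals[sample.int(length(terminals), 1)]
    k <- length(parent)
    parent <- c(parent, t, t)
    terminals <- c(setdiff(terminals, t), k + 1L, k + 2L)
  }
  w <- rgamma(n_seg, shape = 1.5, rate = 1)
  list(parent = parent, lengths = total_len * w / sum(w))
}

## append a dendrite (segment tree) to the section table, soma = section 1
add_dendrite <- function(secs, next_id, tree, d0) {
  n <- length(tree$parent)
  ids <- next_id:(next_id + n - 1L)
  parents <- ids[pmax(tree$parent, 1L)]
  parents[tree$parent == 0L] <- 1L
  secs <- rbind(secs, data.frame(
    id = ids, label = "dendrite", parent = as.integer(parents),
    length = tree$lengths, diam_prox = d0, diam_dist = d0))
  list(secs = secs, next_id = next_id + n, root_id = ids[1])
}

#' Sample a population of synthetic neurons
#'
#' @param params a `stage_params` object.
#' @param n number of neurons.
#' @param seed integer seed; the draw is reproducible.
#' @return list of `neuron_morphology`.
#' @export
sample_population <- function(params, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) sample_neuron(params))
}

#' Summarize a population into a morphometry table
#'
#' @param pop list of `neuron_morphology` (e.g. from [sample_population()]).
#' @return data.frame, one `morphometric_summary` row per neuron, with a
#'   `stage` column when the neurons carry a stage attribute.
#' @export
summarize_population <- function(pop) {
  rows <- lapply(pop, summarize_morphology)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$stage <- vapply(pop, function(m) {
    st <- attr(m, "stage"); if (is.null(st)) NA_character_ else st
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Sample a synthetic morpho-electrical feature table
#'
#' Draws, per neuron, the morphometric summary from a generated morphology
#' and the AP-shape parameters (threshold, amplitude, half-width, IS and SD
#' second-derivative peaks, SD/IS ratio) from the stage's population
#' parameters. This emulates the joint feature table used by the multivariate
#' developmental analyses; cross-block correlations between morphology and
#' AP shape are not modelled.
#'
#' @param stages character vector of stages, one entry per group.
#' @param n_per_stage neurons per stage (recycled).
#' @param seed integer seed.
#' @return data.frame with a `stage` column, the morphometric fields and the
#'   electrophysiological fields.
#' @export
sample_feature_table <- function(stages, n_per_stage, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_per_stage <- rep_len(n_per_stage, length(stages))
  blocks <- Map(function(st, n) {
    par <- default_stage_params(st)
    tab <- summarize_population(lapply(seq_len(n),
                                       function(i) sample_neuron(par)))
    e <- par$electro
    for (i in seq_len(nrow(e)))
      tab[[e$field[i]]] <- rtnorm_mean(n, e$mean[i], e$sd[i], e$lo[i])
    tab$stage <- st
    tab
  }, stages, n_per_stage)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
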