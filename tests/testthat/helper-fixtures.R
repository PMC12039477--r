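## Shared fixtures. The toy neuron has two 100 um primary dendrites, the
## axon arising from D1 at 30 um (so D1 is split into 30 + 70 um collinear
## sections), a 10 um axon start, a 25 um AIS and a 50 um distal axon.
toy_neuron <- function() {
  secs <- data.frame(
    id = 1:7,
    label = c("soma", "dendrite", "dendrite", "dendrite",
              "axon_start", "ais", "axon"),
    parent = c(NA, 1, 2, 1, 2, 5, 6),
    length = c(10, 30, 70, 100, 10, 25, 50),
    diam_prox = c(10, 2, 2, 2, 0.7, 0.7, 0.7),
    diam_dist = c(10, 2, 2, 2, 0.7, 0.7, 0.7))
  neuron_morphology(secs, soma_volume = 1000)
}

## somatic-axon variant: both dendrites are nABDs
toy_somatic_neuron <- function() {
  secs <- data.frame(
    id = 1:6,
    label = c("soma", "dendrite", "dendrite", "axon_start", "ais", "axon"),
    parent = c(NA, 1, 1, 1, 4, 5),
    length = c(10, 100, 100, 10, 25, 50),
    diam_prox = c(10, 2, 2, 0.7, 0.7, 0.7),
    diam_dist = c(10, 2, 2, 0.7, 0.7, 0.7))
  neuron_morphology(secs, soma_volume = 1000)
}

## random dendritic tree builder used by the segment-count oracle: returns
## a morphology with one primary dendrite of `k` bifurcations plus an axon
## on the soma (so all segments are nABD segments)
random_tree_neuron <- function(k) {
  parent <- c(1L)           # section ids into secs; 1 = soma
  secs <- data.frame(id = 1L, label = "soma", parent = NA_integer_,
                     length = 10, diam_prox = 10, diam_dist = 10)
  add_sec <- function(secs, parent, len) {
    id <- max(secs$id) + 1L
    rbind(secs, data.frame(id = id, label = "dendrite", parent = parent,
                           length = len, diam_prox = 1, diam_dist = 1))
  }
  secs <- add_sec(secs, 1L, runif(1, 20, 80))     # stem
  terminals <- c(2L)
  for (i in seq_len(k)) {
    t <- terminals[sample.int(length(terminals), 1)]
    secs <- add_sec(secs, t, runif(1, 10, 50))
    secs <- add_sec(secs, t, runif(1, 10, 50))
    terminals <- c(setdiff(terminals, t),
                   max(secs$id) - 1L, max(secs$id))
  }
  n <- max(secs$id)
  secs <- rbind(secs, data.frame(
    id = n + 1:3, label = c("axon_start", "ais", "axon"),
    parent = c(1L, n + 1L, n + 2L), length = c(10, 25, 50),
    diam_prox = 0.7, diam_dist = 0.7))
  neuron_morphology(secs, soma_volume = 1000)
}

## independent brute-force segment count: walk the dendritic graph and
## count maximal paths between nodes of degree != 2
brute_force_segments <- function(m) {
  s <- m$sections
  dend <- s[s$label == "dendrite", ]
  n_children <- vapply(dend$id, function(id)
    sum(dend$parent == id, na.rm = TRUE), numeric(1))
  ## walking from every terminal or branch section towards the soma, a new
  ## segment starts after each node with != 1 dendritic children
  sum(n_children != 1)
}

## short default config used by simulation-heavy tests
fast_config <- function(duration = 3000, discard = 1800, dt = 0.02) {
  sim_config(dt = dt, duration = duration, steady_state_discard = discard,
             method = "be")
}

## memoized pacemaking run shared by several tests
.sim_cache <- new.env(parent = emptyenv())
cached_p21_run <- function() {
  if (is.null(.sim_cache$p21)) {
    set.seed(4242)
    m <- sample_neuron(default_stage_params("P21"))
    .sim_cache$p21 <- list(
      m = m, res = run_protocol(m, build_scheme("model2"), fast_config()))
  }
  .sim_cache$p21
}
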