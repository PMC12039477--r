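#' @useDynLib nigradev, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov approx coef cor.test dist hclust cutree
#'   kruskal.test lm p.adjust pnorm dnorm qnorm rgamma rnorm runif sd
#'   setNames shapiro.test t.test TukeyHSD uniroot var
#' @importFrom utils read.csv write.csv
"_PACKAGE"

SECTION_LABELS <- c("soma", "dendrite", "axon_start", "ais", "axon")

#' Build a neuron morphology from a section table
#'
#' A morphology is a rooted tree of labelled sections. The root is a single
#' soma section; dendritic sections attach to the soma or to other dendrites;
#' the axonal path is the chain axon_start -> ais -> axon and attaches either
#' to the soma or to the distal end of one dendritic section (the axon-bearing
#' dendrite, ABD). All geometry is in micrometres.
#'
#' @param sections data.frame with columns `id`, `label` (one of soma,
#'   dendrite, axon_start, ais, axon), `parent` (id or NA for the root),
#'   `length`, `diam_prox`, `diam_dist`.
#' @param soma_volume soma volume in cubic micrometres; if `NULL` it is taken
#'   from the soma section treated as a cylinder.
#' @param stage optional developmental stage label ("P3", "P7", "P14", "P21").
#' @return object of class `neuron_morphology`.
#' @export
neuron_morphology <- function(sections, soma_volume = NULL, stage = NULL) {
  req <- c("id", "label", "parent", "length", "diam_prox", "diam_dist")
  if (!all(req %in% names(sections)))
    stop("sections must have columns: ", paste(req, collapse = ", "))
  sections <- as.data.frame(sections)[, req]
  sections$id <- as.integer(sections$id)
  sections$parent <- as.integer(sections$parent)
  validate_sections(sections)
  if (is.null(soma_volume)) {
    s <- sections[sections$label == "soma", ]
    d <- (s$diam_prox + s$diam_dist) / 2
    soma_volume <- pi * d^2 / 4 * s$length
  }
  if (!is.finite(soma_volume) || soma_volume <= 0)
    stop("soma_volume must be positive")
  m <- structure(
    list(sections = sections, soma_volume = soma_volume,
         axon_origin = axon_origin_of(sections)),
    class = "neuron_morphology")
  attr(m, "stage") <- stage
  m
}

validate_sections <- function(s) {
  if (anyDuplicated(s$id)) stop("duplicate section ids")
  if (!all(s$label %in% SECTION_LABELS))
    stop("unknown section label(s): ",
         paste(setdiff(unique(s$label), SECTION_LABELS), collapse = ", "))
  root <- s$id[is.na(s$parent)]
  if (length(root) != 1L || s$label[is.na(s$parent)] != "soma")
    stop("exactly one root section, labelled soma, is required")
  if (sum(s$label == "soma") != 1L) stop("exactly one soma section is required")
  missing_par <- setdiff(s$parent[!is.na(s$parent)], s$id)
  if (length(missing_par))
    stop("section parent(s) not found: ", paste(missing_par, collapse = ", "))
  if (any(s$length <= 0) || any(s$diam_prox <= 0) || any(s$diam_dist <= 0))
    stop("section lengths and diameters must be strictly positive")
  ## connectivity + acyclicity: walk each section to the root
  par <- setNames(s$parent, s$id)
  for (id in s$id) {
    seen <- integer(0); cur <- id
    while (!is.na(par[[as.character(cur)]])) {
      if (cur %in% seen) stop("cycle detected at section ", id)
      seen <- c(seen, cur)
      cur <- par[[as.character(cur)]]
      if (length(seen) > nrow(s)) stop("disconnected or cyclic tree")
    }
  }
  ## axonal path: exactly one axon_start; chain axon_start -> ais -> axon
  ax <- s[s$label == "axon_start", ]
  if (nrow(ax) >= 1) {
    if (nrow(ax) > 1) stop("more than one axon_start section")
    plab <- s$label[match(ax$parent, s$id)]
    if (!plab %in% c("soma", "dendrite"))
      stop("axon_start must attach to the soma or a dendrite")
  } else if (any(s$label %in% c("ais", "axon"))) {
    stop("ais/axon sections present without an axon_start")
  }
  for (lab in c("ais", "axon")) {
    sub <- s[s$label == lab, ]
    allowed <- switch(lab, ais = c("axon_start", "ais"),
                      axon = c("ais", "axon"))
    plab <- s$label[match(sub$parent, s$id)]
    if (nrow(sub) && !all(plab %in% allowed))
      stop(lab, " sections must continue the axonal path (",
           paste(allowed, collapse = "/"), ")")
  }
  dend <- s[s$label == "dendrite", ]
  if (nrow(dend)) {
    plab <- s$label[match(dend$parent, s$id)]
    if (!all(plab %in% c("soma", "dendrite")))
      stop("dendrite sections must attach to the soma or a dendrite")
  }
  invisible(TRUE)
}

axon_origin_of <- function(s) {
  ax <- s[s$label == "axon_start", ]
  if (nrow(ax) == 0) return(NULL)
  parent <- s[match(ax$parent, s$id), ]
  if (parent$label == "soma") {
    list(on = "soma", section = NA_integer_, pos = 0)
  } else {
    list(on = "dendrite", section = parent$id,
         pos = path_length_to(s, parent$id))
  }
}

## path length from the soma surface to the distal end of section `id`
## (dendritic arc length; the soma section itself does not count)
path_length_to <- function(s, id) {
  len <- 0
  cur <- id
  repeat {
    row <- s[s$id == cur, ]
    if (row$label == "soma") break
    len <- len + row$length
    cur <- row$parent
  }
  len
}

#' @export
print.neuron_morphology <- function(x, ...) {
  s <- x$sections
  cat("<neuron_morphology>",
      sprintf("%d sections (%d dendrite, axonal path: %s)",
              nrow(s), sum(s$label == "dendrite"),
              if (is.null(x$axon_origin)) "none" else x$axon_origin$on), "\n")
  cat(sprintf("  total dendritic length %.1f um, soma volume %.0f um^3\n",
              sum(s$length[s$label == "dendrite"]), x$soma_volume))
  if (!is.null(x$axon_origin) && x$axon_origin$on == "dendrite")
    cat(sprintf("  axon origin on dendrite section %d at %.1f um from soma\n",
                x$axon_origin$section, x$axon_origin$pos))
  invisible(x)
}

children_of <- function(s, id, labels = SECTION_LABELS) {
  s$id[!is.na(s$parent) & s$parent == id & s$label %in% labels]
}

## all dendrite section ids in the subtree rooted at `root_id` (inclusive)
dendrite_subtree <- function(s, root_id) {
  out <- integer(0); stack <- root_id
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    out <- c(out, cur)
    stack <- c(stack, children_of(s, cur, "dendrite"))
  }
  out
}

primary_dendrites <- function(m) {
  s <- m$sections
  soma_id <- s$id[s$label == "soma"]
  children_of(s, soma_id, "dendrite")
}

#' Identify the axon-bearing dendrite (ABD)
#'
#' @param m a `neuron_morphology`.
#' @return the id of the primary dendrite whose subtree carries the axon
#'   origin, or `NA` when the axon arises from the soma.
#' @export
identify_abd <- function(m) {
  ao <- m$axon_origin
  if (is.null(ao)) stop("morphology has no axonal path")
  if (ao$on == "soma") return(NA_integer_)
  s <- m$sections
  cur <- ao$section
  repeat {
    par <- s$parent[s$id == cur]
    if (s$label[s$id == par] == "soma") return(cur)
    cur <- par
  }
}

#' Count dendritic segments
#'
#' A segment is the stretch of dendrite between two branch points, or between
#' a branch point (or the soma) and a tip; an unbranched dendrite is one
#' segment. Pass-through subdivisions of a section (including the node where
#' the axon leaves the ABD) do not create segments, and the axonal path is
#' never counted.
#'
#' @param m a `neuron_morphology`.
#' @param subset one of `"all"`, `"abd"`, `"nabd"`.
#' @return integer segment count; `NA` for `subset = "abd"` on a neuron whose
#'   axon arises from the soma (ABD undefined).
#' @export
count_segments <- function(m, subset = c("all", "abd", "nabd")) {
  subset <- match.arg(subset)
  s <- m$sections
  abd <- if (is.null(m$axon_origin)) NA_integer_ else identify_abd(m)
  prim <- primary_dendrites(m)
  if (subset == "abd" && is.na(abd)) return(NA_integer_)
  roots <- switch(subset,
                  all  = prim,
                  abd  = abd,
                  nabd = setdiff(prim, if (is.na(abd)) integer(0) else abd))
  ids <- unlist(lapply(roots, dendrite_subtree, s = s))
  if (!length(ids)) return(0L)
  ## a section ends a segment iff it does not have exactly one dendritic child
  n_child <- vapply(ids, function(i) length(children_of(s, i, "dendrite")),
                    integer(1))
  sum(n_child != 1L)
}

dendrite_length <- function(m, roots) {
  s <- m$sections
  ids <- unlist(lapply(roots, dendrite_subtree, s = s))
  if (!length(ids)) return(0)
  sum(s$length[match(ids, s$id)])
}

axonal_length <- function(m, label) {
  s <- m$sections
  sum(s$length[s$label == label])
}

#' Morphometric summary of one neuron
#'
#' Computes the per-neuron metric vector used throughout the developmental
#' analysis: dendritic complexity (segment counts) and lengths split into the
#' axon-bearing dendrite (ABD) and the non-axon-bearing dendrites (nABDs),
#' proximal-axon geometry (axon-soma distance, axon start length, AIS-soma
#' distance, AIS length), and soma volume. For neurons whose axon arises from
#' the soma the ABD does not exist and all ABD-conditional fields are `NA`.
#'
#' @param m a `neuron_morphology`.
#' @return one-row data.frame of class `morphometric_summary`.
#' @export
summarize_morphology <- function(m) {
  s <- m$sections
  abd <- identify_abd(m)
  prim <- primary_dendrites(m)
  somatic <- is.na(abd)
  nabd_roots <- setdiff(prim, if (somatic) integer(0) else abd)
  n_abd <- count_segments(m, "abd")
  n_nabd <- count_segments(m, "nabd")
  len_abd <- if (somatic) NA_real_ else dendrite_length(m, abd)
  len_nabd <- dendrite_length(m, nabd_roots)
  axon_soma <- if (somatic) 0 else m$axon_origin$pos
  axon_start <- axonal_length(m, "axon_start")
  out <- data.frame(
    n_segments_total = count_segments(m, "all"),
    n_segments_abd = n_abd,
    n_segments_nabd = n_nabd,
    n_primary_nabd = length(nabd_roots),
    avg_segments_per_nabd = n_nabd / length(nabd_roots),
    len_total = dendrite_length(m, prim),
    len_abd = len_abd,
    len_nabd_total = len_nabd,
    len_nabd_avg = len_nabd / length(nabd_roots),
    axon_soma_distance = axon_soma,
    axon_start_length = axon_start,
    ais_soma_distance = axon_soma + axon_start,
    ais_length = axonal_length(m, "ais"),
    soma_volume = m$soma_volume,
    has_somatic_axon = somatic)
  class(out) <- c("morphometric_summary", class(out))
  out
}

#' Equivalent cylinder for a soma volume
#'
#' The soma is represented in the compartmental model by a cylinder whose
#' length equals its diameter, so pi d^3 / 4 = V.
#'
#' @param volume soma volume, cubic micrometres.
#' @return list with `diameter` and `length` (equal), micrometres.
#' @export
equivalent_cylinder <- function(volume) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  d <- (4 * volume / pi)^(1 / 3)
  list(diameter = d, length = d)
}

#' Apply regular dendritic taper and fixed axonal diameter
#'
#' Primary-stem sections (soma to first branch point) keep the primary
#' diameter; beyond the first branch point, diameters interpolate linearly
#' with arc length from the stem diameter down to `terminal_diam`, reaching it
#' exactly at the tip of the longest path through each section (every terminal
#' section therefore ends at `terminal_diam`). All axonal sections are set to
#' the constant `axon_diam`.
#'
#' @param m a `neuron_morphology`.
#' @param terminal_diam diameter at dendritic tips, micrometres (default 0.5).
#' @param axon_diam constant axonal diameter, micrometres (default 0.7).
#' @return the tapered `neuron_morphology`.
#' @export
apply_taper <- function(m, terminal_diam = 0.5, axon_diam = 0.7) {
  if (terminal_diam <= 0) stop("terminal_diam must be positive")
  if (axon_diam <= 0) stop("axon_diam must be positive")
  s <- m$sections
  for (p in primary_dendrites(m)) {
    d0 <- s$diam_prox[s$id == p]
    ## walk the primary stem: chain until the first dendritic branch point
    stem <- p
    repeat {
      kids <- children_of(s, stem[length(stem)], "dendrite")
      if (length(kids) != 1L) break
      stem <- c(stem, kids)
    }
    s[s$id %in% stem, c("diam_prox", "diam_dist")] <- d0
    ## taper the rest of the subtree from the stem end
    sub <- setdiff(dendrite_subtree(s, p), stem)
    if (!length(sub)) next
    stem_end <- stem[length(stem)]
    depth_prox <- setNames(numeric(length(sub)), sub)   # arc from stem end
    for (id in sub) {                                    # parents precede? walk up
      len <- 0; cur <- s$parent[s$id == id]
      while (!cur %in% c(stem_end)) {
        len <- len + s$length[s$id == cur]
        cur <- s$parent[s$id == cur]
      }
      depth_prox[as.character(id)] <- len
    }
    ## max tip depth through each section
    max_below <- function(id) {
      kids <- children_of(s, id, "dendrite")
      if (!length(kids)) return(0)
      max(vapply(kids, function(k) s$length[s$id == k] + max_below(k),
                 numeric(1)))
    }
    for (id in sub) {
      sp <- depth_prox[as.character(id)]
      sl <- s$length[s$id == id]
      total <- sp + sl + max_below(id)
      s$diam_prox[s$id == id] <- d0 + (terminal_diam - d0) * sp / total
      s$diam_dist[s$id == id] <- d0 + (terminal_diam - d0) * (sp + sl) / total
    }
  }
  s[s$label %in% c("axon_start", "ais", "axon"),
    c("diam_prox", "diam_dist")] <- axon_diam
  m$sections <- s
  m
}
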