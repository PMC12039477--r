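## SWC input/output. SWC is the standard 7-column text format for digital
## neuron reconstructions: point id, type code, x, y, z, radius, parent id.
## Type codes: 1 soma, 2 axon, 3/4 dendrite. SWC has no code for the axon
## initial segment, so the axon_start / AIS / distal-axon partition of the
## axonal path comes from a JSON side-car file (or explicit arguments).

#' Load a neuron morphology from an SWC file
#'
#' Each SWC edge (point to parent) becomes one section; soma points collapse
#' to a single root section. The axonal path is split into axon_start, AIS
#' and distal axon using `axon_start_length` / `ais_length`, taken from the
#' arguments or from a side-car JSON file `<path>.json` with fields
#' `soma_volume`, `axon_start_length`, `ais_length`.
#'
#' @param path SWC file path.
#' @param axon_start_length,ais_length axonal partition, micrometres;
#'   `NULL` means read from the side-car (required if an axon is present).
#' @param soma_volume soma volume, cubic micrometres; default from the soma
#'   samples (sphere for a single sample, frusta otherwise) or the side-car.
#' @return a `neuron_morphology`.
#' @export
load_morphology <- function(path, axon_start_length = NULL,
                            ais_length = NULL, soma_volume = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(soma_volume)) soma_volume <- meta$soma_volume
    if (is.null(axon_start_length)) axon_start_length <- meta$axon_start_length
    if (is.null(ais_length)) ais_length <- meta$ais_length
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC at line ", lineno[bad[1]], ": expected 7 columns")
  pt <- as.data.frame(do.call(rbind, lapply(fields, as.numeric)))
  names(pt) <- c("id", "type", "x", "y", "z", "r", "parent")
  if (anyNA(pt))
    stop("malformed SWC at line ",
         lineno[which(apply(is.na(pt), 1, any))[1]], ": non-numeric field")
  miss <- pt$parent != -1 & !(pt$parent %in% pt$id)
  if (any(miss))
    stop("SWC structure error: point ", pt$id[which(miss)[1]],
         " references missing parent ", pt$parent[which(miss)[1]])
  if (sum(pt$parent == -1) != 1L)
    stop("SWC structure error: expected exactly one root point")
  soma_pts <- pt[pt$type == 1, ]
  if (nrow(soma_pts) == 0) stop("SWC structure error: no soma point")
  if (is.null(soma_volume)) {
    if (nrow(soma_pts) == 1) {
      soma_volume <- 4 / 3 * pi * soma_pts$r[1]^3
    } else {
      v <- 0
      for (i in seq_len(nrow(soma_pts))) {
        p <- soma_pts$parent[i]
        if (p %in% soma_pts$id) {
          q <- soma_pts[soma_pts$id == p, ]
          L <- sqrt(sum((c(soma_pts$x[i], soma_pts$y[i], soma_pts$z[i]) -
                           c(q$x, q$y, q$z))^2))
          r1 <- q$r; r2 <- soma_pts$r[i]
          v <- v + pi * L / 3 * (r1^2 + r1 * r2 + r2^2)
        }
      }
      soma_volume <- v
    }
  }
  soma_d <- equivalent_cylinder(soma_volume)$diameter
  ## sections: one per non-soma edge; soma collapses to section 1
  sec <- data.frame(id = 1L, label = "soma", parent = NA_integer_,
                    length = soma_d, diam_prox = soma_d, diam_dist = soma_d)
  id_map <- setNames(rep(1L, nrow(soma_pts)), soma_pts$id)
  nonsoma <- pt[pt$type != 1, ]
  nonsoma <- nonsoma[order(nonsoma$id), ]
  next_id <- 2L
  for (i in seq_len(nrow(nonsoma))) {
    p <- nonsoma[i, ]
    par_pt <- pt[pt$id == p$parent, ]
    if (nrow(par_pt) == 0)
      stop("SWC structure error: point ", p$id, " has no parent in tree")
    L <- sqrt((p$x - par_pt$x)^2 + (p$y - par_pt$y)^2 + (p$z - par_pt$z)^2)
    if (L <= 0) L <- 1e-6  # coincident sample points: keep a token arc
    lab <- if (p$type == 2) "axon_raw" else "dendrite"
    sec <- rbind(sec, data.frame(
      id = next_id, label = lab, parent = id_map[[as.character(p$parent)]],
      length = L, diam_prox = 2 * par_pt$r, diam_dist = 2 * p$r))
    id_map[[as.character(p$id)]] <- next_id
    next_id <- next_id + 1L
  }
  sec <- split_axonal_path(sec, axon_start_length, ais_length)
  neuron_morphology(sec, soma_volume = soma_volume)
}

## relabel the raw axonal chain into axon_start / ais / axon by arc length
split_axonal_path <- function(sec, axon_start_length, ais_length) {
  ax <- which(sec$label == "axon_raw")
  if (!length(ax)) return(sec)
  if (is.null(axon_start_length) || is.null(ais_length))
    stop("axon present but axon_start_length/ais_length not supplied ",
         "(side-car JSON or arguments)")
  ## order the chain from its attachment point outward
  ax_ids <- sec$id[ax]
  roots <- ax_ids[!(sec$parent[ax] %in% ax_ids)]
  if (length(roots) != 1L)
    stop("SWC structure error: axonal path must be a single chain")
  chain <- roots
  repeat {
    kids <- sec$id[!is.na(sec$parent) &
                     sec$parent == chain[length(chain)] &
                     sec$label == "axon_raw"]
    if (!length(kids)) break
    if (length(kids) > 1)
      stop("SWC structure error: branching axon not supported")
    chain <- c(chain, kids)
  }
  pos <- 0
  cuts <- c(axon_start_length, axon_start_length + ais_length)
  next_id <- max(sec$id) + 1L
  k <- 1L
  while (k <= length(chain)) {
    cid <- chain[k]
    i <- which(sec$id == cid)
    ## split this section wherever a cut falls strictly inside it
    for (cut in cuts) {
      if (pos < cut - 1e-6 && pos + sec$length[i] > cut + 1e-6) {
        l1 <- cut - pos
        frac <- l1 / sec$length[i]
        dmid <- sec$diam_prox[i] +
          frac * (sec$diam_dist[i] - sec$diam_prox[i])
        new_row <- sec[i, ]
        new_row$id <- next_id
        new_row$parent <- sec$id[i]
        new_row$length <- sec$length[i] - l1
        new_row$diam_prox <- dmid
        ## reattach downstream children of the original to the new piece
        down <- !is.na(sec$parent) & sec$parent == sec$id[i] &
          sec$label == "axon_raw" & sec$id != next_id
        sec$parent[down] <- next_id
        sec$length[i] <- l1
        sec$diam_dist[i] <- dmid
        sec <- rbind(sec, new_row)
        next_id <- next_id + 1L
        chain <- append(chain, new_row$id, after = k)
        break
      }
    }
    L <- sec$length[sec$id == cid]
    lab <- if (pos + L <= cuts[1] + 1e-6) "axon_start"
           else if (pos + L <= cuts[2] + 1e-6) "ais" else "axon"
    sec$label[sec$id == cid] <- lab
    pos <- pos + L
    k <- k + 1L
  }
  if (pos < cuts[2] - 1e-6)
    stop("axonal path shorter than axon_start_length + ais_length")
  sec
}

#' Write a neuron morphology to an SWC file (plus JSON side-car)
#'
#' Synthetic morphologies carry no real 3-D coordinates, so sections are
#' embedded as straight lines in deterministic directions; arc lengths and
#' diameters are preserved exactly. A side-car `<path>.json` records
#' soma volume and the axon_start/AIS partition so that
#' [load_morphology()] round-trips.
#'
#' @param m a `neuron_morphology`.
#' @param path output SWC path.
#' @return `path`, invisibly.
#' @export
save_morphology <- function(m, path) {
  s <- m$sections
  soma <- s[s$label == "soma", ]
  rows <- list(sprintf("%d %d %.9f %.9f %.9f %.9f %d",
                       1L, 1L, 0, 0, 0, soma$diam_dist / 2, -1L))
  pt_of_section <- setNames(1L, soma$id)
  pos_of_section <- list(); pos_of_section[[as.character(soma$id)]] <- c(0, 0, 0)
  next_pt <- 2L
  ## deterministic direction per section id (golden-angle spiral on sphere)
  dir_of <- function(k) {
    ga <- pi * (3 - sqrt(5))
    z <- 1 - 2 * ((k %% 97) + 0.5) / 97
    r <- sqrt(max(0, 1 - z^2)); th <- ga * k
    c(r * cos(th), r * sin(th), z)
  }
  type_of <- c(soma = 1L, dendrite = 3L, axon_start = 2L, ais = 2L, axon = 2L)
  ## emit in an order where parents precede children
  remaining <- s[s$label != "soma", ]
  emitted <- soma$id
  while (nrow(remaining)) {
    ready <- remaining$parent %in% emitted
    if (!any(ready)) stop("cannot order sections (disconnected?)")
    for (i in which(ready)) {
      sec <- remaining[i, ]
      base <- pos_of_section[[as.character(sec$parent)]]
      xyz <- base + dir_of(sec$id) * sec$length
      rows[[length(rows) + 1L]] <- sprintf(
        "%d %d %.9f %.9f %.9f %.9f %d",
        next_pt, type_of[[sec$label]], xyz[1], xyz[2], xyz[3],
        sec$diam_dist / 2, pt_of_section[[as.character(sec$parent)]])
      pt_of_section[[as.character(sec$id)]] <- next_pt
      pos_of_section[[as.character(sec$id)]] <- xyz
      next_pt <- next_pt + 1L
    }
    emitted <- c(emitted, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  writeLines(c("# SWC written by nigradev", unlist(rows)), path)
  jsonlite::write_json(
    list(soma_volume = m$soma_volume,
         axon_start_length = axonal_length(m, "axon_start"),
         ais_length = axonal_length(m, "ais")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
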