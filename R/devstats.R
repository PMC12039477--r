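## Developmental-stage statistics: per-parameter four-stage comparisons
## (normality-gated one-way ANOVA + Tukey HSD, or Kruskal-Wallis + Dunn),
## paired ABD-vs-nABD tests, Pearson regressions, the stacked significance
## grid, agglomerative hierarchical clustering, and linear discriminant
## analysis on standardized features.

SIG_BANDS <- c("ns", "<0.05", "<0.01", "<0.001")

band_of <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = rev(SIG_BANDS), right = FALSE)
}

#' The twelve clustering parameters
#'
#' Five AP-shape and seven morphological features used by the hierarchical
#' clustering of developmental stages.
#' @export
CLUSTER_PARAMS <- c("ap_half_width", "is_peak", "sd_peak", "sd_is_ratio",
                    "ap_amplitude", "soma_volume", "axon_start_length",
                    "ais_soma_distance", "len_nabd_avg", "len_nabd_total",
                    "len_total", "len_abd")

## Dunn's post hoc test after Kruskal-Wallis: pairwise z statistics on mean
## ranks with tie correction; two-sided p values, Holm-adjusted. Written
## in-package (no installed package provides it).
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = p.adjust(p, "holm"))
}

#' Compare one parameter across developmental stages
#'
#' Chooses the test family from the data distribution: if every stage group
#' passes Shapiro-Wilk normality (alpha = 0.05) the comparison is a one-way
#' ANOVA with Tukey HSD post hoc; otherwise Kruskal-Wallis with Dunn post
#' hoc. All pairwise stage comparisons are returned with significance bands.
#'
#' @param table data.frame with a `stage` column and the parameter column.
#' @param parameter column name to compare.
#' @param alpha_normality Shapiro-Wilk gate level.
#' @return object of class `comparison_result`: `parameter`, `test`
#'   ("anova_tukey" or "kruskal_dunn"), `overall_p`, `pairs` data.frame
#'   (stage1, stage2, p, band).
#' @export
compare_stages <- function(table, parameter, alpha_normality = 0.05) {
  if (!parameter %in% names(table)) stop("unknown parameter: ", parameter)
  df <- table[!is.na(table[[parameter]]), c("stage", parameter)]
  names(df) <- c("stage", "y")
  df$stage <- factor(df$stage, levels = intersect(STAGES, unique(df$stage)))
  sizes <- table(df$stage)
  if (sum(sizes >= 3) < 2)
    stop("need at least two stages with >= 3 values for ", parameter)
  df <- df[df$stage %in% names(sizes)[sizes >= 3], ]
  df$stage <- droplevels(df$stage)
  normal <- all(tapply(df$y, df$stage, function(x) {
    if (length(unique(x)) < 3) return(FALSE)
    shapiro.test(x)$p.value >= alpha_normality
  }))
  if (normal) {
    fit <- aov(y ~ stage, data = df)
    overall_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$stage
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairs <- data.frame(stage1 = vapply(nm, `[`, "", 2),
                        stage2 = vapply(nm, `[`, "", 1),
                        p = tk[, "p adj"], row.names = NULL)
    test <- "anova_tukey"
  } else {
    kw <- kruskal.test(y ~ stage, data = df)
    overall_p <- kw$p.value
    dn <- dunn_test(df$y, df$stage)
    pairs <- data.frame(stage1 = dn$group1, stage2 = dn$group2, p = dn$p)
    test <- "kruskal_dunn"
  }
  pairs$band <- band_of(pairs$p)
  structure(list(parameter = parameter, test = test, overall_p = overall_p,
                 pairs = pairs), class = "comparison_result")
}

#' Paired ABD versus nABD comparison per stage
#'
#' Neuron-per-neuron paired t test of the ABD value against the averaged
#' nABD value (length or complexity). Somatic-axon neurons (no ABD) are
#' excluded.
#'
#' @param table morphometry table with `stage` and the two columns.
#' @param abd_col,nabd_col column names (default length).
#' @return data.frame per stage: n pairs, mean difference (ABD - nABD),
#'   t, p, band.
#' @export
paired_abd_nabd <- function(table, abd_col = "len_abd",
                            nabd_col = "len_nabd_avg") {
  out <- lapply(intersect(STAGES, unique(table$stage)), function(st) {
    sub <- table[table$stage == st & !is.na(table[[abd_col]]) &
                   !is.na(table[[nabd_col]]), ]
    if (nrow(sub) < 3)
      return(data.frame(stage = st, n = nrow(sub), mean_diff = NA_real_,
                        t = NA_real_, p = NA_real_))
    d <- sub[[abd_col]] - sub[[nabd_col]]
    if (sd(d) == 0) {
      ## degenerate pairing (identical columns or constant offset)
      return(data.frame(stage = st, n = nrow(sub), mean_diff = mean(d),
                        t = NA_real_,
                        p = if (mean(d) == 0) 1 else 0))
    }
    tt <- t.test(sub[[abd_col]], sub[[nabd_col]], paired = TRUE)
    data.frame(stage = st, n = nrow(sub),
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               p = tt$p.value)
  })
  out <- do.call(rbind, out)
  out$band <- band_of(out$p)
  out
}

#' Pearson correlation and least-squares line
#'
#' @param x,y numeric vectors (pairs with missing values dropped).
#' @return list: `r`, `p` (two-sided, t distribution), `n`, `slope`,
#'   `intercept`.
#' @export
pearson_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                slope = NA_real_, intercept = NA_real_))
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Stacked significance grid
#'
#' Runs [compare_stages()] for every parameter and stacks the pairwise
#' significance bands into a 6-stage-pair x parameter grid (the stacked
#' representation of the developmental statistics).
#'
#' @param table feature table with `stage`.
#' @param parameters parameter columns (default: all numeric columns).
#' @return matrix of bands (rows = stage pairs "P3-P7", ...; columns =
#'   parameters), with attribute `p` holding the p values.
#' @export
stacking_matrix <- function(table, parameters = NULL) {
  if (is.null(parameters))
    parameters <- setdiff(names(table)[vapply(table, is.numeric,
                                              logical(1))], "stage")
  stages <- intersect(STAGES, unique(table$stage))
  pair_names <- utils::combn(stages, 2, paste, collapse = "-")
  bands <- matrix(NA_character_, nrow = length(pair_names),
                  ncol = length(parameters),
                  dimnames = list(pair_names, parameters))
  pmat <- matrix(NA_real_, nrow = length(pair_names),
                 ncol = length(parameters),
                 dimnames = list(pair_names, parameters))
  for (par in parameters) {
    cr <- try(compare_stages(table, par), silent = TRUE)
    if (inherits(cr, "try-error")) next
    for (i in seq_len(nrow(cr$pairs))) {
      key <- paste(cr$pairs$stage1[i], cr$pairs$stage2[i], sep = "-")
      key2 <- paste(cr$pairs$stage2[i], cr$pairs$stage1[i], sep = "-")
      row <- if (key %in% pair_names) key else key2
      bands[row, par] <- as.character(cr$pairs$band[i])
      pmat[row, par] <- cr$pairs$p[i]
    }
  }
  attr(bands, "p") <- pmat
  bands
}

#' Agglomerative hierarchical clustering of neurons
#'
#' Ward clustering on Euclidean distances between z-scored features
#' (complete cases). The automatic threshold cuts the dendrogram at the
#' largest gap between successive merge heights, which determines the
#' number of flat classes.
#'
#' @param table feature table with `stage`.
#' @param parameters feature columns (default [CLUSTER_PARAMS]).
#' @return list of class `ahc_result`: `hclust` object, `classes` (integer
#'   per retained row), `rows` (row indices used), `n_classes`,
#'   `class_mean_age` (mean postnatal day per class, from the stage label).
#' @export
ahc <- function(table, parameters = CLUSTER_PARAMS) {
  x <- table[, parameters, drop = FALSE]
  keep <- stats::complete.cases(x)
  if (sum(keep) < 4) stop("need at least 4 complete-case rows")
  z <- scale(as.matrix(x[keep, ]))
  hc <- hclust(dist(z), method = "ward.D2")
  heights <- hc$height
  gaps <- diff(heights)
  ## cut below the largest gap between successive merges
  k <- length(heights) - which.max(gaps) + 1L
  k <- max(2L, min(k, nrow(z) - 1L))
  classes <- cutree(hc, k = k)
  age <- as.numeric(sub("^P", "", table$stage[keep]))
  cma <- tapply(age, classes, mean)
  structure(list(
    hclust = hc, classes = classes, rows = which(keep), n_classes = k,
    class_mean_age = setNames(as.numeric(cma), names(cma))),
    class = "ahc_result")
}

#' Linear discriminant analysis of developmental stages
#'
#' LDA on z-scored features (complete cases) with the stage as the class
#' label; returns the projection onto the first two discriminant axes,
#' per-stage centroids, and per-parameter loadings. Singular within-class
#' scatter falls back to a slightly regularized fit (with a warning).
#'
#' @param table feature table with `stage`.
#' @param parameters feature columns (default: the nine-parameter set, see
#'   [LDA_PARAMS]).
#' @return list of class `lda_result`: `scores` (n x 2), `stage` labels,
#'   `centroids`, `loadings`, the fitted `MASS::lda` object.
#' @export
lda_stages <- function(table, parameters = LDA_PARAMS) {
  x <- table[, parameters, drop = FALSE]
  keep <- stats::complete.cases(x) & !is.na(table$stage)
  z <- scale(as.matrix(x[keep, ]))
  stage <- factor(table$stage[keep],
                  levels = intersect(STAGES, unique(table$stage[keep])))
  fit <- try(MASS::lda(z, grouping = stage), silent = TRUE)
  if (inherits(fit, "try-error")) {
    warning("singular within-class scatter; regularizing")
    z <- z + matrix(rnorm(length(z), sd = 1e-8), nrow = nrow(z))
    fit <- MASS::lda(z, grouping = stage)
  }
  nd <- min(2L, ncol(fit$scaling))
  scores <- z %*% fit$scaling[, seq_len(nd), drop = FALSE]
  if (nd == 1L) scores <- cbind(scores, 0)
  colnames(scores) <- c("F1", "F2")
  centroids <- apply(scores, 2, tapply, stage, mean)
  structure(list(scores = scores, stage = stage, centroids = centroids,
                 loadings = fit$scaling[, seq_len(nd), drop = FALSE],
                 fit = fit), class = "lda_result")
}

#' The nine-parameter discriminant set
#'
#' Default feature set for [lda_stages()]: the clustering parameters minus
#' the three most redundant length measures (total dendritic length is the
#' ABD + nABD sum, average nABD length duplicates the nABD total, and
#' AIS-soma distance is the axon-start sum). Configurable; the canonical
#' nine-parameter set is not enumerated in print.
#' @export
LDA_PARAMS <- c("ap_half_width", "is_peak", "sd_peak", "sd_is_ratio",
                "ap_amplitude", "soma_volume", "axon_start_length",
                "len_nabd_total", "len_abd")
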