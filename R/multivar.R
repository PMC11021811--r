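# Trait correlation matrices, Ward.D2 trait clustering, founder-space PCA
# with DO projection, and 1-SD normal data ellipses.

#' Pairwise Pearson correlation matrix with significance mask
#'
#' Pairwise-complete Pearson correlations between traits with two-sided
#' t-test p-values and the nonsignificance mask (`p > 0.05`) used to flag
#' entries in correlation heatmaps. Pairs with fewer than 3 complete
#' observations, or involving a constant trait, are marked unavailable
#' (`NA`) with a warning.
#'
#' @param table Cohort table (data frame).
#' @param traits Character vector of trait columns.
#' @param alpha Mask threshold (default 0.05).
#' @return Object of class `correlation_matrix`: matrices `r`, `p`, `n`,
#'   logical `mask` (TRUE where `p > alpha`), and `traits`.
#' @export
pearson_matrix <- function(table, traits, alpha = 0.05) {
  missing_tr <- setdiff(traits, names(table))
  if (length(missing_tr)) {
    stop("pearson_matrix: traits not in table: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  n <- matrix(0L, k, k, dimnames = list(traits, traits))
  warned <- character()
  for (i in seq_len(k)) {
    r[i, i] <- 1
    p[i, i] <- 0
    n[i, i] <- sum(!is.na(table[[traits[i]]]))
    for (j in seq_len(i - 1L)) {
      x <- table[[traits[i]]]
      y <- table[[traits[j]]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L || stats::var(x[ok]) < .Machine$double.eps ||
          stats::var(y[ok]) < .Machine$double.eps) {
        warned <- c(warned, paste0(traits[i], "~", traits[j]))
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (length(warned)) {
    warning("correlation unavailable (constant trait or < 3 pairs) for: ",
            paste(warned, collapse = ", "), call. = FALSE)
  }
  mask <- p > alpha
  diag(mask) <- FALSE
  structure(list(traits = traits, r = r, p = p, n = n, mask = mask,
                 alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d traits, %d nonsignificant pairs (p > %g)\n",
              length(x$traits), sum(x$mask, na.rm = TRUE) / 2, x$alpha))
  invisible(x)
}

#' Hierarchical trait clustering on correlation distance
#'
#' Agglomerative clustering of traits with the Ward.D2 criterion (squared
#' Lance-Williams update) on the distance `d = 1 - r`, cut into `k`
#' clusters. Signed distance is the default because traits whose biology
#' agrees have positive correlations; `1 - |r|` is available.
#'
#' @param corr A [pearson_matrix()] result.
#' @param k Number of clusters (1 <= k <= number of traits).
#' @param transform `"one_minus_r"` (default) or `"one_minus_abs_r"`.
#' @return Named integer vector of cluster labels, with the `hclust` tree
#'   as attribute `"tree"`.
#' @export
cluster_traits <- function(corr, k,
                           transform = c("one_minus_r",
                                         "one_minus_abs_r")) {
  if (!inherits(corr, "correlation_matrix")) {
    stop("cluster_traits: 'corr' must come from pearson_matrix()",
         call. = FALSE)
  }
  transform <- match.arg(transform)
  if (k < 1 || k > length(corr$traits)) {
    stop("cluster_traits: k must be in [1, number of traits]",
         call. = FALSE)
  }
  r <- corr$r
  off <- r[upper.tri(r)]
  if (anyNA(off)) {
    stop("cluster_traits: correlation matrix has unavailable entries; ",
         "remove the affected traits or impute before clustering",
         call. = FALSE)
  }
  d <- if (transform == "one_minus_r") 1 - r else 1 - abs(r)
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Principal component analysis of founder traits
#'
#' Standardizes each trait to mean 0, SD 1 over the fitted (founder) rows
#' and extracts principal components by singular-value decomposition (via
#' `prcomp`). For reproducibility across runs each loading column is
#' sign-fixed so its largest-magnitude entry is positive. Rows with missing
#' values are dropped (listwise) with a message.
#'
#' @param table Cohort table.
#' @param traits Character vector of trait columns.
#' @return Object of class `pca_model`: `traits`, `center`, `scale`,
#'   `weightings` (traits x PCs loadings, orthonormal columns),
#'   `explained` (variance proportions, nonincreasing, summing to 1),
#'   `sdev`, and fitted `scores`.
#' @export
fit_pca <- function(table, traits) {
  missing_tr <- setdiff(traits, names(table))
  if (length(missing_tr)) {
    stop("fit_pca: traits not in table: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(table[, traits, drop = FALSE])
  keep <- stats::complete.cases(x)
  if (sum(!keep)) {
    message("fit_pca: dropping ", sum(!keep), " incomplete rows")
  }
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < length(traits) + 1L) {
    stop("fit_pca: need at least traits + 1 complete rows", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    stop("fit_pca: constant trait(s): ",
         paste(traits[sds < .Machine$double.eps], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(traits = traits, center = pc$center, scale = pc$scale,
                 weightings = rot,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, scores = scores),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d traits, %d rows; PC1-PC4 explain %s\n",
              length(x$traits), nrow(x$scores),
              paste(sprintf("%.1f%%",
                            100 * utils::head(x$explained, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Project animals onto a fitted founder PC space
#'
#' Each row is centered and scaled with the founder parameters and linearly
#' combined according to the founder PC weightings; no refitting occurs, so
#' projecting the training rows reproduces the fitted scores. Rows with a
#' missing model trait are skipped with a message.
#'
#' @param model A [fit_pca()] result.
#' @param table Cohort table containing all model traits.
#' @return Score matrix (rows x PCs), with skipped-row indices in attribute
#'   `"skipped"`.
#' @export
project_onto_pca <- function(model, table) {
  if (!inherits(model, "pca_model")) {
    stop("project_onto_pca: 'model' must come from fit_pca()",
         call. = FALSE)
  }
  missing_tr <- setdiff(model$traits, names(table))
  if (length(missing_tr)) {
    stop("project_onto_pca: table lacks model traits: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(table[, model$traits, drop = FALSE])
  keep <- stats::complete.cases(x)
  if (sum(!keep)) {
    message("project_onto_pca: skipping ", sum(!keep),
            " rows with missing traits")
  }
  xs <- scale(x[keep, , drop = FALSE], center = model$center,
              scale = model$scale)
  sc <- xs %*% model$weightings
  rownames(sc) <- rownames(x)[keep]
  attr(sc, "skipped") <- which(!keep)
  sc
}

#' Normal data ellipses in PC coordinates
#'
#' For each group, the contour `(x - mu)' Sigma^{-1} (x - mu) = level^2` of
#' the fitted bivariate normal: semi-axes are `level * sqrt(eigenvalues)` of
#' the sample covariance and the orientation comes from the leading
#' eigenvector. `level = 1` is the 1-SD normal data ellipse commonly drawn
#' around strain groups in PC score plots.
#'
#' @param scores Two-column matrix of coordinates (e.g. PC1-PC2).
#' @param groups Group label per row.
#' @param level Radius in SD multiples (default 1).
#' @return Data frame (class `ellipse_spec`): one row per group with
#'   center, semi-axes `a >= b`, orientation `angle_deg`
#'   (counter-clockwise from the x-axis), `n`, and a `degenerate` flag for
#'   singular covariances (collinear points).
#' @export
normal_ellipse <- function(scores, groups, level = 1) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) {
    stop("normal_ellipse: 'scores' must have exactly 2 columns",
         call. = FALSE)
  }
  if (length(groups) != nrow(scores)) {
    stop("normal_ellipse: 'groups' length must match rows", call. = FALSE)
  }
  out <- lapply(unique(groups), function(g) {
    xy <- scores[groups == g, , drop = FALSE]
    if (nrow(xy) < 3L) {
      stop("normal_ellipse: group '", g, "' has fewer than 3 points",
           call. = FALSE)
    }
    mu <- colMeans(xy)
    S <- stats::cov(xy)
    e <- eigen(S, symmetric = TRUE)
    degen <- e$values[2] <= 1e-12 * max(e$values[1], 1e-300)
    data.frame(group = g, center1 = mu[1], center2 = mu[2],
               a = level * sqrt(max(e$values[1], 0)),
               b = level * sqrt(max(e$values[2], 0)),
               angle_deg = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi,
               n = nrow(xy), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ellipse_spec", "data.frame")
  out
}

#' Ellipse outline coordinates for plotting
#'
#' @param spec One row of a [normal_ellipse()] result.
#' @param n_points Number of polygon vertices.
#' @return Data frame with `x`, `y` outlining the ellipse.
#' @export
ellipse_path <- function(spec, n_points = 100) {
  th <- seq(0, 2 * pi, length.out = n_points)
  ang <- spec$angle_deg * pi / 180
  x0 <- spec$a * cos(th)
  y0 <- spec$b * sin(th)
  data.frame(x = spec$center1 + x0 * cos(ang) - y0 * sin(ang),
             y = spec$center2 + x0 * sin(ang) + y0 * cos(ang))
}
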