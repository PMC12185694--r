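#' Normality-gated two-group comparison
#'
#' Runs Shapiro-Wilk on each group; when both are compatible with
#' normality (p >= 0.05) the groups are compared by a pooled-variance
#' two-sample t-test, otherwise by a Wilcoxon rank-sum test. One-tailed
#' tests require the direction to be supplied explicitly — it is never
#' inferred from the data.
#'
#' @param a,b Numeric samples (each n >= 3).
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @param welch Use Welch's unequal-variance t instead of the pooled t.
#' @param shapiro_alpha Normality-gate threshold (default 0.05).
#' @return One-row tibble: `test` ("t" or "rank-sum"), `statistic`, `p`,
#'   `tails`, `n_a`, `n_b`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
auto_compare <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         welch = FALSE, shapiro_alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (length(a) < 3 || length(b) < 3) stop("Each group needs n >= 3.", call. = FALSE)
  sw_a <- if (stats::sd(a) > 0) stats::shapiro.test(a)$p.value else 0
  sw_b <- if (stats::sd(b) > 0) stats::shapiro.test(b)$p.value else 0
  normal <- sw_a >= shapiro_alpha && sw_b >= shapiro_alpha
  if (normal) {
    ht <- stats::t.test(a, b, alternative = alternative, var.equal = !welch)
    test <- "t"
  } else {
    ht <- stats::wilcox.test(a, b, alternative = alternative, exact = FALSE,
                             correct = TRUE)
    test <- "rank-sum"
  }
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p = ht$p.value,
                 tails = if (alternative == "two.sided") 2L else 1L,
                 n_a = length(a), n_b = length(b),
                 shapiro_p_a = sw_a, shapiro_p_b = sw_b)
}

#' Pearson or Spearman correlation with optional one-tailed p
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` — the
#'   hypothesised direction must be stated explicitly for one-tailed use.
#' @return One-row tibble: `method`, `estimate`, `p`, `tails`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 4) {
    stop("Need equal-length vectors with n >= 4.", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Constant input; correlation undefined.", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = method, alternative = alternative,
                        exact = FALSE)
  tibble::tibble(method = method, estimate = unname(ht$estimate),
                 p = ht$p.value,
                 tails = if (alternative == "two.sided") 2L else 1L,
                 n = length(x))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates; the p-value uses a t approximation with
#' `n - 2 - k` degrees of freedom (k = number of covariates).
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @return One-row tibble: `method` ("partial-pearson"), `estimate`, `p`,
#'   `tails`, `n`, `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates) {
  z <- as.matrix(as.data.frame(covariates))
  storage.mode(z) <- "double"
  n <- length(x)
  k <- ncol(z)
  if (length(y) != n || nrow(z) != n) stop("Lengths differ.", call. = FALSE)
  if (n <= k + 3) stop("Need n > number of covariates + 3.", call. = FALSE)
  design <- cbind(1, z)
  if (qr(design)$rank < ncol(design)) stop("Collinear covariates.", call. = FALSE)
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1)) {
    stop("`x` is fully explained by the covariates; partial correlation undefined.",
         call. = FALSE)
  }
  # y collinear with a covariate: nothing of y is left to correlate
  r <- if (stats::sd(ry) < 1e-10 * max(stats::sd(y), 1)) 0 else stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(method = "partial-pearson", estimate = r, p = p, tails = 2L,
                 n = n, n_covariates = k)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorted p-values `p(i)` are adjusted to `max_{j<=i} (m - j + 1) p(j)`,
#' capped at 1, and returned in the original order. Identical to
#' `p.adjust(method = "holm")`; exposed under the analysis's own name.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Compare linear models over nested/alternative predictor sets
#'
#' Ordinary least squares of the outcome on each predictor set; reports
#' each model's R-squared, coefficients, and every predictor's unique
#' contribution (the drop in R-squared when that predictor is removed from
#' the set).
#'
#' @param data Data frame holding the outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param predictor_sets Named list of character vectors, one per model.
#' @return A tibble with one row per model: `model`, `predictors`,
#'   `r_squared`, `adj_r_squared`, `n`, and a list-column `terms` (tibbles
#'   with `term`, `estimate`, `p`, `delta_r2`).
#' @export
joint_linear_models <- function(data, outcome, predictor_sets) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (is.null(names(predictor_sets))) {
    names(predictor_sets) <- purrr::map_chr(predictor_sets, paste, collapse = "+")
  }
  purrr::imap_dfr(predictor_sets, function(preds, label) {
    stopifnot(all(preds %in% names(data)))
    n <- nrow(data)
    if (n <= length(preds) + 2) stop("Too few observations.", call. = FALSE)
    X <- as.matrix(data[preds])
    if (qr(cbind(1, X))$rank < length(preds) + 1) {
      stop(sprintf("Rank-deficient design in model '%s'.", label), call. = FALSE)
    }
    fml <- stats::reformulate(preds, response = outcome)
    fit <- stats::lm(fml, data = data)
    smry <- summary(fit)
    r2 <- smry$r.squared
    terms <- purrr::map_dfr(preds, function(p) {
      reduced <- setdiff(preds, p)
      r2_red <- if (length(reduced) == 0) 0 else {
        summary(stats::lm(stats::reformulate(reduced, response = outcome),
                          data = data))$r.squared
      }
      tibble::tibble(term = p,
                     estimate = unname(stats::coef(fit)[p]),
                     p = smry$coefficients[p, "Pr(>|t|)"],
                     delta_r2 = r2 - r2_red)
    })
    tibble::tibble(model = label, predictors = paste(preds, collapse = " + "),
                   r_squared = r2, adj_r_squared = smry$adj.r.squared,
                   n = n, terms = list(terms))
  })
}

# 26-connected components of a 3D logical array via igraph.
label_clusters_26 <- function(mask3d) {
  dims <- dim(mask3d)
  labels <- array(0L, dims)
  idx <- which(mask3d)
  if (length(idx) == 0) return(labels)
  coord <- arrayInd(idx, dims)
  key <- function(co) (co[, 3] - 1) * dims[1] * dims[2] + (co[, 2] - 1) * dims[1] + co[, 1]
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  edges <- list()
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(coord, 2, shifts[s, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_idx <- key(nb[ok, , drop = FALSE])
    from <- pos[idx[ok]]
    to <- pos[nb_idx]
    keep <- to > 0
    if (any(keep)) edges[[length(edges) + 1]] <- cbind(from[keep], to[keep])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(edges, list(cbind(seq_along(idx), seq_along(idx))))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  labels[idx] <- as.integer(comp)
  labels
}

# Per-voxel pooled two-sample t over stacked subject maps (4D: x,y,z,subject).
voxel_t_map <- function(arr_a, arr_b) {
  da <- dim(arr_a); db <- dim(arr_b)
  stopifnot(length(da) == 4, all(da[1:3] == db[1:3]))
  na <- da[4]; nb <- db[4]
  nv <- prod(da[1:3])
  ma <- matrix(arr_a, nv, na); mb <- matrix(arr_b, nv, nb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  va <- rowSums((ma - mean_a)^2) / (na - 1)
  vb <- rowSums((mb - mean_b)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tval <- (mean_a - mean_b) / sqrt(sp2 * (1 / na + 1 / nb))
  tval[!is.finite(tval)] <- 0
  array(tval, da[1:3])
}

max_cluster_size <- function(tmap, tcrit) {
  labels <- label_clusters_26(abs(tmap) > tcrit)
  if (max(labels) == 0) return(0L)
  max(tabulate(labels[labels > 0]))
}

#' Voxel-wise two-group t-test with cluster-extent correction
#'
#' Per-voxel pooled two-sample t-maps thresholded at the voxel-level p,
#' followed by 26-connected clustering. Clusters survive if their size
#' reaches the extent threshold: either user-supplied, or estimated as the
#' 95th percentile of the maximum null cluster size under group-label
#' permutation (a self-contained, assumption-light replacement for
#' Gaussian-random-field cluster correction).
#'
#' @param maps_a,maps_b 4D arrays `(x, y, z, subject)`, >= 3 subjects per
#'   group, common grid.
#' @param voxel_p Voxel-level two-sided threshold (default 0.05).
#' @param extent Minimum cluster size in voxels; `NULL` estimates it by
#'   permutation.
#' @param n_perm Number of label permutations when `extent` is `NULL`.
#' @param cluster_alpha Cluster-wise significance for the permutation
#'   threshold (default 0.05).
#' @return A list of class `nf_voxelstat`: `t_map`, `t_crit`, `labels`
#'   (cluster-label array over surviving clusters), `clusters` (tibble
#'   with `cluster`, `size`, `peak_t`), `extent`, `voxel_p`.
#' @export
voxelwise_test <- function(maps_a, maps_b, voxel_p = 0.05, extent = NULL,
                           n_perm = 500, cluster_alpha = 0.05) {
  da <- dim(maps_a); db <- dim(maps_b)
  if (length(da) != 4 || length(db) != 4 || !all(da[1:3] == db[1:3])) {
    stop("Group maps must be 4D arrays on a common grid.", call. = FALSE)
  }
  na <- da[4]; nb <- db[4]
  if (na < 3 || nb < 3) stop("Need >= 3 subjects per group.", call. = FALSE)
  df <- na + nb - 2
  tcrit <- stats::qt(1 - voxel_p / 2, df)
  tmap <- voxel_t_map(maps_a, maps_b)

  if (is.null(extent)) {
    nv <- prod(da[1:3])
    all_maps <- array(c(maps_a, maps_b), c(da[1:3], na + nb))
    null_max <- vapply(seq_len(n_perm), function(i) {
      perm <- sample(na + nb)
      pa <- all_maps[, , , perm[seq_len(na)], drop = FALSE]
      pb <- all_maps[, , , perm[na + seq_len(nb)], drop = FALSE]
      max_cluster_size(voxel_t_map(pa, pb), tcrit)
    }, integer(1))
    extent <- as.integer(stats::quantile(null_max, 1 - cluster_alpha, type = 1)) + 1L
  }

  labels <- label_clusters_26(abs(tmap) > tcrit)
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  surviving <- which(sizes >= extent)
  out_labels <- array(0L, da[1:3])
  clusters <- tibble::tibble(cluster = integer(), size = integer(),
                             peak_t = numeric())
  for (j in seq_along(surviving)) {
    vox <- labels == surviving[j]
    out_labels[vox] <- j
    clusters <- dplyr::bind_rows(clusters, tibble::tibble(
      cluster = j, size = sum(vox), peak_t = tmap[vox][which.max(abs(tmap[vox]))]))
  }
  structure(list(t_map = tmap, t_crit = tcrit, labels = out_labels,
                 clusters = clusters, extent = extent, voxel_p = voxel_p),
            class = "nf_voxelstat")
}

#' @export
print.nf_voxelstat <- function(x, ...) {
  cat(sprintf("Voxel-wise t-test: |t| > %.3f (p < %g), extent >= %d voxels\n",
              x$t_crit, x$voxel_p, x$extent))
  if (nrow(x$clusters) == 0) {
    cat("  no surviving clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}
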