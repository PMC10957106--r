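#' Cluster grid cells into phyloregions
#'
#' Agglomerative clustering of a pairwise dissimilarity matrix via the
#' Lance-Williams recursion (`stats::hclust`). Undefined pairs are imputed
#' with the matrix maximum before clustering (keeps cells rather than
#' dropping them, biasing toward separation). `ward` applies the Ward
#' recursion to squared input dissimilarities (the "ward.D2" contract);
#' `ward_variant = "raw"` uses unsquared dissimilarities ("ward.D").
#'
#' @param D symmetric dissimilarity matrix (or `dist`), zero diagonal.
#' @param method `"ward"` or `"upgma"`.
#' @param k_range cluster counts to cut at (default 2:8, capped at n-1).
#' @param ward_variant `"squared"` (default) or `"raw"`.
#' @return object of class `phyloregionalization`: list with `hclust`,
#'   `labels` (cells x k matrix, columns `k2..k8`), `method`,
#'   `cophenetic_r`.
#' @export
cluster_cells <- function(D, method = c("ward", "upgma"), k_range = 2:8,
                          ward_variant = c("squared", "raw")) {
  method <- match.arg(method)
  ward_variant <- match.arg(ward_variant)
  M <- as.matrix(D)
  stopifnot(isSymmetric(unname(M)), all(abs(diag(M)) < 1e-12))
  off <- M[upper.tri(M)]
  if (anyNA(off)) {
    mx <- max(off, na.rm = TRUE)
    if (!is.finite(mx)) stop("all pairs undefined; cannot cluster")
    message(sum(is.na(off)), " undefined pairs imputed with matrix maximum")
    M[is.na(M)] <- mx
    diag(M) <- 0
  }
  d <- stats::as.dist(M)
  hm <- switch(method, ward = if (ward_variant == "squared") "ward.D2" else "ward.D",
               upgma = "average")
  hc <- stats::hclust(d, method = hm)
  ks <- k_range[k_range <= attr(d, "Size") - 1L & k_range >= 2L]
  labels <- sapply(ks, function(k) stats::cutree(hc, k))
  labels <- matrix(labels, ncol = length(ks),
                   dimnames = list(rownames(M), paste0("k", ks)))
  structure(list(hclust = hc, labels = labels, method = method,
                 cophenetic_r = cophenetic_correlation(hc, d)),
            class = "phyloregionalization")
}

#' Cophenetic correlation of a dendrogram with its input distances
#'
#' @param hc an `hclust` object.
#' @param D the dissimilarity matrix or `dist` it was built from.
#' @return Pearson correlation over all pairs, in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(hc, D) {
  stats::cor(as.vector(stats::cophenetic(hc)), as.vector(stats::as.dist(D)))
}

#' Choose between Ward and UPGMA by cophenetic correlation
#'
#' Fits both candidate algorithms and reports their cophenetic correlations;
#' UPGMA maximises it by construction but can yield highly unbalanced
#' regions, which is why the cluster balance (size of the largest k=2
#' cluster) is reported alongside.
#'
#' @inheritParams cluster_cells
#' @return list with both `phyloregionalization`s, their cophenetic
#'   correlations, and largest-cluster fractions at k = 2.
#' @export
select_clustering <- function(D, k_range = 2:8) {
  fits <- list(ward = cluster_cells(D, "ward", k_range),
               upgma = cluster_cells(D, "upgma", k_range))
  bal <- vapply(fits, function(f) max(table(f$labels[, 1])) / nrow(f$labels),
                numeric(1))
  list(fits = fits,
       cophenetic_r = vapply(fits, `[[`, numeric(1), "cophenetic_r"),
       largest_cluster_fraction_k2 = bal)
}

# Dunn's post hoc z-tests on pooled mid-ranks with tie correction
dunn_test <- function(values, groups) {
  g <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group_i = lev[pairs[1, ]], group_j = lev[pairs[2, ]],
             z = z, p_raw = p_raw,
             p_adj = stats::p.adjust(p_raw, "bonferroni"))
}

#' Climatic distinctness tests between clusters
#'
#' For two clusters a two-sided Wilcoxon rank sum test; for more, a
#' Kruskal-Wallis rank sum test followed (when significant at `alpha`) by
#' Dunn's pairwise z-tests with Bonferroni adjustment. A cluster counts as
#' climatically distinct when it differs significantly from every other
#' cluster.
#'
#' @param labels cluster label per cell.
#' @param values climate variable per cell (same length).
#' @param alpha significance level (default 0.05).
#' @return list with `test` ("wilcoxon" or "kruskal"), `p_value`, `dunn`
#'   (data.frame or NULL), `n_distinct`.
#' @export
cluster_climate_tests <- function(labels, values, alpha = 0.05) {
  g <- as.factor(labels)
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2))
  if (nlevels(g) == 2L) {
    # exact null for small tie-free samples, normal approximation otherwise
    p <- suppressWarnings(stats::wilcox.test(values ~ g)$p.value)
    return(list(test = "wilcoxon", p_value = p, dunn = NULL,
                n_distinct = if (p < alpha) 2L else 0L))
  }
  p <- stats::kruskal.test(values, g)$p.value
  dunn <- NULL; n_distinct <- 0L
  if (is.finite(p) && p < alpha) {
    dunn <- dunn_test(values, g)
    sig <- dunn$p_adj < alpha
    n_distinct <- sum(vapply(levels(g), function(l) {
      rows <- dunn$group_i == l | dunn$group_j == l
      all(sig[rows])
    }, logical(1)))
  }
  list(test = "kruskal", p_value = p, dunn = dunn, n_distinct = n_distinct)
}
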