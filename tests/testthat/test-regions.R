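block_matrix <- function(n1 = 5, n2 = 5, within = 0.1, between = 0.9,
                         jitter = 0, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  M <- matrix(between, n, n)
  M[seq_len(n1), seq_len(n1)] <- within
  M[(n1 + 1):n, (n1 + 1):n] <- within
  J <- matrix(stats::runif(n * n, 0, jitter), n, n)
  M <- M + (J + t(J)) / 2   # tie-free but block structure preserved
  diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("c", seq_len(n))
  M
}

test_that("well-separated blocks are recovered exactly at k = 2", {
  M <- block_matrix()
  for (m in c("ward", "upgma")) {
    reg <- cluster_cells(M, m)
    lab <- reg$labels[, "k2"]
    expect_equal(rand_index(lab, rep(1:2, each = 5)), 1)
  }
})

test_that("merge order matches a hand Lance-Williams computation", {
  set.seed(5)
  M <- matrix(0, 6, 6)
  M[upper.tri(M)] <- c(2, 6, 10, 9, 3, 5, 9, 8, 4, 7, 5, 11, 10, 8, 3)
  M <- M + t(M)
  rownames(M) <- colnames(M) <- paste0("c", 1:6)
  for (variant in c("ward2", "upgma")) {
    method <- if (variant == "ward2") "ward" else "upgma"
    hc <- cluster_cells(M, method)$hclust
    or <- oracle_lance_williams(M, variant)
    expect_identical(hclust_merge_sets(hc), or$merges)
    expect_equal(unname(hc$height), or$heights, tolerance = 1e-10)
  }
})

test_that("UPGMA chains into one dominant cluster where Ward stays balanced", {
  # near-uniform dissimilarities: UPGMA accretes cells onto one growing blob
  # while Ward's size penalty keeps groups even
  set.seed(6)
  n <- 16
  J <- matrix(stats::runif(n * n, 0, 0.2), n, n)
  M <- 1 + (J + t(J)) / 2
  diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("c", seq_len(n))
  up <- cluster_cells(M, "upgma")$labels[, "k4"]
  wd <- cluster_cells(M, "ward")$labels[, "k4"]
  expect_gt(max(table(up)), max(table(wd)))
})

test_that("cophenetic correlation is exact for ultrametric input and bounded", {
  # an ultrametric distance matrix is reproduced perfectly by UPGMA
  tr <- ape::rcoal(8)
  M <- ape::cophenetic.phylo(tr)
  reg <- cluster_cells(M, "upgma")
  expect_equal(reg$cophenetic_r, 1, tolerance = 1e-10)
  set.seed(2)
  R <- block_matrix(4, 4, jitter = 0.5, seed = 3)
  for (m in c("ward", "upgma"))
    expect_true(abs(cluster_cells(R, m)$cophenetic_r) <= 1)
  # direct pairwise recomputation on a 6-point fixture
  M6 <- block_matrix(3, 3, seed = 4)
  hc <- cluster_cells(M6, "upgma")$hclust
  r_direct <- stats::cor(as.vector(stats::cophenetic(hc)),
                         as.vector(stats::as.dist(M6)))
  expect_equal(cophenetic_correlation(hc, M6), r_direct)
})

test_that("cluster labels are invariant to cell ordering", {
  M <- block_matrix(6, 6, jitter = 0.3, seed = 9)
  reg1 <- cluster_cells(M, "ward")
  set.seed(1)
  perm <- sample(nrow(M))
  reg2 <- cluster_cells(M[perm, perm], "ward")
  for (k in colnames(reg1$labels)) {
    l1 <- reg1$labels[rownames(M), k]
    l2 <- reg2$labels[rownames(M), k]
    expect_equal(rand_index(l1, l2), 1)
  }
})

test_that("undefined pairs are imputed with the maximum before clustering", {
  M <- block_matrix()
  M[1, 8] <- M[8, 1] <- NA
  expect_message(reg <- cluster_cells(M, "ward"), "imputed")
  expect_equal(rand_index(reg$labels[, "k2"], rep(1:2, each = 5)), 1)
})

test_that("climate tests separate offset clusters and adjust Dunn p-values", {
  set.seed(8)
  vals <- c(stats::rnorm(50), stats::rnorm(50, 5))
  out <- cluster_climate_tests(rep(1:2, each = 50), vals)
  expect_identical(out$test, "wilcoxon")
  expect_lt(out$p_value, 0.001)
  expect_equal(out$n_distinct, 2L)

  vals3 <- c(stats::rnorm(40), stats::rnorm(40, 4), stats::rnorm(40, 8))
  out3 <- cluster_climate_tests(rep(1:3, each = 40), vals3)
  expect_identical(out3$test, "kruskal")
  expect_lt(out3$p_value, 1e-6)
  expect_true(all(out3$dunn$p_adj >= out3$dunn$p_raw - 1e-15))
  expect_true(all(out3$dunn$p_adj <= 1))
  expect_equal(out3$n_distinct, 3L)
})

test_that("the two-sample test matches the exact rank-sum null for tiny samples", {
  # tie-free samples with n <= 8 use the exact Wilcoxon distribution
  x <- c(1.2, 3.4, 5.1, 7.7); y <- c(2.2, 4.9, 6.3)
  p_pkg <- cluster_climate_tests(c(1, 1, 1, 1, 2, 2, 2), c(x, y))$p_value
  # brute-force enumeration over all assignments of ranks to group 1
  r <- rank(c(x, y))
  W_obs <- sum(r[1:4]) - 4 * 5 / 2
  combos <- utils::combn(7, 4)
  W_null <- apply(combos, 2, function(ix) sum(seq_len(7)[ix]) - 10)
  p_exact <- mean(abs(W_null - 6) >= abs(W_obs - 6))  # mean of null = n1*n2/2
  expect_equal(p_pkg, p_exact)
})
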