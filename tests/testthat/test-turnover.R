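test_that("Simpson and Sorensen pair formulas behave as stated", {
  expect_equal(simpson_turnover(2, 1, 3), 1 / 3)
  expect_equal(simpson_turnover(5, 0, 0), 0)          # identical cells
  expect_equal(simpson_turnover(3, 0, 10), 0)         # nested: richness-blind
  expect_true(is.na(simpson_turnover(0, 0, 4)))       # undefined pair
  expect_equal(sorensen_dissimilarity(2, 1, 3), 4 / 8)
  # Simpson <= Sorensen on random components
  set.seed(1)
  for (i in 1:200) {
    abc <- stats::runif(3, 0, 10)
    s1 <- simpson_turnover(abc[1], abc[2], abc[3])
    s2 <- sorensen_dissimilarity(abc[1], abc[2], abc[3])
    expect_true(s1 <= s2 + 1e-12 && s1 >= 0 && s2 <= 1)
  }
})

test_that("reverse PBD deviation is signed and monotone in PBD", {
  expect_equal(pbd_dev_reverse(0.4, 0.4), 0)
  expect_equal(pbd_dev_reverse(0.5, 0.25), -0.5)
  expect_true(is.na(pbd_dev_reverse(0, 0.2)))
  pbds <- seq(0, 1, 0.1)
  vals <- vapply(pbds, function(p) pbd_dev_reverse(0.6, p), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("phylogenetic components reduce to taxonomic Simpson on star trees", {
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, 6)
  set.seed(4)
  for (i in 1:30) {
    si <- sample(star$tip.label, sample(2:5, 1))
    sj <- sample(star$tip.label, sample(2:5, 1))
    pc <- phylo_components(star, si, sj)
    a <- length(intersect(si, sj)); b <- length(setdiff(si, sj))
    c <- length(setdiff(sj, si))
    expect_equal(pc$a, a); expect_equal(pc$b, b); expect_equal(pc$c, c)
  }
  pc <- phylo_components(star, c("t1", "t2"), c("t2", "t3"))
  expect_equal(simpson_turnover(pc$a, pc$b, pc$c), 0.5)
  same <- phylo_components(star, c("t1", "t2"), c("t1", "t2"))
  expect_equal(same$b + same$c, 0)
})

test_that("components match the per-branch classification oracle", {
  set.seed(11)
  for (r in 1:30) {
    tr <- random_ultra_tree(sample(6:20, 1))
    si <- sample(tr$tip.label, sample(2:4, 1))
    sj <- sample(tr$tip.label, sample(2:4, 1))
    pc <- phylo_components(tr, si, sj)
    or <- oracle_phylo_components(tr, si, sj)
    expect_equal(pc$a, or$a, tolerance = 1e-12)
    expect_equal(pc$b, or$b, tolerance = 1e-12)
    expect_equal(pc$c, or$c, tolerance = 1e-12)
  }
})

make_test_grid <- function(seed = 9, n_tips = 25) {
  cfg <- sim_config(n_tips = n_tips, trait_sigma2 = 5e3, root_state = 1800,
                    seed = seed)
  dat <- simulate_dataset(cfg)
  grid <- grid_occurrences(dat$landscape$occurrences)
  grid <- apply_filters(grid, min_taxa = 3)
  clim <- data.frame(lon = dat$landscape$cells$lon,
                     lat = dat$landscape$cells$lat,
                     MAP = dat$landscape$cells$map)
  list(grid = attach_climate(grid, clim), tree = dat$tree)
}

test_that("pairwise tables are symmetric, bounded and carry haversine distances", {
  tg <- make_test_grid()
  tab <- pairwise_table(tg$grid, tg$tree)
  mets <- c("taxonomic_sim", "taxonomic_sorensen", "phylo_sim", "phylo_sorensen")
  for (m in mets) expect_true(all(tab[[m]] >= 0 & tab[[m]] <= 1, na.rm = TRUE))
  expect_true(all(tab$taxonomic_sim <= tab$taxonomic_sorensen + 1e-12, na.rm = TRUE))
  expect_true(all(tab$phylo_sim <= tab$phylo_sorensen + 1e-12, na.rm = TRUE))
  expect_equal(nrow(tab), choose(nrow(tg$grid$cells), 2))
  # symmetry: the matrix form mirrors exactly
  M <- dissim_matrix(tab, "phylo_sim")
  expect_identical(M, t(M))
  # two cells one degree apart on the equator
  d <- geosphere::distHaversine(c(0, 0), c(1, 0), r = 6371000) / 1000
  expect_equal(d, 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(d, 111.1949, tolerance = 1e-4)
})

test_that("ancient mode at cutoff zero equals the full table and coarsens monotonically", {
  tg <- make_test_grid()
  tab_full <- pairwise_table(tg$grid, tg$tree)
  tab_anc0 <- pairwise_table(tg$grid, tg$tree, mode = "ancient", cutoff = 0)
  expect_equal(tab_anc0$phylo_sim, tab_full$phylo_sim)
  # nested-lineage fixture: slicing above the cherries merges each cell's
  # unique tips into shared lineages, so deep turnover cannot exceed shallow
  tr <- ape::read.tree(text = "((a:5,b:5):15,(c:5,d:5):15);")
  full <- phylo_components(tr, c("a", "c"), c("b", "d"))
  s_full <- simpson_turnover(full$a, full$b, full$c)
  sl <- slice_tree_at(tr, 10)
  to_lin <- function(tips) unique(names(Filter(function(v) any(tips %in% v),
                                               sl$lineages)))
  deep <- phylo_components(sl$tree, to_lin(c("a", "c")), to_lin(c("b", "d")))
  s_deep <- simpson_turnover(deep$a, deep$b, deep$c)
  expect_lte(if (is.na(s_deep)) 0 else s_deep, s_full + 1e-12)
  expect_gt(s_full, 0)
})
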