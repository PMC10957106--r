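test_that("birth-death trees are ultrametric, binary, sized and reproducible", {
  cfg <- sim_config(n_tips = 50, seed = 3)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 50)
  expect_true(ape::is.binary(tr))
  expect_true(check_ultrametric(tr, 1e-9))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(cfg)))

  t2 <- simulate_tree(sim_config(n_tips = 2, seed = 7))
  expect_equal(t2$Nnode, 1L)
  expect_equal(t2$edge.length[1], t2$edge.length[2])
})

test_that("tree simulator matches an independent birth-death sampler on gamma", {
  n_rep <- 120
  mine <- vapply(seq_len(n_rep), function(r)
    ape::gammaStat(simulate_tree(sim_config(n_tips = 100, seed = 900 + r))),
    numeric(1))
  set.seed(1)
  ref <- vapply(seq_len(n_rep), function(r)
    ape::gammaStat(ape::rphylo(100, birth = 0.3, death = 0.1)), numeric(1))
  se <- sqrt(stats::var(mine) / n_rep + stats::var(ref) / n_rep)
  expect_lt(abs(mean(mine) - mean(ref)), 4 * se)
})

test_that("lambda-transformed Brownian traits have the stated covariance", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  C <- matrix(c(2, 1, 0, 0,
                1, 2, 0, 0,
                0, 0, 2, 1,
                0, 0, 1, 2), 4, 4, byrow = TRUE)
  sims <- t(vapply(seq_len(2000), function(r)
    simulate_bm_trait(tr, 1, 1, 0, seed = r)[1:4], numeric(4)))
  expect_lt(max(abs(stats::cov(sims) - C)), 0.25)

  # lambda = 0: off-diagonal covariance vanishes, variance = depth
  sims0 <- t(vapply(seq_len(2000), function(r)
    simulate_bm_trait(tr, 1, 0, 0, seed = 5000 + r)[1:4], numeric(4)))
  C0 <- stats::cov(sims0)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.2)
  expect_lt(max(abs(diag(C0) - 2)), 0.25)

  # degenerate: zero variance collapses to the root state
  expect_true(all(simulate_bm_trait(tr, 0, 1, 7, seed = 1) == 7))
  expect_error(simulate_bm_trait(tr, -1, 1, 0), "non-negative")
})

test_that("trait variance grows linearly with tree depth", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  depths <- 1:5
  vars <- vapply(depths, function(s) {
    trs <- tr; trs$edge.length <- trs$edge.length * s / 2
    stats::var(vapply(seq_len(1000), function(r)
      simulate_bm_trait(trs, 1, 1, 0, seed = 7000 * s + r)[1], numeric(1)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(vars ~ depths))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("imposed shifts offset exactly the descendant subtree", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  st <- stats::setNames(rep(1000, 7), c("a", "b", "c", "d",
                                        paste0("node_", 5:7)))
  expect_identical(impose_niche_shifts(tr, st, NULL)$states, st)
  # node 6 subtends a and b
  sh <- impose_niche_shifts(tr, st, data.frame(node = 6, delta = 900))
  expect_equal(unname(sh$states[c("a", "b")]), c(1900, 1900))
  expect_equal(unname(sh$states[c("c", "d", "node_5", "node_7")]),
               rep(1000, 4))
  expect_equal(sh$true_shift_nodes, 6L)
})

test_that("Mk histories match the 2-state transition probability and are seeded", {
  tr2 <- ape::read.tree(text = "(a:1.5,b:1.5);")
  Q <- matrix(c(-0.4, 0.4, 0.2, -0.2), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("s1", "s2")))
  flips <- vapply(seq_len(2500), function(r)
    simulate_mk_history(tr2, Q, 1, seed = r)$tip_states, character(2))
  p_change <- mean(flips != "s1")
  expect_lt(abs(p_change - phyloturn:::expm_rate(Q, 1.5)[1, 2]), 0.02)

  tr <- random_ultra_tree(20)
  h1 <- simulate_mk_history(tr, Q, 1, seed = 5)
  h2 <- simulate_mk_history(tr, Q, 1, seed = 5)
  expect_identical(h1, h2)

  q0 <- matrix(0, 2, 2, dimnames = dimnames(Q))
  h0 <- simulate_mk_history(tr, q0, 2, seed = 1)
  expect_true(all(h0$tip_states == "s2"))
  expect_equal(nrow(h0$events), 0L)
})

test_that("landscape occurrences respect the extent and track species niches", {
  cfg <- sim_config(n_tips = 30, spatial_noise_deg = 0, seed = 2)
  tr <- simulate_tree(cfg)
  st <- simulate_bm_trait(tr, cfg$trait_sigma2, 1, cfg$root_state, seed = 2)
  land <- simulate_landscape_and_occurrences(tr, st[1:30], cfg)
  ex <- cfg$landscape_extent
  expect_true(all(land$occurrences$lon >= ex[1] & land$occurrences$lon < ex[2]))
  expect_true(all(land$occurrences$lat >= ex[3] & land$occurrences$lat < ex[4]))
  # zero spatial noise: every occurrence sits in a cell whose MAP is within
  # one gradient step of the species' trait
  cell_map <- land$cells$map[match(
    paste0(floor(land$occurrences$lon / 0.5), "_", floor(land$occurrences$lat / 0.5)),
    paste0(floor(land$cells$lon / 0.5), "_", floor(land$cells$lat / 0.5)))]
  traits <- st[land$occurrences$taxon]
  expect_true(all(abs(cell_map - traits) <= land$gradient_step + 1e-9 |
                    traits < min(land$cells$map) | traits > max(land$cells$map)))
  # monthly layers are consistent with MAP and the DSL ground truth
  expect_equal(rowSums(land$monthly), land$cells$map, tolerance = 1e-9)
  expect_equal(apply(land$monthly, 1, dry_season_length),
               land$cells$dsl_true)
})
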