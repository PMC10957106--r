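#' Square dissimilarity matrix from a pairwise table
#'
#' @param table a `dissimilarity_table`.
#' @param column which dissimilarity column to use.
#' @return symmetric matrix with zero diagonal, cells as dimnames.
#' @export
dissim_matrix <- function(table, column = "phylo_sim") {
  cells <- sort(unique(c(table$cell_i, table$cell_j)))
  M <- matrix(NA_real_, length(cells), length(cells),
              dimnames = list(cells, cells))
  diag(M) <- 0
  i <- match(table$cell_i, cells); j <- match(table$cell_j, cells)
  M[cbind(i, j)] <- table[[column]]
  M[cbind(j, i)] <- table[[column]]
  M
}

#' Rand index between two partitions
#' @param a,b label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' Two-band landscape phyloregionalization experiment
#'
#' Simulates a tree whose two root clades are forced into disjoint
#' precipitation niches (a dry and a wet band), grids their occurrences,
#' computes phylogenetic Simpson turnover and checks whether k = 2 Ward
#' clustering recovers the true climatic bands.
#'
#' @param seed integer seed.
#' @param n_tips tips per tree.
#' @param band_offset niche offset in mm imposed on one root clade.
#' @return list with `rand`, `grid`, `labels`, `truth`.
#' @export
experiment_two_band <- function(seed, n_tips = 60, band_offset = 1800) {
  # both root clades must be populous enough that their climate bands pass
  # the downstream 3-taxon richness filter; resample until the root split is
  # reasonably balanced (deterministic in `seed`)
  ntip <- NULL
  for (attempt in 0:49) {
    cfg <- sim_config(n_tips = n_tips, trait_sigma2 = 5e3, root_state = 1000,
                      map_range = c(200, 3800), spatial_noise_deg = 0.15,
                      seed = seed + 100000L * attempt)
    tree <- simulate_tree(cfg)
    ntip <- ape::Ntip(tree)
    root_kids <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
    sizes <- vapply(root_kids, function(k) {
      if (k <= ntip) 1L else length(descendant_nodes(tree)[[k]])
    }, integer(1))
    if (min(sizes) >= 0.25 * ntip) break
  }
  states <- simulate_bm_trait(tree, cfg$trait_sigma2, 1, cfg$root_state,
                              seed = cfg$seed)
  sh <- impose_niche_shifts(tree, states,
                            data.frame(node = root_kids[1], delta = band_offset))
  tips <- sh$states[seq_len(ntip)]
  land <- simulate_landscape_and_occurrences(tree, tips, cfg)
  grid <- grid_occurrences(land$occurrences)
  grid <- apply_filters(grid, min_taxa = 3)
  tab <- pairwise_table(grid, tree)
  M <- dissim_matrix(tab, "phylo_sim")
  reg <- cluster_cells(M, "ward")
  truth <- land$cells$cluster_true[
    match(rownames(M), paste0(floor(land$cells$lon / 0.5), "_",
                              floor(land$cells$lat / 0.5)))]
  list(rand = rand_index(unname(reg$labels[, "k2"]), truth), grid = grid,
       labels = reg$labels[, "k2"], truth = truth, table = tab, tree = tree)
}

#' Imposed niche-shift recovery experiment
#'
#' Simulates Brownian MAP evolution, imposes `n_shifts` regime shifts on
#' random branches (each shift moves the subtree into the core of the
#' opposite precipitation regime, so category boundaries are crossed with
#' `|delta| >= delta_min`), reconstructs ancestral states from the tip
#' values alone and measures how many imposed shifts the category-change
#' detector recovers. Sensitivity is reported both strictly (the exact
#' branch flagged) and at event level (the true branch or one immediately
#' adjacent flagged), since a jump on a short branch is only weakly
#' localisable from smoothed endpoint states.
#'
#' @param seed integer seed.
#' @param n_tips tips per tree.
#' @param n_shifts imposed shifts per tree.
#' @param delta_min minimum absolute imposed offset (mm).
#' @return list with `sensitivity_strict`, `sensitivity_event`,
#'   `false_positive_rate` (detections not adjacent to any true shift, over
#'   clean branches), `n_detected`.
#' @export
experiment_shift_recovery <- function(seed, n_tips = 100, n_shifts = 10,
                                      delta_min = 750) {
  cfg <- sim_config(n_tips = n_tips, trait_sigma2 = 2e3, root_state = 1500,
                    seed = seed)
  tree <- simulate_tree(cfg)
  states <- simulate_bm_trait(tree, cfg$trait_sigma2, 1, cfg$root_state,
                              seed = cfg$seed)
  ntip <- ape::Ntip(tree)
  set.seed(seed + 10L)
  pool <- sample(tree$edge[, 2])
  picked <- integer(0); deltas <- numeric(0)
  for (nd in pool) {
    if (length(picked) == n_shifts) break
    base <- states[nd]
    tgt <- if (base >= 1500) stats::runif(1, 300, 700) else
      stats::runif(1, 2300, 2700)
    dl <- tgt - base
    if (abs(dl) < delta_min) next
    picked <- c(picked, nd); deltas <- c(deltas, dl)
  }
  sh <- impose_niche_shifts(tree, states, data.frame(node = picked, delta = deltas))
  tips <- sh$states[seq_len(ntip)]
  asr <- ancestral_states_bm(tree, tips)
  det <- detect_niche_shifts(tree, asr$estimate, niche_category_spec("MAP"))
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  adj <- lapply(picked, function(nd) {
    p <- tree$edge[tree$edge[, 2] == nd, 1]
    unique(c(nd, p, kids_of[[as.character(nd)]], kids_of[[as.character(p)]]))
  })
  near_true <- unique(unlist(adj))
  fp <- setdiff(det$child, near_true)
  list(sensitivity_strict = mean(picked %in% det$child),
       sensitivity_event = mean(vapply(adj, function(a) any(a %in% det$child),
                                       logical(1))),
       false_positive_rate = length(fp) / (nrow(tree$edge) - length(near_true)),
       n_detected = nrow(det))
}

#' Pagel's lambda recovery experiment
#'
#' @param lambda_true generating lambda.
#' @param n_reps replicates.
#' @param n_tips tips per tree.
#' @param seed integer seed.
#' @return vector of lambda estimates.
#' @export
experiment_lambda_recovery <- function(lambda_true, n_reps = 200,
                                       n_tips = 200, seed = 1L) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(n_tips = n_tips, lambda_true = lambda_true,
                      trait_sigma2 = 1, root_state = 0,
                      seed = seed + 1000L * r)
    tree <- simulate_tree(cfg)
    x <- simulate_bm_trait(tree, 1, lambda_true, 0, seed = cfg$seed)
    pagels_lambda(tree, x[seq_len(n_tips)])$lambda_hat
  }, numeric(1))
}

#' DEC parameter recovery experiment
#'
#' Trees are rescaled to a 60-Ma crown age (the age scale of a mid-Cenozoic
#' pantropical radiation) and ranges simulated from a widespread ancestor;
#' fitting conditions the likelihood on survival, matching the generator.
#'
#' @param n_reps replicates.
#' @param seed integer seed.
#' @param d_true,e_true generating rates.
#' @param n_tips tips per tree.
#' @return data.frame with one row per replicate: `d_hat`, `e_hat`.
#' @export
experiment_dec_recovery <- function(n_reps = 50, seed = 1L, d_true = 0.02,
                                    e_true = 0.01, n_tips = 100) {
  rs <- range_space(c("A", "B", "C"))
  out <- lapply(seq_len(n_reps), function(r) {
    tree <- simulate_tree(sim_config(n_tips = n_tips, seed = seed + 31L * r))
    tree$edge.length <- tree$edge.length *
      (60 / max(ape::node.depth.edgelength(tree)))
    sim <- simulate_dec_history(tree, rs, d = d_true, e = e_true,
                                root_range = "A;B;C", seed = seed + 77L * r)
    fit <- fit_dec(tree, sim$tip_ranges, rs = rs, condition_survival = TRUE)
    data.frame(d_hat = fit$d, e_hat = fit$e)
  })
  do.call(rbind, out)
}

#' Seeded end-to-end pipeline run
#'
#' Simulates a data set, grids it, computes turnover, fits the GDM variation
#' partition (climate vs geography), clusters phyloregions, detects niche
#' shifts, fits Mk + stochastic maps and DEC, and counts dispersal events.
#' Everything derives from `seed`, so two invocations are bit-identical.
#'
#' @param seed integer seed.
#' @param n_tips tips in the simulated tree.
#' @return list of stage outputs and summary numbers.
#' @export
run_pipeline <- function(seed, n_tips = 60) {
  cfg <- sim_config(n_tips = n_tips, trait_sigma2 = 5e3, root_state = 1800,
                    spatial_noise_deg = 0.2, seed = seed)
  dat <- simulate_dataset(cfg)
  tree <- dat$tree
  ntip <- ape::Ntip(tree)
  land <- dat$landscape
  grid <- grid_occurrences(land$occurrences)
  grid <- apply_filters(grid, min_taxa = 3)
  clim <- data.frame(lon = land$cells$lon, lat = land$cells$lat,
                     MAP = land$cells$map,
                     DSL = apply(land$monthly, 1, dry_season_length))
  grid <- attach_climate(grid, clim)
  tab <- pairwise_table(grid, tree)
  vp <- variation_partition(tab, "phylo_sim",
                            set_A = c("MAP", "DSL"),
                            set_B = "geographic_distance_km")
  gr <- geographic_residuals(tab, "phylo_sim")
  tab$residual_rescaled <- gr$residual_rescaled
  M <- dissim_matrix(tab, "phylo_sim")
  reg <- cluster_cells(M, "ward")
  clim_test <- cluster_climate_tests(reg$labels[, "k2"],
                                     grid$climate$MAP[match(rownames(M), rownames(grid$climate))])
  asr <- ancestral_states_bm(tree, dat$states[seq_len(ntip)])
  shifts <- detect_niche_shifts(tree, asr$estimate, niche_category_spec("MAP"))
  bins <- shifts_per_time_bin(shifts, tree)
  mk_fit <- fit_mk_ard(tree, dat$tip_states_mk)
  maps <- stochastic_maps(mk_fit, tree, dat$tip_states_mk, n = 100,
                          seed = seed + 50L)
  trans <- count_transitions(maps, tree)
  rs <- range_space(c("A", "B", "C"))
  dec_sim <- simulate_dec_history(tree, rs, d = 0.02, e = 0.005,
                                  root_range = "A;B;C", seed = seed)
  dec <- fit_dec(tree, dec_sim$tip_ranges, rs = rs, condition_survival = TRUE)
  decj <- fit_dec(tree, dec_sim$tip_ranges, with_j = TRUE, rs = rs,
                  condition_survival = TRUE)
  av <- aic_average(list(dec = dec, decj = decj))
  decided <- decide_ranges(av$node_probs, rs)
  disp <- count_dispersals(decided, tree,
                           stats::setNames(c("G1", "G2", "G3"), c("A", "B", "C")))
  list(config = cfg, tree = tree, grid = grid, table = tab,
       partition = vp, regionalization = reg, climate_test = clim_test,
       shifts = shifts, shift_bins = bins, mk = mk_fit,
       transitions = trans, dec = dec, decj = decj, aic_weights = av$weights,
       dispersals = disp,
       summary = c(n_cells = nrow(grid$cells), n_pairs = nrow(tab),
                   pct_dev_joint = vp$D_AB,
                   unique_geography = vp$unique_B, unique_climate = vp$unique_A,
                   n_shifts = nrow(shifts), n_transitions = nrow(trans),
                   n_dispersals = nrow(disp)))
}
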