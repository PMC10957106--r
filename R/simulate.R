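#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generators. Defaults are the
#' study conditions used throughout the test suite: a modest birth-death tree,
#' Brownian precipitation niches with strong phylogenetic signal, a slow
#' two-state Mk process, and a one-degree-resolution longitude gradient of
#' mean annual precipitation.
#'
#' @param n_tips number of extant tips.
#' @param birth_rate,death_rate speciation/extinction rates per lineage per Ma.
#' @param trait_sigma2 Brownian variance of the niche trait per Ma (mm^2/Ma
#'   for MAP).
#' @param lambda_true Pagel's lambda used to transform the tree before trait
#'   simulation, in `[0, 1]`.
#' @param mk_rates square rate matrix for the discrete character (rows sum to
#'   0, off-diagonals >= 0), per Ma.
#' @param root_state root value of the continuous trait (mm/yr MAP).
#' @param landscape_extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param map_range `c(min, max)` mm/yr of the longitudinal MAP gradient.
#' @param n_occurrences_per_species occurrence records drawn per species.
#' @param spatial_noise_deg SD in degrees of the jitter added to sampled cell
#'   centers.
#' @param seed integer seed; each generator uses `seed` plus a fixed offset.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_tips = 100, birth_rate = 0.3, death_rate = 0.1,
                       trait_sigma2 = 5e4, lambda_true = 1,
                       mk_rates = matrix(c(-0.05, 0.05, 0.05, -0.05), 2, 2,
                                         byrow = TRUE),
                       root_state = 1500,
                       landscape_extent = c(0, 10, 0, 5),
                       map_range = c(200, 3800),
                       n_occurrences_per_species = 20,
                       spatial_noise_deg = 0.25,
                       seed = 1L) {
  stopifnot(n_tips >= 2, birth_rate > death_rate, death_rate >= 0,
            trait_sigma2 >= 0, lambda_true >= 0, lambda_true <= 1,
            n_occurrences_per_species >= 1,
            landscape_extent[2] > landscape_extent[1],
            landscape_extent[4] > landscape_extent[3])
  stopifnot(all(mk_rates[row(mk_rates) != col(mk_rates)] >= 0),
            all(abs(rowSums(mk_rates)) < 1e-12))
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 death_rate = death_rate, trait_sigma2 = trait_sigma2,
                 lambda_true = lambda_true, mk_rates = mk_rates,
                 root_state = root_state,
                 landscape_extent = landscape_extent, map_range = map_range,
                 n_occurrences_per_species = as.integer(n_occurrences_per_species),
                 spatial_noise_deg = spatial_noise_deg,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a birth-death tree conditioned on its number of extant tips
#'
#' Uses the general sampling approach: the process is grown forward well past
#' `n_tips` extant lineages, a sampling time is drawn uniformly over all time
#' slabs during which exactly `n_tips` lineages were extant, the tree is cut
#' there and extinct lineages pruned. Tips are relabelled `t1..tn`.
#'
#' @param config a [sim_config()].
#' @param max_retries bounded retries when the process dies out.
#' @return ultrametric binary `phylo` with `config$n_tips` tips.
#' @export
simulate_tree <- function(config, max_retries = 200) {
  set.seed(config$seed + 1L)
  for (try in seq_len(max_retries)) {
    tr <- .bd_gsa_once(config$n_tips, config$birth_rate, config$death_rate)
    if (!is.null(tr)) return(tr)
  }
  stop("birth-death simulation failed to reach ", config$n_tips,
       " tips after ", max_retries, " retries")
}

# one attempt of the general sampling approach; NULL on failure
.bd_gsa_once <- function(n, b, d, n_max = max(3L * n, n + 20L)) {
  # lineage bookkeeping: birth time, parent, end time (death), children
  tb <- c(0, 0); parent <- c(NA, 1L); td <- c(NA_real_, NA_real_)
  alive <- c(1L, 2L)
  t <- 0
  slabs <- list()  # (start, end) with exactly n alive
  events <- list() # (time, type, lineage) applied in order, for cutting
  repeat {
    nn <- length(alive)
    if (nn == 0L || nn >= n_max) break
    dt <- stats::rexp(1, nn * (b + d))
    if (nn == n) slabs[[length(slabs) + 1L]] <- c(t, t + dt)
    t <- t + dt
    lin <- alive[sample.int(nn, 1)]
    if (stats::runif(1) < b / (b + d)) {
      id <- length(tb) + 1L
      tb <- c(tb, t); parent <- c(parent, lin); td <- c(td, NA_real_)
      alive <- c(alive, id)
    } else {
      td[lin] <- t
      alive <- setdiff(alive, lin)
    }
  }
  if (length(slabs) == 0L) return(NULL)
  lens <- vapply(slabs, function(s) s[2] - s[1], numeric(1))
  s <- slabs[[sample.int(length(slabs), 1, prob = lens)]]
  u <- stats::runif(1, s[1], s[2])
  .assemble_cut_tree(tb, parent, td, u, n)
}

# build the phylo of all lineages born before u, cut at time u, prune extinct
.assemble_cut_tree <- function(tb, parent, td, u, n) {
  keep <- which(tb < u)
  end <- ifelse(is.na(td[keep]) | td[keep] > u, u, td[keep])
  id_map <- integer(length(tb)); id_map[keep] <- seq_along(keep)
  tb <- tb[keep]; parent <- id_map[parent[keep]]
  children <- vector("list", length(keep))
  for (i in seq_along(keep)) if (!is.na(parent[i]) && parent[i] > 0 && tb[i] > 0)
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  M <- length(keep)
  n_edge <- 2L * (M - 1L)
  edge <- matrix(0L, n_edge, 2); elen <- numeric(n_edge)
  root <- M + 1L; next_node <- M + 2L; n_written <- 0L
  # iterative preorder over (lineage, segment start time, parent node id);
  # the root joins lineages 1 and 2 at time 0
  stack <- list(c(2L, 0, root), c(1L, 0, root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    lin <- fr[1]; t0 <- fr[2]; pnode <- fr[3]
    kids <- children[[lin]]
    kids <- kids[tb[kids] > t0]
    if (length(kids) == 0L) {
      node <- lin; blen <- end[lin] - t0
    } else {
      k <- kids[which.min(tb[kids])]
      node <- next_node; next_node <- next_node + 1L
      blen <- tb[k] - t0
      stack[[length(stack) + 1L]] <- c(lin, tb[k], node)
      stack[[length(stack) + 1L]] <- c(k, tb[k], node)
    }
    if (pnode > 0L) {
      n_written <- n_written + 1L
      edge[n_written, ] <- c(pnode, node); elen[n_written] <- blen
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = paste0("x", seq_len(M)), Nnode = M - 1L),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  extinct <- which(end < u)
  if (length(extinct)) tree <- ape::drop.tip(tree, paste0("x", extinct))
  stopifnot(ape::Ntip(tree) == n)
  tree$tip.label <- paste0("t", seq_len(n))
  tree
}

# lambda transform: scale internal node heights (above the root) by lambda,
# keep tip heights; returns tree with adjusted branch lengths
lambda_transform <- function(tree, lambda) {
  if (lambda == 1) return(tree)
  ntip <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)  # height above root
  hh <- h
  hh[(ntip + 1):(ntip + tree$Nnode)] <- lambda * h[(ntip + 1):(ntip + tree$Nnode)]
  tree$edge.length <- hh[tree$edge[, 2]] - hh[tree$edge[, 1]]
  tree
}

#' Simulate a Brownian trait with Pagel's lambda signal
#'
#' Values evolve by Brownian motion on the lambda-transformed tree (internal
#' node heights multiplied by `lambda_true`, tip heights preserved), so tip
#' values have covariance `sigma2 * C(lambda)` where off-diagonal shared path
#' lengths are scaled by lambda.
#'
#' @param tree ultrametric `phylo`.
#' @param sigma2 Brownian variance per Ma; must be non-negative.
#' @param lambda_true Pagel's lambda in `[0, 1]`.
#' @param root_state value at the root.
#' @param seed integer seed.
#' @return numeric vector of length `Ntip + Nnode` (all node values; tips
#'   named by label).
#' @export
simulate_bm_trait <- function(tree, sigma2, lambda_true = 1, root_state = 0,
                              seed = 1L) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  stopifnot(lambda_true >= 0, lambda_true <= 1)
  set.seed(seed + 2L)
  tt <- lambda_transform(tree, lambda_true)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  x <- numeric(nn)
  x[ntip + 1L] <- root_state
  ord <- ape::reorder.phylo(tt, "cladewise")  # parents before children
  steps <- stats::rnorm(nrow(ord$edge), 0, sqrt(sigma2 * pmax(ord$edge.length, 0)))
  for (k in seq_len(nrow(ord$edge)))
    x[ord$edge[k, 2]] <- x[ord$edge[k, 1]] + steps[k]
  names(x) <- c(tree$tip.label, paste0("node_", (ntip + 1L):nn))
  x
}

#' Impose niche shifts on simulated node states
#'
#' Offsets the child node of each listed branch and all of its descendants by
#' `delta`, recording the shifted branches as ground truth so downstream shift
#' detection can be benchmarked.
#'
#' @param tree `phylo` the states were simulated on.
#' @param states vector of node states as returned by [simulate_bm_trait()].
#' @param shift_spec data.frame with columns `node` (child node id of the
#'   shifted branch) and `delta`.
#' @return list with `states` (offset vector) and `true_shift_nodes`.
#' @export
impose_niche_shifts <- function(tree, states, shift_spec) {
  if (is.null(shift_spec) || nrow(shift_spec) == 0L)
    return(list(states = states, true_shift_nodes = integer(0)))
  nn <- ape::Ntip(tree) + tree$Nnode
  stopifnot(all(shift_spec$node >= 1), all(shift_spec$node <= nn))
  desc <- descendant_nodes(tree)
  for (i in seq_len(nrow(shift_spec))) {
    nodes <- c(shift_spec$node[i], desc[[shift_spec$node[i]]])
    states[nodes] <- states[nodes] + shift_spec$delta[i]
  }
  list(states = states, true_shift_nodes = as.integer(shift_spec$node))
}

# all descendant node ids (internal and tips) per node
descendant_nodes <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", nn)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; c <- po$edge[k, 2]
    out[[p]] <- c(out[[p]], c, out[[c]])
  }
  out
}

#' Simulate a discrete character history under a continuous-time Markov model
#'
#' Gillespie simulation along every branch from the root; the full event
#' history per branch is kept as ground truth.
#'
#' @param tree `phylo`.
#' @param q_matrix rate matrix (rows sum to 0), states taken from its
#'   rownames (or `1..k`).
#' @param root_state root state (index or name).
#' @param seed integer seed.
#' @return list with `tip_states` (named character), `node_states` (all
#'   nodes), and `events` (data.frame: edge, time, from, to).
#' @export
simulate_mk_history <- function(tree, q_matrix, root_state = 1, seed = 1L) {
  stopifnot(all(abs(rowSums(q_matrix)) < 1e-12))
  set.seed(seed + 3L)
  k <- nrow(q_matrix)
  states <- rownames(q_matrix)
  if (is.null(states)) states <- as.character(seq_len(k))
  rs <- if (is.character(root_state)) match(root_state, states) else root_state
  ntip <- ape::Ntip(tree)
  node_state <- integer(ntip + tree$Nnode)
  node_state[ntip + 1L] <- rs
  ev <- list()
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    s <- node_state[ord$edge[e, 1]]
    len <- ord$edge.length[e]
    t <- 0
    repeat {
      rate <- -q_matrix[s, s]
      if (rate <= 0) break
      t <- t + stats::rexp(1, rate)
      if (t >= len) break
      probs <- q_matrix[s, ]; probs[s] <- 0
      s_new <- sample.int(k, 1, prob = probs)
      ev[[length(ev) + 1L]] <- data.frame(edge = e, time = t,
                                          from = states[s], to = states[s_new])
      s <- s_new
    }
    node_state[ord$edge[e, 2]] <- s
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(edge = integer(0), time = numeric(0),
               from = character(0), to = character(0))
  tip_states <- stats::setNames(states[node_state[seq_len(ntip)]], tree$tip.label)
  list(tip_states = tip_states, node_states = states[node_state],
       events = events)
}

#' Simulate a gradient climate landscape and occurrence records
#'
#' Mean annual precipitation increases linearly with longitude across the
#' extent on a 0.5-degree lattice. Twelve monthly layers are derived from MAP
#' by a fixed seasonal profile (wet months share the surplus equally, dry
#' months receive 50 mm), so dry season length has a known ground truth per
#' cell. Each species' occurrences are drawn around the cells whose MAP is
#' nearest its trait value, with Gaussian spatial jitter.
#'
#' @param tree `phylo` providing species labels.
#' @param tip_traits named vector of species MAP optima (mm/yr).
#' @param config a [sim_config()].
#' @return list with `cells` (data.frame: lon, lat, map, dsl_true,
#'   cluster_true), `monthly` (cells x 12 matrix, mm/month), `occurrences`
#'   (data.frame: taxon, lon, lat).
#' @export
simulate_landscape_and_occurrences <- function(tree, tip_traits, config) {
  set.seed(config$seed + 4L)
  ex <- config$landscape_extent
  res <- 0.5
  lon_c <- seq(ex[1] + res / 2, ex[2] - res / 2, by = res)
  lat_c <- seq(ex[3] + res / 2, ex[4] - res / 2, by = res)
  cells <- expand.grid(lon = lon_c, lat = lat_c)
  frac <- (cells$lon - ex[1]) / (ex[2] - ex[1])
  cells$map <- config$map_range[1] + frac * diff(config$map_range)
  wet <- pmin(pmax(findInterval(cells$map, 650 + 350 * (0:11)), 0L), 12L)
  cells$dsl_true <- 12L - wet
  monthly <- t(vapply(seq_len(nrow(cells)), function(i) {
    w <- wet[i]
    if (w == 0) return(rep(cells$map[i] / 12, 12))  # uniformly dry year
    m <- rep(50, 12)
    m[seq_len(w)] <- (cells$map[i] - 50 * (12 - w)) / w
    m
  }, numeric(12)))
  split_map <- mean(range(tip_traits))
  cells$cluster_true <- ifelse(cells$map < split_map, 1L, 2L)

  gradient_step <- diff(config$map_range) / max(length(lon_c) - 1L, 1L)
  occ <- lapply(tree$tip.label, function(sp) {
    target <- which(abs(cells$map - tip_traits[sp]) ==
                      min(abs(cells$map - tip_traits[sp])))
    pick <- target[sample.int(length(target), config$n_occurrences_per_species,
                              replace = TRUE)]
    lon <- cells$lon[pick] + stats::rnorm(length(pick), 0, config$spatial_noise_deg)
    lat <- cells$lat[pick] + stats::rnorm(length(pick), 0, config$spatial_noise_deg)
    eps <- 1e-9
    data.frame(taxon = sp,
               lon = pmin(pmax(lon, ex[1]), ex[2] - eps),
               lat = pmin(pmax(lat, ex[3]), ex[4] - eps))
  })
  list(cells = cells, monthly = monthly, occurrences = do.call(rbind, occ),
       gradient_step = gradient_step)
}

#' Run all synthetic generators from one configuration
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `states` (all node values), `tip_states_mk`,
#'   `mk_events`, `landscape`, and `ground_truth`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_tree(config)
  states <- simulate_bm_trait(tree, config$trait_sigma2, config$lambda_true,
                              config$root_state, seed = config$seed)
  mk <- simulate_mk_history(tree, config$mk_rates, root_state = 1,
                            seed = config$seed)
  tips <- states[seq_len(ape::Ntip(tree))]
  land <- simulate_landscape_and_occurrences(tree, tips, config)
  list(tree = tree, states = states, tip_states_mk = mk$tip_states,
       mk_events = mk$events, landscape = land,
       ground_truth = list(true_node_states = states,
                           true_range_history = mk$events,
                           true_cluster_of_cell = land$cells$cluster_true))
}
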