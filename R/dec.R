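# --- range state space -------------------------------------------------------

#' Enumerate geographic range states
#'
#' Non-empty subsets of the areas up to `max_range_size`, plus the empty
#' (extinct) range which is carried in the anagenetic matrix only.
#'
#' @param areas character vector of area names (at most 8).
#' @param max_range_size largest allowed range (default: all areas).
#' @return object of class `range_space`: `areas`, `masks` (bitmask per
#'   non-empty state), `labels`.
#' @export
range_space <- function(areas, max_range_size = length(areas)) {
  na <- length(areas)
  if (na > 8) stop("state-space overflow: more than 8 areas")
  stopifnot(max_range_size >= 1, max_range_size <= na)
  masks <- Filter(function(m) {
    sz <- sum(bitwAnd(m, 2^(0:(na - 1))) > 0)
    sz >= 1 && sz <= max_range_size
  }, seq_len(2^na - 1))
  masks <- unlist(masks)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(na - 1))) > 0), numeric(1))
  ord <- order(sizes, masks)
  masks <- masks[ord]
  labels <- vapply(masks, function(m)
    paste(areas[bitwAnd(m, 2^(0:(na - 1))) > 0], collapse = ";"), character(1))
  structure(list(areas = areas, masks = masks, labels = labels,
                 max_range_size = max_range_size),
            class = "range_space")
}

mask_size <- function(mask) vapply(mask, function(m) sum(bitwAnd(m, 2^(0:7)) > 0), numeric(1))

# anagenetic rate matrix over (null + non-empty) range states;
# state 1 is the absorbing null range
dec_Q <- function(rs, d, e) {
  na <- length(rs$areas)
  S <- length(rs$masks)
  idx <- integer(2^na); idx[rs$masks] <- seq_len(S) + 1L  # +1: null first
  Q <- matrix(0, S + 1L, S + 1L)
  for (i in seq_len(S)) {
    m <- rs$masks[i]
    in_a <- which(bitwAnd(m, 2^(0:(na - 1))) > 0)
    sz <- length(in_a)
    # dispersal: add one area, rate d per occupied source area
    for (a in setdiff(seq_len(na), in_a)) {
      m2 <- bitwOr(m, 2^(a - 1))
      if (idx[m2] > 0) Q[i + 1L, idx[m2]] <- d * sz
    }
    # extinction: lose one area (to the null range when single)
    for (a in in_a) {
      m2 <- bitwAnd(m, bitwNot(2^(a - 1)))
      j <- if (m2 == 0) 1L else idx[m2]
      if (j > 0) Q[i + 1L, j] <- Q[i + 1L, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# cladogenetic event table for one parent state: ordered daughter pairs with
# normalized probabilities; DEC events have weight 1, founder events weight j
dec_clado_events <- function(rs, parent_i, j = 0) {
  na <- length(rs$areas)
  S <- length(rs$masks)
  idx <- integer(2^na); idx[rs$masks] <- seq_len(S)
  m <- rs$masks[parent_i]
  in_a <- which(bitwAnd(m, 2^(0:(na - 1))) > 0)
  out <- list()
  add <- function(l, r, w) out[[length(out) + 1L]] <<- c(l, r, w)
  if (length(in_a) == 1L) {
    add(parent_i, parent_i, 1)              # sympatry
  } else {
    for (a in in_a) {
      sa <- idx[2^(a - 1)]
      rest <- idx[bitwAnd(m, bitwNot(2^(a - 1)))]
      if (rest > 0) { add(sa, rest, 1); add(rest, sa, 1) }   # vicariance
      add(sa, parent_i, 1); add(parent_i, sa, 1)             # subset sympatry
    }
  }
  if (j > 0) {
    for (a in setdiff(seq_len(na), in_a)) {
      sa <- idx[2^(a - 1)]
      add(parent_i, sa, j); add(sa, parent_i, j)             # founder event
    }
  }
  ev <- do.call(rbind, out)
  ev[, 3] <- ev[, 3] / sum(ev[, 3])
  ev
}

# parse "A;B" style tip ranges to state indices
parse_ranges <- function(tip_ranges, rs) {
  vapply(tip_ranges, function(r) {
    ar <- strsplit(r, ";")[[1]]
    pos <- match(ar, rs$areas)
    if (anyNA(pos)) stop("unknown area in tip range: ", r)
    m <- sum(2^(pos - 1))
    i <- match(m, rs$masks)
    if (is.na(i)) stop("tip range exceeds max range size: ", r)
    i
  }, numeric(1))
}

#' Dispersal-extinction-cladogenesis log-likelihood
#'
#' Pruning over range states with anagenetic transitions `exp(Q t)`
#' (dispersal adds an area at rate `d` per occupied source area, extinction
#' removes one at rate `e`; the empty range is absorbing) and cladogenetic
#' event weights at nodes (sympatry for single-area parents; vicariance and
#' subset sympatry for wider ranges; founder events with weight `j` when
#' positive). The root prior is uniform over the allowed non-empty ranges.
#'
#' @param tree `phylo`.
#' @param tip_ranges named character vector per tip, areas separated by `;`.
#' @param d,e,j anagenetic rates and founder weight.
#' @param rs a [range_space()]; built from the observed areas when NULL.
#' @param max_range_size passed to [range_space()] when `rs` is NULL.
#' @param condition_survival condition the likelihood on no lineage reaching
#'   the empty range (divide by the survival probability of the whole tree);
#'   appropriate when the data-generating process is itself conditioned on
#'   all sampled lineages surviving, as in simulation benchmarks.
#' @return list with `loglik`, and internals (`cond`, `Pmats`, `postorder`,
#'   `rs`, `clado`) reused by the reconstruction.
#' @export
dec_likelihood <- function(tree, tip_ranges, d, e, j = 0, rs = NULL,
                           max_range_size = NULL, condition_survival = FALSE) {
  if (is.null(rs)) {
    areas <- sort(unique(unlist(strsplit(tip_ranges, ";"))))
    if (is.null(max_range_size)) max_range_size <- length(areas)
    rs <- range_space(areas, max_range_size)
  }
  S <- length(rs$masks)
  Qfull <- dec_Q(rs, d, e)
  ntip <- ape::Ntip(tree); nn <- ntip + tree$Nnode
  tipidx <- parse_ranges(tip_ranges[tree$tip.label], rs)
  cond <- matrix(0, nn, S)
  cond[cbind(seq_len(ntip), tipidx)] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  Pf <- expm_factory(Qfull)
  Pmats <- vector("list", nrow(po$edge))
  clado <- lapply(seq_len(S), function(i) dec_clado_events(rs, i, j))
  loglik <- 0
  branch_top <- matrix(0, nn, S)  # conditional at the top of each child branch
  combine <- function(v1, v2) {
    vapply(seq_len(S), function(i) {
      ev <- clado[[i]]
      sum(ev[, 3] * v1[ev[, 1]] * v2[ev[, 2]])
    }, numeric(1))
  }
  children <- split(po$edge[, 2], po$edge[, 1])
  for (eix in seq_len(nrow(po$edge))) {
    p <- po$edge[eix, 1]; ch <- po$edge[eix, 2]
    if (ch > ntip) {  # internal child: combine its daughters first
      kids <- children[[as.character(ch)]]
      v <- combine(branch_top[kids[1], ], branch_top[kids[2], ])
      sc <- sum(v)
      if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
      loglik <- loglik + log(sc)
      cond[ch, ] <- v / sc
    }
    # drop the null row/col: data cannot descend from an extinct lineage
    P <- Pf(po$edge.length[eix])
    Pmats[[eix]] <- P
    v <- drop(P[-1, -1, drop = FALSE] %*% cond[ch, ])
    sc <- sum(v)
    if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
    loglik <- loglik + log(sc)
    branch_top[ch, ] <- v / sc
  }
  root <- ntip + 1L
  kids <- children[[as.character(root)]]
  v <- combine(branch_top[kids[1], ], branch_top[kids[2], ])
  sc <- sum(v)
  if (sc <= 0 || !is.finite(sc)) return(list(loglik = -Inf))
  loglik <- loglik + log(sc)
  cond[root, ] <- v / sc
  prior <- rep(1 / S, S)
  loglik <- loglik + log(sum(prior * cond[root, ]))
  if (condition_survival) {
    ones <- matrix(0, nn, S); ones[seq_len(ntip), ] <- 1
    surv <- .dec_prune_core(po, ones, Pmats, clado, S, ntip)
    loglik <- loglik - (surv + log(sum(prior * attr(surv, "root_cond"))))
  }
  list(loglik = loglik, cond = cond, branch_top = branch_top, Pmats = Pmats,
       postorder = po, rs = rs, clado = clado, prior = prior,
       d = d, e = e, j = j)
}

# shared scaled pruning pass used for the survival normalizer
.dec_prune_core <- function(po, cond, Pmats, clado, S, ntip) {
  children <- split(po$edge[, 2], po$edge[, 1])
  nn <- nrow(cond)
  branch_top <- matrix(0, nn, S)
  loglik <- 0
  combine <- function(v1, v2) {
    vapply(seq_len(S), function(i) {
      ev <- clado[[i]]
      sum(ev[, 3] * v1[ev[, 1]] * v2[ev[, 2]])
    }, numeric(1))
  }
  for (eix in seq_len(nrow(po$edge))) {
    ch <- po$edge[eix, 2]
    if (ch > ntip) {
      kids <- children[[as.character(ch)]]
      v <- combine(branch_top[kids[1], ], branch_top[kids[2], ])
      sc <- sum(v); loglik <- loglik + log(sc); cond[ch, ] <- v / sc
    }
    v <- drop(Pmats[[eix]][-1, -1, drop = FALSE] %*% cond[ch, ])
    sc <- sum(v); loglik <- loglik + log(sc); branch_top[ch, ] <- v / sc
  }
  root <- ntip + 1L
  kids <- children[[as.character(root)]]
  v <- combine(branch_top[kids[1], ], branch_top[kids[2], ])
  sc <- sum(v); loglik <- loglik + log(sc)
  structure(loglik, root_cond = v / sc)
}

#' Fit a DEC or DEC+J model by maximum likelihood
#'
#' @param tree `phylo`.
#' @param tip_ranges named character vector (`"A;B"` style).
#' @param with_j fit the founder-event weight `j` (in `[0, 3]`) as a free
#'   parameter.
#' @param rs optional [range_space()].
#' @param max_range_size passed to [range_space()] when `rs` is NULL.
#' @param condition_survival see [dec_likelihood()].
#' @return object of class `dec_model`: `d`, `e`, `j`, `loglik`, `AIC`,
#'   `n_par`, `rs`, `node_probs` (marginal range probabilities per node).
#' @export
fit_dec <- function(tree, tip_ranges, with_j = FALSE, rs = NULL,
                    max_range_size = NULL, condition_survival = FALSE) {
  if (is.null(rs)) {
    areas <- sort(unique(unlist(strsplit(tip_ranges, ";"))))
    if (is.null(max_range_size)) max_range_size <- length(areas)
    rs <- range_space(areas, max_range_size)
  }
  nll <- function(par) {
    d <- exp(par[1]); e <- exp(par[2])
    j <- if (with_j) par[3] else 0
    ll <- dec_likelihood(tree, tip_ranges, d, e, j, rs = rs,
                         condition_survival = condition_survival)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  init <- c(log(0.01), log(0.01), if (with_j) 0.01)
  lower <- c(log(1e-8), log(1e-8), if (with_j) 0)
  upper <- c(log(10), log(10), if (with_j) 3)
  opt <- stats::optim(init, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 300))
  d <- exp(opt$par[1]); e <- exp(opt$par[2])
  j <- if (with_j) opt$par[3] else 0
  lik <- dec_likelihood(tree, tip_ranges, d, e, j, rs = rs,
                        condition_survival = condition_survival)
  k <- if (with_j) 3L else 2L
  structure(list(d = d, e = e, j = j, with_j = with_j,
                 loglik = lik$loglik, AIC = 2 * k - 2 * lik$loglik,
                 n_par = k, rs = rs,
                 node_probs = dec_node_marginals(lik),
                 convergence = opt$convergence),
            class = "dec_model")
}

#' Marginal ancestral range probabilities from a DEC pruning pass
#'
#' Standard two-pass belief propagation: the outside (up-pass) message at
#' each node is combined with the node's conditional likelihood.
#'
#' @param lik the list returned by [dec_likelihood()].
#' @return matrix (nodes x range states) of probabilities; tip rows hold the
#'   observed range indicator.
#' @export
dec_node_marginals <- function(lik) {
  po <- lik$postorder
  S <- length(lik$rs$masks)
  ntip <- ape::Ntip(po); nn <- ntip + po$Nnode
  children <- split(po$edge[, 2], po$edge[, 1])
  edge_of_child <- match(seq_len(nn), po$edge[, 2])
  U <- matrix(0, nn, S)
  root <- ntip + 1L
  U[root, ] <- lik$prior
  # preorder: parents before children
  for (eix in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[eix, 1]; ch <- po$edge[eix, 2]
    kids <- children[[as.character(p)]]
    sib <- kids[kids != ch]
    Tsib <- lik$branch_top[sib, ]
    O <- numeric(S)
    which_side <- if (ch == kids[1]) 1L else 2L
    for (i in seq_len(S)) {
      if (U[p, i] == 0) next
      ev <- lik$clado[[i]]
      own <- ev[, which_side]; other <- ev[, 3 - which_side]
      contrib <- ev[, 3] * Tsib[other] * U[p, i]
      for (r in seq_len(nrow(ev))) O[own[r]] <- O[own[r]] + contrib[r]
    }
    P <- lik$Pmats[[eix]][-1, -1, drop = FALSE]
    U[ch, ] <- drop(O %*% P)
  }
  M <- lik$cond * U
  sw <- rowSums(M)
  sw[sw == 0] <- 1
  M <- M / sw
  colnames(M) <- lik$rs$labels
  M
}

#' AIC-weighted model averaging of ancestral range probabilities
#'
#' @param models list of fitted `dec_model`s over the same tree and range
#'   space.
#' @return list with `weights` (named, sum to 1) and `node_probs` (averaged
#'   matrix).
#' @export
aic_average <- function(models) {
  stopifnot(length(models) >= 1)
  aics <- vapply(models, `[[`, numeric(1), "AIC")
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)
  np <- Reduce(`+`, Map(function(m, wi) m$node_probs * wi, models, w))
  nms <- names(models)
  if (is.null(nms)) nms <- paste0("model", seq_along(models))
  list(weights = stats::setNames(w, nms), node_probs = np)
}

#' Decide ancestral ranges from range-state probabilities
#'
#' Default (`greedy_marginal`): per-area marginal probabilities are
#' accumulated in decreasing order (ties broken by area order) until they
#' exceed 50% of their total; the visited areas form the decided range.
#' `composite` takes the single most probable range state.
#'
#' @param node_probs matrix (nodes x states) of range probabilities.
#' @param rs the [range_space()].
#' @param mode `"greedy_marginal"` or `"composite"`.
#' @return list of character vectors (area names), one per node.
#' @export
decide_ranges <- function(node_probs, rs, mode = c("greedy_marginal", "composite")) {
  mode <- match.arg(mode)
  na <- length(rs$areas)
  in_state <- vapply(seq_len(na), function(a)
    bitwAnd(rs$masks, 2^(a - 1)) > 0, logical(length(rs$masks)))
  lapply(seq_len(nrow(node_probs)), function(v) {
    p <- node_probs[v, ]
    if (mode == "composite") {
      i <- which.max(p)
      return(rs$areas[bitwAnd(rs$masks[i], 2^(0:(na - 1))) > 0])
    }
    marg <- drop(p %*% in_state)
    if (sum(marg) == 0) return(character(0))
    marg <- marg / sum(marg)
    ord <- order(-marg, seq_len(na))
    cum <- cumsum(marg[ord])
    take <- ord[seq_len(which(cum > 0.5)[1])]
    rs$areas[sort(take)]
  })
}

#' Canonical area groupings for transoceanic dispersal counting
#'
#' `seven`: North and South America merged into the Americas, all other
#' areas separate. `three`: the Americas, Oceania, and everything else as
#' one Old World group (the stricter definition).
#'
#' @param areas area names; defaults to the eight canonical areas.
#' @param definition `"seven"` or `"three"`.
#' @return named character vector: area -> group.
#' @export
area_grouping <- function(areas = c("NorthAmerica", "SouthAmerica", "Africa",
                                    "Madagascar", "Asia", "Australia",
                                    "Oceania", "Mediterranean"),
                          definition = c("seven", "three")) {
  definition <- match.arg(definition)
  g <- stats::setNames(areas, areas)
  am <- areas %in% c("NorthAmerica", "SouthAmerica", "Americas")
  g[am] <- "Americas"
  if (definition == "three")
    g[!am & areas != "Oceania"] <- "OldWorld"
  g
}

#' Count transoceanic dispersal events from decided ranges
#'
#' A branch carries one dispersal event for every group present in the
#' child's decided range but absent from the parent's; events are dated at
#' the branch midpoint.
#'
#' @param decided list of area vectors per node ([decide_ranges()]).
#' @param tree `phylo`.
#' @param grouping named vector area -> group ([area_grouping()]).
#' @return data.frame: `edge`, `from_groups`, `to_group`, `shift_age`.
#' @export
count_dispersals <- function(decided, tree, grouping) {
  ages <- node_ages(tree)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    pg <- unique(unname(grouping[decided[[p]]]))
    cg <- unique(unname(grouping[decided[[ch]]]))
    for (g in setdiff(cg, pg)) {
      out[[length(out) + 1L]] <- data.frame(
        edge = e, from_groups = paste(pg, collapse = "+"), to_group = g,
        shift_age = unname((ages[p] + ages[ch]) / 2))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(edge = integer(0), from_groups = character(0),
               to_group = character(0), shift_age = numeric(0))
}

#' Simulate a range history under DEC(+J)
#'
#' Forward simulation for benchmarking: anagenetic dispersal/extinction along
#' branches (paths hitting the empty range are redrawn), cladogenetic events
#' sampled by their weights at nodes.
#'
#' @param tree `phylo`.
#' @param rs a [range_space()].
#' @param d,e,j model parameters.
#' @param root_range label (`"A;B"`) or state index of the root range.
#' @param seed integer seed.
#' @param max_branch_retries redraws allowed per branch before failing.
#' @return list with `tip_ranges` (labels), `node_states` (state index per
#'   node), `events` (data.frame: edge, time, from, to labels).
#' @export
simulate_dec_history <- function(tree, rs, d, e, j = 0, root_range = 1,
                                 seed = 1L, max_branch_retries = 1000) {
  set.seed(seed + 5L)
  S <- length(rs$masks)
  Qfull <- dec_Q(rs, d, e)
  Q <- Qfull[-1, -1, drop = FALSE]  # excluding null; used for state lookup
  root_i <- if (is.character(root_range)) match(root_range, rs$labels) else root_range
  stopifnot(!is.na(root_i))
  ntip <- ape::Ntip(tree); nn <- ntip + tree$Nnode
  node_state <- integer(nn)
  # sample cladogenetic daughters at each internal node on the fly (preorder)
  daughter_at <- matrix(0L, nn, 2)
  ord <- ape::reorder.phylo(tree, "cladewise")
  children <- split(ord$edge[, 2], ord$edge[, 1])
  node_state[ntip + 1L] <- root_i
  ev_log <- list()
  assign_node <- function(v) {
    ev <- dec_clado_events(rs, node_state[v], j)
    r <- sample.int(nrow(ev), 1, prob = ev[, 3])
    daughter_at[v, ] <<- as.integer(ev[r, 1:2])
  }
  assign_node(ntip + 1L)
  for (eix in seq_len(nrow(ord$edge))) {
    p <- ord$edge[eix, 1]; ch <- ord$edge[eix, 2]
    kids <- children[[as.character(p)]]
    start <- daughter_at[p, if (ch == kids[1]) 1L else 2L]
    len <- ord$edge.length[eix]
    for (try in seq_len(max_branch_retries)) {
      s <- start + 1L  # index into Qfull (null first)
      tt <- 0; path <- list()
      dead <- FALSE
      repeat {
        r <- -Qfull[s, s]
        dt <- if (r > 0) stats::rexp(1, r) else Inf
        if (tt + dt >= len) break
        tt <- tt + dt
        pr <- Qfull[s, ]; pr[s] <- 0
        s_new <- sample.int(S + 1L, 1, prob = pr)
        if (s_new == 1L) { dead <- TRUE; break }
        path[[length(path) + 1L]] <- c(tt, s_new - 1L)
        s <- s_new
      }
      if (!dead) {
        for (pp in path) {
          frm <- if (length(ev_log) && ev_log[[length(ev_log)]]$edge == eix)
            ev_log[[length(ev_log)]]$to else rs$labels[start]
          ev_log[[length(ev_log) + 1L]] <- data.frame(
            edge = eix, time = pp[1], from = frm, to = rs$labels[pp[2]])
        }
        node_state[ch] <- s - 1L
        break
      }
      if (try == max_branch_retries)
        stop("branch simulation kept going extinct; increase retries")
    }
    if (ch > ntip) assign_node(ch)
  }
  events <- if (length(ev_log)) do.call(rbind, ev_log) else
    data.frame(edge = integer(0), time = numeric(0),
               from = character(0), to = character(0))
  list(tip_ranges = stats::setNames(rs$labels[node_state[seq_len(ntip)]],
                                    tree$tip.label),
       node_states = node_state, events = events)
}
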