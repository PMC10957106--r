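# Independent oracle implementations used across the test files. These are
# deliberately written via different routes than the package code.

# per-branch classification of shared/unique branch length between two tip
# sets, restricted to the spanning subtree of their union (phangorn route)
oracle_phylo_components <- function(tree, set_i, set_j) {
  un <- union(set_i, set_j)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  a <- b <- c <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc[[e]]]
    if (length(intersect(tips, un)) == 0) next
    if (all(un %in% tips)) next  # rootward of the union's MRCA
    ii <- length(intersect(tips, set_i)) > 0
    jj <- length(intersect(tips, set_j)) > 0
    if (ii && jj) a <- a + tree$edge.length[e]
    else if (ii) b <- b + tree$edge.length[e]
    else if (jj) c <- c + tree$edge.length[e]
  }
  list(a = a, b = b, c = c)
}

# exhaustive-enumeration Mk likelihood (sums over internal-state assignments)
oracle_mk_loglik <- function(tree, tip_states, Q, pi) {
  states <- rownames(Q)
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  obs <- match(tip_states[tree$tip.label], states)
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(e) phyloturn:::expm_rate(Q, tree$edge.length[e]))
  grid <- expand.grid(rep(list(seq_len(k)), tree$Nnode))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- c(obs, as.integer(grid[g, ]))
    pr <- pi[asg[ntip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * Pm[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
    tot <- tot + pr
  }
  as.numeric(log(tot))
}

# exhaustive-enumeration DEC likelihood over pre-cladogenesis node states
oracle_dec_loglik <- function(tree, tip_ranges, d, e, j, rs) {
  S <- length(rs$masks)
  ntip <- ape::Ntip(tree)
  Qf <- phyloturn:::dec_Q(rs, d, e)
  clado <- lapply(seq_len(S), function(i) phyloturn:::dec_clado_events(rs, i, j))
  tipidx <- phyloturn:::parse_ranges(tip_ranges[tree$tip.label], rs)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  Pm <- lapply(seq_len(nrow(tree$edge)),
               function(ei) phyloturn:::expm_rate(Qf, tree$edge.length[ei])[-1, -1])
  grid <- expand.grid(rep(list(seq_len(S)), tree$Nnode))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- c(tipidx, as.integer(grid[g, ]))
    pr <- 1 / S
    for (v in (ntip + 1):(ntip + tree$Nnode)) {
      kids <- children[[as.character(v)]]
      ev <- clado[[asg[v]]]
      e1 <- which(tree$edge[, 1] == v & tree$edge[, 2] == kids[1])
      e2 <- which(tree$edge[, 1] == v & tree$edge[, 2] == kids[2])
      pr <- pr * sum(ev[, 3] * Pm[[e1]][ev[, 1], asg[kids[1]]] *
                       Pm[[e2]][ev[, 2], asg[kids[2]]])
    }
    tot <- tot + pr
  }
  log(tot)
}

# dense-matrix GLS ancestral estimate at one node (BLUP under BM)
oracle_gls_node <- function(tree, x, v) {
  ntip <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)
  full <- ape::mrca(tree, full = TRUE)
  ids <- c(seq_len(ntip), v)
  Cov <- matrix(h[full[ids, ids]], ntip + 1, ntip + 1)
  Ctt <- Cov[seq_len(ntip), seq_len(ntip)]
  cvt <- Cov[ntip + 1, seq_len(ntip)]
  one <- rep(1, ntip)
  Ci <- solve(Ctt)
  mu <- drop(one %*% Ci %*% x / (one %*% Ci %*% one))
  mu + drop(cvt %*% Ci %*% (x[tree$tip.label] - mu))
}

# step-by-step Lance-Williams agglomeration; variant "ward2" or "upgma".
# Returns the member sets merged at each step and the merge heights.
oracle_lance_williams <- function(D, variant = c("ward2", "upgma")) {
  variant <- match.arg(variant)
  D <- as.matrix(D)
  n <- nrow(D)
  work <- if (variant == "ward2") D^2 else D
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  merges <- list(); heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
      i <- active[ii]; j <- active[jj]
      if (work[i, j] < bd) { bd <- work[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    merges[[step]] <- sort(unlist(members[c(i, j)]))
    heights[step] <- if (variant == "ward2") sqrt(bd) else bd
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      work[i, k] <- work[k, i] <- if (variant == "ward2") {
        ((ni + nk) * work[i, k] + (nj + nk) * work[j, k] - nk * work[i, j]) /
          (ni + nj + nk)
      } else {
        (ni * work[i, k] + nj * work[j, k]) / (ni + nj)
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(merges = merges, heights = heights)
}

# member sets merged at each hclust step
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    take <- function(id) if (id < 0) -id else unlist(sets[[id]])
    sets[[s]] <- sort(c(take(hc$merge[s, 1]), take(hc$merge[s, 2])))
  }
  sets
}

# random ultrametric tree helper for property tests
random_ultra_tree <- function(n, scale = 10) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * scale / max(ape::node.depth.edgelength(tr))
  tr
}
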