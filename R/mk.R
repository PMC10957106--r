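# factory for transition probability matrices exp(Q t): closed form for 2
# states, a single eigendecomposition reused across branch lengths otherwise,
# with a Pade (Matrix::expm) fallback when Q is defective
expm_factory <- function(Q) {
  k <- nrow(Q)
  if (k == 2L) {
    a <- Q[1, 2]; b <- Q[2, 1]; s <- a + b
    return(function(t) {
      if (s <= 0) return(diag(2))
      eb <- exp(-s * t)
      matrix(c((b + a * eb) / s, (a - a * eb) / s,
               (b - b * eb) / s, (a + b * eb) / s), 2, 2, byrow = TRUE)
    })
  }
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(ev)) {
    Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vi) && all(is.finite(ev$values))) {
      V <- ev$vectors; lam <- ev$values
      f <- function(t) {
        P <- Re(V %*% (exp(lam * t) * Vi))
        pmax(P, 0)
      }
      # sanity: rows of exp(Q) must sum to 1
      if (max(abs(rowSums(f(1)) - 1)) < 1e-8) return(f)
    }
  }
  function(t) as.matrix(Matrix::expm(Q * t))
}

# one-off convenience wrapper
expm_rate <- function(Q, t) expm_factory(Q)(t)

# stationary distribution of Q (pi Q = 0); uniform fallback for degenerate Q
stationary_freqs <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  pi <- tryCatch(qr.solve(A, c(rep(0, k), 1)), error = function(e) rep(1 / k, k))
  if (any(!is.finite(pi)) || any(pi < -1e-8)) pi <- rep(1 / k, k)
  pi <- pmax(pi, 0); pi / sum(pi)
}

# pruning-algorithm log-likelihood for an Mk model; returns per-node scaled
# conditional likelihoods and per-edge P matrices for reuse
mk_pruning <- function(tree, tip_states, Q, root = c("stationary", "uniform")) {
  root <- match.arg(root)
  states <- rownames(Q)
  if (is.null(states)) states <- as.character(seq_len(nrow(Q)))
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  L <- matrix(0, nn, k)
  obs <- match(tip_states[tree$tip.label], states)
  if (anyNA(obs)) stop("tip state not among model states")
  L[cbind(seq_len(ntip), obs)] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  Pf <- expm_factory(Q)
  Pmats <- vector("list", nrow(po$edge))
  loglik <- 0
  node_prod <- matrix(1, nn, k)  # running partial products at internal nodes
  node_prod[seq_len(ntip), ] <- L[seq_len(ntip), ]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    P <- Pf(po$edge.length[e])
    Pmats[[e]] <- P
    v <- drop(P %*% node_prod[ch, ])
    sc <- sum(v)
    if (sc <= 0) return(list(loglik = -Inf))
    loglik <- loglik + log(sc)
    node_prod[p, ] <- node_prod[p, ] * (v / sc)
    # renormalize parent's partial to avoid underflow
    m <- sum(node_prod[p, ])
    if (m > 0 && m < 1e-10) {
      node_prod[p, ] <- node_prod[p, ] / m
      loglik <- loglik + log(m)
    }
  }
  pi <- if (root == "stationary") stationary_freqs(Q) else rep(1 / k, k)
  rt <- ntip + 1L
  tot <- sum(pi * node_prod[rt, ])
  list(loglik = loglik + log(tot), cond = node_prod, Pmats = Pmats,
       postorder = po, pi = pi, states = states)
}

#' Fit an all-rates-different Mk model by maximum likelihood
#'
#' Pruning-algorithm likelihood with bounded optimisation over the
#' off-diagonal rates; the root state is weighted by the stationary
#' frequencies of the fitted rate matrix.
#'
#' @param tree `phylo`.
#' @param tip_states named character (or factor) vector over tips.
#' @param root `"stationary"` (default) or `"uniform"` root treatment.
#' @return object of class `mk_model`: `Q`, `states`, `loglik`, `root`.
#' @export
fit_mk_ard <- function(tree, tip_states, root = "stationary") {
  states <- sort(unique(as.character(tip_states)))
  stopifnot(length(states) >= 2)
  k <- length(states)
  np <- k * (k - 1L)
  build_Q <- function(r) {
    Q <- matrix(0, k, k, dimnames = list(states, states))
    Q[row(Q) != col(Q)] <- r
    diag(Q) <- -rowSums(Q)
    Q
  }
  total_len <- sum(tree$edge.length)
  nll <- function(logr) {
    Q <- build_Q(exp(logr))
    -mk_pruning(tree, tip_states, Q, root)$loglik
  }
  init <- rep(log(k / total_len), np)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = log(1e-9), upper = log(1e3),
                      control = list(maxit = 500))
  Q <- build_Q(exp(opt$par))
  structure(list(Q = Q, states = states, loglik = -opt$value, root = root,
                 convergence = opt$convergence),
            class = "mk_model")
}

# sample an endpoint-conditioned CTMC path on [0, t] from state a to b;
# modified rejection sampling with a uniformization fallback
sample_path <- function(Q, t, a, b, max_reject = 1000) {
  k <- nrow(Q)
  for (rep in seq_len(max_reject)) {
    s <- a; tt <- 0; path <- list()
    if (a != b) {
      ra <- -Q[a, a]
      if (ra <= 0) break
      u <- stats::runif(1)
      tt <- -log(1 - u * (1 - exp(-ra * t))) / ra  # forced first event
      pr <- Q[a, ]; pr[a] <- 0
      s <- sample.int(k, 1, prob = pr)
      path[[1]] <- c(tt, s)
    }
    repeat {
      r <- -Q[s, s]
      dt <- if (r > 0) stats::rexp(1, r) else Inf
      if (tt + dt >= t) break
      tt <- tt + dt
      pr <- Q[s, ]; pr[s] <- 0
      s_new <- sample.int(k, 1, prob = pr)
      path[[length(path) + 1L]] <- c(tt, s_new)
      s <- s_new
    }
    if (s == b) {
      if (length(path) == 0L) return(matrix(numeric(0), 0, 2))
      return(do.call(rbind, path))
    }
  }
  uniformization_path(Q, t, a, b)
}

# uniformization sampler for endpoint-conditioned paths
uniformization_path <- function(Q, t, a, b) {
  k <- nrow(Q)
  mu <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(k) + Q / mu
  # number of uniformized steps
  nmax <- 4L; Rp <- list(diag(k), R)
  while (TRUE) {
    probs <- vapply(0:nmax, function(n) {
      if (length(Rp) < n + 1L) Rp[[n + 1L]] <<- Rp[[n]] %*% R
      stats::dpois(n, mu * t) * Rp[[n + 1L]][a, b]
    }, numeric(1))
    if (stats::ppois(nmax, mu * t) > 1 - 1e-12 || nmax > 500L) break
    nmax <- nmax * 2L
  }
  probs <- pmax(probs, 0)
  if (sum(probs) <= 0) stop("uniformization failed: unreachable endpoint")
  N <- sample.int(length(probs), 1, prob = probs) - 1L
  if (N == 0L) return(matrix(numeric(0), 0, 2))
  times <- sort(stats::runif(N, 0, t))
  st <- integer(N); cur <- a
  for (i in seq_len(N)) {
    m <- N - i
    w <- R[cur, ] * Rp[[m + 1L]][, b]
    st[i] <- sample.int(k, 1, prob = pmax(w, 0))
    cur <- st[i]
  }
  keep <- which(c(st[1] != a, diff(st) != 0))
  cbind(times[keep], st[keep])
}

#' Stochastic character maps under a fitted Mk model
#'
#' Histories are sampled conditional on the tip data: node states from the
#' conditional distributions of the pruning pass, then endpoint-conditioned
#' event histories along each branch by modified rejection sampling (with a
#' uniformization fallback on extreme branches).
#'
#' @param model an `mk_model` (or a list with `Q` and `root`).
#' @param tree `phylo`.
#' @param tip_states named vector over tips.
#' @param n number of maps (default 100).
#' @param seed integer seed.
#' @return object of class `mk_maps`: list with `node_states` (n x nodes
#'   matrix of state indices), `histories` (per map: data.frame edge, time,
#'   from, to), `node_freq` (nodes x states empirical frequencies),
#'   `states`.
#' @export
stochastic_maps <- function(model, tree, tip_states, n = 100, seed = 1L) {
  set.seed(seed)
  Q <- model$Q
  pr <- mk_pruning(tree, tip_states, Q, model$root)
  k <- nrow(Q); ntip <- ape::Ntip(tree); nn <- ntip + tree$Nnode
  po <- pr$postorder
  # preorder edges = reverse postorder
  pre <- rev(seq_len(nrow(po$edge)))
  node_states <- matrix(0L, n, nn)
  histories <- vector("list", n)
  root <- ntip + 1L
  root_w <- pr$pi * pr$cond[root, ]
  for (m in seq_len(n)) {
    ns <- integer(nn)
    ns[root] <- sample.int(k, 1, prob = root_w)
    ev <- list()
    for (e in pre) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      P <- pr$Pmats[[e]]
      w <- P[ns[p], ] * pr$cond[ch, ]
      ns[ch] <- sample.int(k, 1, prob = w)
      path <- sample_path(Q, po$edge.length[e], ns[p], ns[ch])
      if (nrow(path)) {
        from <- c(ns[p], path[-nrow(path), 2])
        ev[[length(ev) + 1L]] <- cbind(edge = e, time = path[, 1],
                                       from = from, to = path[, 2])
      }
    }
    node_states[m, ] <- ns
    h <- if (length(ev)) do.call(rbind, ev) else
      matrix(numeric(0), 0, 4, dimnames = list(NULL, c("edge", "time", "from", "to")))
    colnames(h) <- c("edge", "time", "from", "to")
    histories[[m]] <- as.data.frame(h)
  }
  node_freq <- t(vapply(seq_len(nn), function(v)
    tabulate(node_states[, v], k) / n, numeric(k)))
  colnames(node_freq) <- pr$states
  structure(list(node_states = node_states, histories = histories,
                 node_freq = node_freq, states = pr$states,
                 postorder_edges = po$edge),
            class = "mk_maps")
}

#' Majority-rule transition branches across stochastic maps
#'
#' A branch is flagged when its parent and child node states conflict in at
#' least `threshold` of the maps; the reported direction is the majority
#' direction among conflicting maps.
#'
#' @param maps an `mk_maps` object.
#' @param tree the `phylo` the maps were sampled on.
#' @param threshold conflict fraction required (default 0.5).
#' @return data.frame: `edge` (index into `tree$edge`), `fraction`, `from`,
#'   `to`, `midpoint_age`.
#' @export
count_transitions <- function(maps, tree, threshold = 0.5) {
  ages <- node_ages(tree)
  edges <- maps$postorder_edges
  out <- list()
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    conflict <- maps$node_states[, p] != maps$node_states[, ch]
    frac <- mean(conflict)
    if (frac >= threshold) {
      dirs <- paste(maps$node_states[conflict, p],
                    maps$node_states[conflict, ch])
      md <- names(sort(table(dirs), decreasing = TRUE))[1]
      fromto <- as.integer(strsplit(md, " ")[[1]])
      # map postorder edge back to tree$edge row
      row <- which(tree$edge[, 1] == p & tree$edge[, 2] == ch)
      out[[length(out) + 1L]] <- data.frame(
        edge = row, fraction = frac,
        from = maps$states[fromto[1]], to = maps$states[fromto[2]],
        midpoint_age = unname((ages[p] + ages[ch]) / 2))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(edge = integer(0), fraction = numeric(0), from = character(0),
               to = character(0), midpoint_age = numeric(0))
}

#' Marginal posterior state probabilities at nodes under an Mk model
#'
#' Two-pass belief propagation on the tree: the pruning (down) pass
#' conditionals are combined with an outside (up) pass, giving each node's
#' marginal posterior given all tip data.
#'
#' @param tree `phylo`.
#' @param tip_states named vector over tips.
#' @param model an `mk_model` (or list with `Q`, `root`).
#' @return matrix (nodes x states) of posterior probabilities.
#' @export
mk_node_marginals <- function(tree, tip_states, model) {
  pr <- mk_pruning(tree, tip_states, model$Q, model$root)
  po <- pr$postorder
  k <- ncol(pr$cond)
  ntip <- ape::Ntip(tree); nn <- ntip + tree$Nnode
  # per-edge normalized contribution vectors to the parent partial
  contrib <- vector("list", nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    v <- drop(pr$Pmats[[e]] %*% pr$cond[po$edge[e, 2], ])
    contrib[[e]] <- v / sum(v)
  }
  edges_of_parent <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  U <- matrix(0, nn, k)
  U[ntip + 1L, ] <- pr$pi
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sib_edges <- setdiff(edges_of_parent[[as.character(p)]], e)
    sib_prod <- rep(1, k)
    for (se in sib_edges) sib_prod <- sib_prod * contrib[[se]]
    O <- U[p, ] * sib_prod
    U[ch, ] <- drop(O %*% pr$Pmats[[e]])
  }
  M <- pr$cond * U
  M <- M / rowSums(M)
  colnames(M) <- pr$states
  M
}
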