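#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Each internal node's estimate is the ML root state of the tree re-rooted
#' at that node (phylogenetically weighted mean); the root estimate equals
#' the GLS mean under the Brownian covariance. Zero-length terminal branches
#' are perturbed by 1e-8 Ma with a warning.
#'
#' @param tree ultrametric `phylo`.
#' @param tip_values named numeric vector covering every tip.
#' @return data.frame with one row per node (tips first): `node`, `age`,
#'   `estimate`, `variance` (0 for tips).
#' @export
ancestral_states_bm <- function(tree, tip_values) {
  stopifnot(all(tree$tip.label %in% names(tip_values)))
  x <- tip_values[tree$tip.label]
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] <= 0)) {
    warning("zero-length terminal branches perturbed by 1e-8")
    tree$edge.length[term] <- pmax(tree$edge.length[term], 1e-8)
  }
  fa <- phytools::fastAnc(tree, x, vars = TRUE)
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  data.frame(node = seq_len(ntip + tree$Nnode), age = unname(ages),
             estimate = c(unname(x), unname(fa$ace)),
             variance = c(rep(0, ntip), unname(fa$var)))
}

#' Pagel's lambda phylogenetic signal
#'
#' Maximises the Brownian multivariate-normal likelihood with off-diagonal
#' covariances scaled by lambda, and reports a one-degree-of-freedom
#' likelihood-ratio test against lambda = 0.
#'
#' @param tree `phylo` with at least 4 tips.
#' @param tip_values named numeric vector.
#' @return list with `lambda_hat`, `logL`, `logL0` (lambda = 0), `p_value`.
#' @export
pagels_lambda <- function(tree, tip_values) {
  stopifnot(ape::Ntip(tree) >= 4)
  x <- tip_values[tree$tip.label]
  ps <- phytools::phylosig(tree, x, method = "lambda", test = TRUE)
  list(lambda_hat = ps$lambda, logL = ps$logL, logL0 = ps$logL0,
       p_value = ps$P)
}

#' Niche category specification
#'
#' Precipitation-regime categories: for MAP (mm/yr) dry < 1200, wet > 1800,
#' intermediate between, minimum change 250 mm; for DSL (months) dry > 8,
#' wet < 4, intermediate between, minimum change 1 month (note the reversed
#' direction: long dry seasons are dry).
#'
#' @param variable `"MAP"` or `"DSL"`.
#' @param boundaries,min_change override the defaults.
#' @return list of class `niche_category_spec`.
#' @export
niche_category_spec <- function(variable = c("MAP", "DSL"), boundaries = NULL,
                                min_change = NULL) {
  variable <- match.arg(variable)
  if (variable == "MAP") {
    b <- if (is.null(boundaries)) c(dry_below = 1200, wet_above = 1800) else boundaries
    mc <- if (is.null(min_change)) 250 else min_change
    dir <- "increasing"
  } else {
    b <- if (is.null(boundaries)) c(wet_below = 4, dry_above = 8) else boundaries
    mc <- if (is.null(min_change)) 1 else min_change
    dir <- "decreasing"
  }
  stopifnot(b[1] < b[2], mc > 0)
  structure(list(variable = variable, boundaries = unname(b),
                 min_change = mc, direction = dir),
            class = "niche_category_spec")
}

#' Categorize niche values
#' @param values numeric vector.
#' @param spec a [niche_category_spec()].
#' @return character vector in dry/intermediate/wet.
#' @export
categorize_niche <- function(values, spec) {
  b <- spec$boundaries
  if (spec$direction == "increasing") {
    ifelse(values < b[1], "dry", ifelse(values > b[2], "wet", "intermediate"))
  } else {
    ifelse(values < b[1], "wet", ifelse(values > b[2], "dry", "intermediate"))
  }
}

#' Detect niche shifts along branches
#'
#' A branch carries a shift iff the parent and child niche categories differ
#' and the absolute change in the reconstructed value is at least
#' `spec$min_change`. Terminal branches use the observed tip value as the
#' child state. The shift is dated at the midpoint of the parent and child
#' node ages.
#'
#' @param tree `phylo`.
#' @param node_states numeric vector over all nodes (tips then internals),
#'   e.g. `estimate` from [ancestral_states_bm()].
#' @param spec a [niche_category_spec()].
#' @return data.frame, one row per shift: `edge`, `child`, `parent_value`,
#'   `child_value`, `parent_category`, `child_category`, `delta`,
#'   `parent_age`, `child_age`, `shift_age`.
#' @export
detect_niche_shifts <- function(tree, node_states, spec) {
  ages <- node_ages(tree)
  pv <- node_states[tree$edge[, 1]]
  cv <- node_states[tree$edge[, 2]]
  pc <- categorize_niche(pv, spec); cc <- categorize_niche(cv, spec)
  hit <- pc != cc & abs(cv - pv) >= spec$min_change
  pa <- ages[tree$edge[, 1]]; ca <- ages[tree$edge[, 2]]
  out <- data.frame(edge = which(hit), child = tree$edge[hit, 2],
                    parent_value = pv[hit], child_value = cv[hit],
                    parent_category = pc[hit], child_category = cc[hit],
                    delta = cv[hit] - pv[hit],
                    parent_age = unname(pa[hit]), child_age = unname(ca[hit]),
                    shift_age = unname((pa[hit] + ca[hit]) / 2))
  rownames(out) <- NULL
  out
}

#' Shifts per 5-Ma time bin relative to phylogenetic splits
#'
#' Bins tile `[0, root age]`; a bin's split count is the number of internal
#' nodes whose age falls in it (branch midpoints behind
#' `denominator = "branches"`), and its shift count the number of shifts
#' whose midpoint age falls in it.
#'
#' @param shifts data.frame with a `shift_age` column (possibly empty).
#' @param tree dated `phylo`.
#' @param bin_width bin width in Ma (default 5).
#' @param denominator `"splits"` (internal nodes) or `"branches"`.
#' @return data.frame: `bin_start`, `bin_end`, `n_shifts`, `n_splits`,
#'   `fraction` (`NA` when the denominator is 0).
#' @export
shifts_per_time_bin <- function(shifts, tree, bin_width = 5,
                                denominator = c("splits", "branches")) {
  denominator <- match.arg(denominator)
  ages <- node_ages(tree)
  root_age <- max(ages)
  breaks <- seq(0, root_age + bin_width, by = bin_width)
  ntip <- ape::Ntip(tree)
  denom_ages <- if (denominator == "splits") {
    ages[(ntip + 1):(ntip + tree$Nnode)]
  } else {
    (ages[tree$edge[, 1]] + ages[tree$edge[, 2]]) / 2
  }
  bin_of <- function(a) findInterval(a, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  n_splits <- tabulate(bin_of(denom_ages), nb)
  n_shifts <- if (nrow(shifts)) tabulate(bin_of(shifts$shift_age), nb) else
    rep(0L, nb)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             n_shifts = n_shifts, n_splits = n_splits,
             fraction = ifelse(n_splits > 0, n_shifts / n_splits, NA_real_))
}

#' Classify tips as tropical or temperate from frost exposure
#'
#' A taxon is temperate iff strictly more than half of its occurrence
#' records fall in frost-experiencing cells; ties and frost-free majorities
#' are tropical.
#'
#' @param records data.frame with `taxon`, `lon`, `lat`.
#' @param frost_df data.frame with `lon`, `lat`, `frost` (logical) at cell
#'   resolution.
#' @param resolution cell size in degrees.
#' @return named character vector, `"tropical"` or `"temperate"` per taxon.
#' @export
classify_tropical <- function(records, frost_df, resolution = 0.5) {
  key <- function(lon, lat) paste0(floor(lon / resolution), "_",
                                   floor(lat / resolution))
  fr <- stats::setNames(as.logical(frost_df$frost),
                        key(frost_df$lon, frost_df$lat))
  hit <- fr[key(records$lon, records$lat)]
  frac <- tapply(hit, as.character(records$taxon),
                 function(v) mean(v, na.rm = TRUE))
  out <- ifelse(!is.na(frac) & frac > 0.5, "temperate", "tropical")
  stats::setNames(as.character(out), names(frac))
}
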