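#' Simpson (beta-sim) turnover from pair components
#'
#' `min(b, c) / (a + min(b, c))`: the richness-independent "true turnover"
#' component of Sorensen dissimilarity. `a` is the shared quantity (species
#' count or shared branch length), `b` and `c` the quantities unique to each
#' cell.
#'
#' @param a,b,c non-negative pair components.
#' @return dissimilarity in `[0, 1]`; `NA` when `a = 0` and `min(b, c) = 0`
#'   (undefined pair).
#' @export
simpson_turnover <- function(a, b, c) {
  stopifnot(a >= 0, b >= 0, c >= 0)
  m <- min(b, c)
  if (a == 0 && m == 0) return(NA_real_)
  m / (a + m)
}

#' Sorensen dissimilarity from pair components
#' @inheritParams simpson_turnover
#' @return `(b + c) / (2a + b + c)`; `NA` when all components are 0.
#' @export
sorensen_dissimilarity <- function(a, b, c) {
  if (a + b + c == 0) return(NA_real_)
  (b + c) / (2 * a + b + c)
}

#' Reverse PBD deviation
#'
#' `PBD_dev = (TBD - PBD) / TBD` measures how much phylogenetic beta diversity
#' (PBD) falls below taxonomic beta diversity (TBD); its negation increases
#' with lineage-level turnover beyond species turnover.
#'
#' @param taxonomic_bd taxonomic beta diversity (> 0).
#' @param phylo_bd phylogenetic beta diversity.
#' @return `-(TBD - PBD)/TBD`; `NA` when `TBD = 0`.
#' @export
pbd_dev_reverse <- function(taxonomic_bd, phylo_bd) {
  if (is.na(taxonomic_bd) || taxonomic_bd == 0) return(NA_real_)
  -(taxonomic_bd - phylo_bd) / taxonomic_bd
}

# edge x species incidence: TRUE when the species descends from the edge's
# child node; rows follow tree$edge order
edge_species_matrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  m <- matrix(FALSE, nrow(tree$edge), ntip,
              dimnames = list(NULL, tree$tip.label))
  for (e in seq_len(nrow(tree$edge)))
    m[e, desc[[tree$edge[e, 2]]]] <- TRUE
  m
}

#' Phylogenetic pair components on a rooted dated tree
#'
#' Branch lengths of the spanning subtree of the union of both tip sets are
#' classified as shared (`a`: ancestral to members of both sets), or unique to
#' either set (`b`, `c`). The branch subtending the MRCA of the union (and
#' everything rootward of it) is excluded, so the dissimilarity depends only
#' on the spanning subtree and equals taxonomic Simpson on a star tree.
#'
#' @param tree `phylo`.
#' @param species_i,species_j character vectors of tip labels.
#' @param esm optional precomputed [edge_species_matrix()] for `tree`.
#' @return list with `a`, `b`, `c` (branch lengths in Ma).
#' @export
phylo_components <- function(tree, species_i, species_j, esm = NULL) {
  stopifnot(all(species_i %in% tree$tip.label),
            all(species_j %in% tree$tip.label))
  if (is.null(esm)) esm <- edge_species_matrix(tree)
  n_i <- rowSums(esm[, species_i, drop = FALSE])
  n_j <- rowSums(esm[, species_j, drop = FALSE])
  un <- union(species_i, species_j)
  n_u <- rowSums(esm[, un, drop = FALSE])
  keep <- n_u > 0 & n_u < length(un)
  el <- tree$edge.length
  list(a = sum(el[keep & n_i > 0 & n_j > 0]),
       b = sum(el[keep & n_i > 0 & n_j == 0]),
       c = sum(el[keep & n_i == 0 & n_j > 0]))
}

#' Pairwise dissimilarity table between grid cells
#'
#' Computes, for every unordered cell pair, taxonomic and phylogenetic
#' Simpson turnover and Sorensen dissimilarity, the reverse PBD deviation,
#' great-circle distance between cell centers (haversine, 6371-km sphere),
#' per-predictor climate values for both cells, and biome distance when
#' biomes are attached. In `ancient` mode the tree is first collapsed at
#' `cutoff` Ma and cell incidences are mapped to the surviving lineages.
#'
#' @param grid a filtered `occurrence_grid`.
#' @param tree ultrametric `phylo`; tips must cover the grid's species
#'   (species absent from the tree are dropped with a message).
#' @param mode `"full"` or `"ancient"`.
#' @param cutoff slice age in Ma for `ancient` mode.
#' @return data.frame of class `dissimilarity_table`.
#' @export
pairwise_table <- function(grid, tree, mode = c("full", "ancient"),
                           cutoff = 0) {
  mode <- match.arg(mode)
  inc <- grid$incidence
  missing_sp <- setdiff(rownames(inc), tree$tip.label)
  if (length(missing_sp)) {
    message(length(missing_sp), " grid species absent from tree dropped")
    inc <- inc[setdiff(rownames(inc), missing_sp), , drop = FALSE]
  }
  if (mode == "ancient" && cutoff > 0) {
    sl <- slice_tree_at(tree, cutoff)
    tree <- sl$tree
    lin_inc <- t(vapply(sl$lineages, function(sp) {
      sp <- intersect(sp, rownames(inc))
      if (length(sp) == 0L) rep(FALSE, ncol(inc)) else
        colSums(inc[sp, , drop = FALSE]) > 0
    }, logical(ncol(inc))))
    colnames(lin_inc) <- colnames(inc)
    inc <- lin_inc
  } else {
    tree <- ape::keep.tip(tree, rownames(inc))
  }
  empty <- colSums(inc) == 0
  if (any(empty)) {
    message(sum(empty), " cells with zero lineages after slicing dropped")
    keep_cells <- which(!empty)
  } else keep_cells <- seq_len(ncol(inc))

  esm <- edge_species_matrix(tree)
  sets <- lapply(keep_cells, function(j) rownames(inc)[inc[, j]])
  pairs <- utils::combn(seq_along(keep_cells), 2)
  cells <- grid$cells[keep_cells, , drop = FALSE]

  one_pair <- function(i, j) {
    si <- sets[[i]]; sj <- sets[[j]]
    a_t <- length(intersect(si, sj))
    b_t <- length(setdiff(si, sj)); c_t <- length(setdiff(sj, si))
    pc <- phylo_components(tree, si, sj, esm)
    tax_sim <- simpson_turnover(a_t, b_t, c_t)
    phy_sim <- simpson_turnover(pc$a, pc$b, pc$c)
    c(taxonomic_sim = tax_sim,
      taxonomic_sorensen = sorensen_dissimilarity(a_t, b_t, c_t),
      phylo_sim = phy_sim,
      phylo_sorensen = sorensen_dissimilarity(pc$a, pc$b, pc$c),
      pbd_dev_reverse = pbd_dev_reverse(tax_sim, phy_sim))
  }
  mets <- t(apply(pairs, 2, function(p) one_pair(p[1], p[2])))
  p1 <- pairs[1, ]; p2 <- pairs[2, ]
  gd <- geosphere::distHaversine(cbind(cells$lon[p1], cells$lat[p1]),
                                 cbind(cells$lon[p2], cells$lat[p2]),
                                 r = 6371000) / 1000
  out <- data.frame(cell_i = cells$cell[p1], cell_j = cells$cell[p2],
                    mets, geographic_distance_km = gd)
  if (!is.null(grid$climate)) {
    clim <- grid$climate[keep_cells, , drop = FALSE]
    for (v in colnames(clim)) {
      out[[paste0(v, "_i")]] <- clim[p1, v]
      out[[paste0(v, "_j")]] <- clim[p2, v]
    }
  }
  if (!is.null(grid$biome)) {
    bio <- grid$biome[keep_cells]
    out$biome_distance <- mapply(function(i, j)
      if (is.na(bio[i]) || is.na(bio[j])) NA_real_ else biome_distance(bio[i], bio[j]),
      p1, p2)
  }
  class(out) <- c("dissimilarity_table", "data.frame")
  out
}
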