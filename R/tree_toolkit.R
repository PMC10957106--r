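#' Node ages of a time-calibrated tree
#'
#' Ages are measured in Ma before present: tips of an ultrametric tree are at
#' (approximately) 0 and the root is the oldest node.
#'
#' @param tree an ultrametric `phylo` object with branch lengths in Ma.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node id.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  names(ages) <- c(tree$tip.label,
                   if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label)
  ages
}

#' Check ultrametricity by absolute root-to-tip spread
#'
#' @param tree a `phylo` object.
#' @param tol maximum allowed spread of root-to-tip path lengths, in Ma.
#' @return `TRUE` iff the spread of root-to-tip distances is at most `tol`.
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(depth) - min(depth)) <= tol
}

# crown age of a tree with >= 2 tips (root age above its tips)
crown_age <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Graft a dated subtree onto a dated backbone
#'
#' Replaces a set of backbone tips by a subtree, rescaling the subtree
#' uniformly so that its crown age equals the attachment age. When
#' `tips_to_replace` has two or more tips the attachment point is their most
#' recent common ancestor in the backbone (a crown graft; if the tips are
#' paraphyletic the subtree is still attached at their MRCA and all of them
#' are removed). When a single tip is replaced the subtree is attached halfway
#' along that terminal branch.
#'
#' @param backbone ultrametric `phylo` backbone.
#' @param subtree ultrametric `phylo` (or a single tip label given as a
#'   one-tip tree via [single_tip_tree()]).
#' @param tips_to_replace character vector of backbone tip labels, non-empty.
#' @return an ultrametric `phylo` with
#'   `Ntip(backbone) - length(tips_to_replace) + Ntip(subtree)` tips.
#' @export
graft_subtree <- function(backbone, subtree, tips_to_replace) {
  stopifnot(length(tips_to_replace) >= 1)
  if (!all(tips_to_replace %in% backbone$tip.label))
    stop("tips_to_replace not all present in backbone")
  ages <- node_ages(backbone)
  ntip <- ape::Ntip(backbone)

  if (length(tips_to_replace) == 1L) {
    tip_id <- match(tips_to_replace, backbone$tip.label)
    edge_i <- which(backbone$edge[, 2] == tip_id)
    attach_age <- backbone$edge.length[edge_i] / 2 + ages[tip_id]
  } else {
    mrca <- ape::getMRCA(backbone, tips_to_replace)
    attach_age <- ages[mrca]
  }
  if (attach_age <= 0) stop("attachment age must be positive")

  sub <- rescale_to_crown_age(subtree, attach_age)

  clade_tips <- if (length(tips_to_replace) >= 2L) {
    mrca <- ape::getMRCA(backbone, tips_to_replace)
    backbone$tip.label[unlist(descendant_tips(backbone)[mrca])]
  } else tips_to_replace
  monophyletic <- setequal(clade_tips, tips_to_replace)

  if (length(tips_to_replace) == 1L || monophyletic) {
    placeholder <- tips_to_replace[1]
    keep_drop <- setdiff(tips_to_replace, placeholder)
    bb <- if (length(keep_drop)) ape::drop.tip(backbone, keep_drop) else backbone
    where <- match(placeholder, bb$tip.label)
    out <- ape::bind.tree(bb, sub, where = where, position = attach_age)
    # single-tip subtrees keep the degree-2 attachment node so the pendant
    # branch records the attachment age
    out <- ape::drop.tip(out, placeholder,
                         collapse.singles = ape::Ntip(sub) > 1L)
  } else {
    # paraphyletic: remove all, then attach on the edge crossing attach_age
    # above the MRCA of the retained descendants of the original MRCA
    mrca <- ape::getMRCA(backbone, tips_to_replace)
    desc <- backbone$tip.label[unlist(descendant_tips(backbone)[mrca])]
    retained <- setdiff(desc, tips_to_replace)
    bb <- ape::drop.tip(backbone, tips_to_replace)
    ages2 <- node_ages(bb)
    anchor <- if (length(retained) >= 2L) ape::getMRCA(bb, retained) else
      match(retained, bb$tip.label)
    pos <- attach_age - ages2[anchor]
    if (pos < -1e-8) stop("attachment point below anchor node; cannot graft")
    pos <- max(pos, 0)
    if (anchor == ape::Ntip(bb) + 1L) bb$root.edge <- pos  # graft above the root
    out <- ape::bind.tree(bb, sub, where = anchor, position = pos)
  }
  if (anyDuplicated(out$tip.label))
    stop("duplicate tip labels after grafting")
  out$node.label <- NULL
  stopifnot(check_ultrametric(out, 1e-6))
  out
}

# uniform rescale so that crown age equals `age`; single-tip subtrees become a
# pendant branch of length `age`
rescale_to_crown_age <- function(subtree, age) {
  if (ape::Ntip(subtree) == 1L) {
    sub <- subtree
    sub$edge.length <- age
    sub$root.edge <- 0
    return(sub)
  }
  ca <- crown_age(subtree)
  if (ca <= 0) stop("subtree crown age must be positive")
  f <- age / ca
  if (f <= 0) stop("rescale factor must be positive")
  subtree$edge.length <- subtree$edge.length * f
  subtree$root.edge <- 0
  subtree
}

#' One-tip tree helper
#' @param label tip label
#' @param length branch length (default 1)
#' @return a `phylo` with a single tip
#' @export
single_tip_tree <- function(label, length = 1) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                 edge.length = length, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

# list of descendant tip indices per node (1..Ntip+Nnode)
descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  # postorder: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; c <- po$edge[k, 2]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

#' Expand genera into polytomies on a dated backbone
#'
#' Species are attached as a star polytomy per genus: at the genus crown node
#' when the genus has two or more backbone tips, or halfway along the terminal
#' branch when the genus is represented by a single backbone tip. Backbone
#' tips are matched to genera by the label prefix before the first underscore
#' (or the whole label).
#'
#' @param backbone ultrametric `phylo`.
#' @param genus_membership named list: genus -> character vector of species.
#' @return ultrametric `phylo` whose tip set is the union of all species.
#' @export
expand_genus_polytomies <- function(backbone, genus_membership) {
  stopifnot(length(genus_membership) >= 1, !is.null(names(genus_membership)))
  tree <- backbone
  for (g in names(genus_membership)) {
    sp <- genus_membership[[g]]
    stopifnot(length(sp) >= 1)
    gtips <- tree$tip.label[genus_of(tree$tip.label) == g]
    if (length(gtips) == 0) stop("genus not found in backbone: ", g)
    if (length(sp) == 1L && length(gtips) == 1L) {
      tree$tip.label[match(gtips, tree$tip.label)] <- sp
      next
    }
    star <- if (length(sp) == 1L) single_tip_tree(sp) else {
      s <- ape::stree(length(sp), type = "star", tip.label = sp)
      s$edge.length <- rep(1, nrow(s$edge))
      s
    }
    tree <- graft_subtree(tree, star, gtips)
  }
  tree
}

genus_of <- function(labels) sub("_.*$", "", labels)

#' Collapse a dated tree at a time slice
#'
#' Every branch crossing `cutoff_ma` becomes one lineage; the sliced tree is
#' ultrametric with its tips at the cutoff (re-zeroed, so tip ages are 0 and
#' the root age is the original root age minus the cutoff). Used for "ancient
#' turnover": beta diversity among the lineages present at a past time.
#'
#' @param tree ultrametric `phylo`.
#' @param cutoff_ma age of the slice in Ma, `0 <= cutoff_ma < root age`.
#' @return list with `tree` (sliced `phylo`) and `lineages` (named list:
#'   lineage tip label -> character vector of original tip labels).
#' @export
slice_tree_at <- function(tree, cutoff_ma) {
  ages <- node_ages(tree)
  root_age <- max(ages)
  if (cutoff_ma < 0 || cutoff_ma >= root_age)
    stop("cutoff must be in [0, root age)")
  if (cutoff_ma == 0) {
    lin <- as.list(tree$tip.label)
    names(lin) <- tree$tip.label
    return(list(tree = tree, lineages = lin))
  }
  ntip <- ape::Ntip(tree)
  parent_age <- ages[tree$edge[, 1]]
  child_age <- ages[tree$edge[, 2]]
  crossing <- which(parent_age > cutoff_ma & child_age <= cutoff_ma)
  desc <- descendant_tips(tree)
  lineages <- lapply(crossing, function(i) tree$tip.label[desc[[tree$edge[i, 2]]]])
  reps <- vapply(lineages, `[`, character(1), 1)
  if (length(reps) == 1L) stop("cutoff leaves a single lineage; nothing to compare")
  sliced <- ape::keep.tip(tree, reps)
  sages <- node_ages(sliced)
  # trim each terminal branch so its tip sits exactly at the cutoff
  for (k in which(sliced$edge[, 2] <= ape::Ntip(sliced))) {
    p <- sliced$edge[k, 1]
    sliced$edge.length[k] <- sages[p] - cutoff_ma
  }
  new_labels <- paste0("lineage_", seq_along(reps))
  names(lineages) <- new_labels[match(sliced$tip.label, reps)[order(match(reps, sliced$tip.label))]]
  # order lineage list to match rep order; relabel sliced tips consistently
  lab_map <- stats::setNames(new_labels, reps)
  sliced$tip.label <- unname(lab_map[sliced$tip.label])
  names(lineages) <- unname(lab_map[reps])
  stopifnot(check_ultrametric(sliced, 1e-6))
  list(tree = sliced, lineages = lineages)
}
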