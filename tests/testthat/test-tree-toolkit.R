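backbone4 <- ape::read.tree(text = "((a:20,b:20):10,(c:5,d:5):25);")

test_that("node ages and ultrametricity bookkeeping are consistent", {
  ages <- node_ages(backbone4)
  expect_equal(unname(ages[1:4]), rep(0, 4))
  expect_equal(unname(ages[5]), 30)
  expect_equal(unname(ages[ape::getMRCA(backbone4, c("a", "b"))]), 20)
  t2 <- ape::read.tree(text = "(a:5,b:5);")
  expect_equal(unname(node_ages(t2)[3]), 5)
  expect_true(check_ultrametric(t2, 1e-6))
  t2$edge.length[1] <- 5 + 1e-3
  expect_false(check_ultrametric(t2, 1e-6))
})

test_that("crown grafts rescale the subtree to the attachment age", {
  sub <- ape::read.tree(text = "((x:4,y:4):6,z:10);")  # crown age 10
  out <- graft_subtree(backbone4, sub, c("a", "b"))    # attachment age 20
  expect_equal(ape::Ntip(out), 4 - 2 + 3)
  expect_true(check_ultrametric(out, 1e-6))
  ages <- node_ages(out)
  expect_equal(unname(ages[ape::getMRCA(out, c("x", "y", "z"))]), 20)
  expect_equal(unname(ages[ape::getMRCA(out, c("x", "y"))]), 8)  # 4 * 2
  expect_equal(unname(ages[ape::getMRCA(out, c("x", "c"))]), 30)
})

test_that("single-tip subtrees and terminal-branch grafts behave as stated", {
  out <- graft_subtree(backbone4, single_tip_tree("z"), c("a", "b"))
  expect_setequal(out$tip.label, c("z", "c", "d"))
  zedge <- which(out$edge[, 2] == match("z", out$tip.label))
  expect_equal(unname(out$edge.length[zedge]), 20)  # pendant at the attachment age

  # replacing one tip attaches halfway along its terminal branch
  sub <- ape::read.tree(text = "(p:1,q:1);")
  out2 <- graft_subtree(backbone4, sub, "c")
  ages <- node_ages(out2)
  expect_equal(unname(ages[ape::getMRCA(out2, c("p", "q"))]), 2.5)
  expect_equal(ape::Ntip(out2), 5)
  expect_true(check_ultrametric(out2, 1e-6))
})

test_that("random grafts preserve ultrametricity and the tip-count identity", {
  for (r in 1:25) {
    set.seed(r)
    bb <- random_ultra_tree(20, scale = 30)
    tree <- bb
    for (g in 1:3) {
      sub <- random_ultra_tree(sample(2:5, 1))
      sub$tip.label <- paste0("g", g, "_", sub$tip.label, "_", r)
      k <- sample(2:4, 1)
      repl <- sample(tree$tip.label[grepl("^t", tree$tip.label)],
                     min(k, sum(grepl("^t", tree$tip.label)) - 2))
      before <- ape::Ntip(tree)
      tree <- graft_subtree(tree, sub, repl)
      expect_equal(ape::Ntip(tree), before - length(repl) + ape::Ntip(sub))
      depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
      expect_lt(stats::var(depth), 1e-6)
    }
    expect_false(anyDuplicated(tree$tip.label) > 0)
  }
})

test_that("genus polytomies expand at the crown or the terminal midpoint", {
  bb <- ape::read.tree(text = "((GenA_x:20,GenA_y:20):10,(GenB_x:8,GenC_x:8):22);")
  members <- list(GenB = paste0("GenB_sp", 1:5),
                  GenA = c("GenA_sp1", "GenA_sp2", "GenA_sp3"),
                  GenC = "GenC_sp1")
  out <- expand_genus_polytomies(bb, members)
  expect_setequal(out$tip.label, unlist(members))
  expect_true(check_ultrametric(out, 1e-6))
  ages <- node_ages(out)
  # single backbone tip of length 8: polytomy halfway, five tips of length 4
  bnode <- ape::getMRCA(out, members$GenB)
  expect_equal(unname(ages[bnode]), 4)
  bedges <- out$edge.length[out$edge[, 1] == bnode]
  expect_equal(unname(bedges), rep(4, 5))
  # multi-tip genus: polytomy at the genus crown (age 20)
  expect_equal(unname(ages[ape::getMRCA(out, members$GenA)]), 20)
  # single species in a single-tip genus is a pure relabel
  expect_true("GenC_sp1" %in% out$tip.label)
})

test_that("time slicing collapses young branches into lineages", {
  tr <- ape::read.tree(text = "((a:10,b:10):30,(c:10,d:10):30);")
  sl <- slice_tree_at(tr, 20)
  expect_equal(ape::Ntip(sl$tree), 2)
  expect_setequal(vapply(sl$lineages, paste, character(1), collapse = "+"),
                  c("a+b", "c+d"))
  expect_true(check_ultrametric(sl$tree, 1e-6))
  expect_equal(unname(node_ages(sl$tree)[3]), 20)  # re-zeroed at the cutoff

  sl0 <- slice_tree_at(tr, 0)
  expect_identical(sl0$tree, tr)
  expect_error(slice_tree_at(tr, 40), "cutoff")
})

test_that("lineage counts equal an independent branch-crossing count", {
  for (r in 1:20) {
    set.seed(100 + r)
    tr <- random_ultra_tree(50, scale = 20)
    cutoff <- stats::runif(1, 0.5, 15)
    ages <- node_ages(tr)
    ltt <- sum(ages[tr$edge[, 1]] > cutoff & ages[tr$edge[, 2]] <= cutoff)
    if (ltt < 2) next
    sl <- slice_tree_at(tr, cutoff)
    expect_equal(ape::Ntip(sl$tree), ltt)
    # idempotence: re-slicing at the same cutoff (age 0 after re-zeroing)
    expect_setequal(unlist(sl$lineages), tr$tip.label)
  }
})
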