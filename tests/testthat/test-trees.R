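test_that("long-branch pruning removes pendant branches strictly over the cutoff", {
  tr <- ape::read.tree(text = "((A:1.6,B:1.5):0.1,(C:0.2,D:2.5):0.1);")
  res <- prune_long_branches(tr)
  expect_setequal(res$removed, c("A", "D"))
  expect_setequal(res$tree$tip.label, c("B", "C"))

  tr2 <- ape::read.tree(text = "((A:1.5,B:0.2):0.1,C:0.3);")
  res2 <- prune_long_branches(tr2)
  expect_equal(res2$removed, character())
  expect_equal(res2$tree$tip.label, tr2$tip.label)

  tr3 <- ape::read.tree(text = "((A,B),C);")
  expect_error(prune_long_branches(tr3), "branch lengths")
})

test_that("pruning suppresses degree-2 nodes and sums the branch lengths", {
  tr <- ape::read.tree(text = "((A:2.0,B:0.3):0.4,C:0.5);")
  res <- prune_long_branches(tr)
  # B's pendant now includes the suppressed internal edge
  expect_equal(sort(res$tree$tip.label), c("B", "C"))
  bl <- res$tree$edge.length[res$tree$edge[, 2] == which(res$tree$tip.label == "B")]
  expect_equal(bl, 0.7)
})

test_that("monophyly is decided by edge bipartitions", {
  tr <- ape::read.tree(text = "((f1:1,f2:1):1,(x1:1,x2:1):1);")
  expect_equal(test_monophyly(tr, c("f1", "f2"))$status, "monophyletic")

  tr2 <- ape::read.tree(text = "((f1:1,x1:1):1,(f2:1,x2:1):1);")
  v <- test_monophyly(tr2, c("f1", "f2"))
  expect_equal(v$status, "non-monophyletic")
  expect_equal(length(v$largest_focal_clade), 1)

  expect_error(test_monophyly(tr, character()), "non-empty")
})

test_that("monophyly equals the exhaustive bipartition oracle on random trees", {
  set.seed(13)
  for (k in 1:60) {
    tr <- ape::rtree(12)
    focal <- sample(tr$tip.label, sample(2:6, 1))
    v <- test_monophyly(tr, focal)
    expect_equal(v$status == "monophyletic", oracle_monophyletic(tr, focal))
    expect_equal(length(v$largest_focal_clade), oracle_largest_focal(tr, focal))
  }
})

test_that("monophyly is invariant under re-rooting and leaf permutation", {
  set.seed(14)
  for (k in 1:20) {
    tr <- ape::rtree(10)
    focal <- sample(tr$tip.label, 4)
    v0 <- test_monophyly(tr, focal)$status
    out <- sample(setdiff(tr$tip.label, focal), 1)
    rr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    expect_equal(test_monophyly(rr, focal)$status, v0)
    expect_equal(test_monophyly(tr, sample(focal))$status, v0)
  }
})

test_that("focal groups split into supported distinct clades", {
  tr <- ape::read.tree(
    text = "(((f1:1,f2:1)100:1,(x1:1,x2:1)90:1)80:1,((f3:1,f4:1)96:1,x3:1)70:1);")
  g <- split_focal_groups(tr, c("f1", "f2", "f3", "f4"))
  expect_equal(nrow(g), 2)
  expect_true(all(g$distinct))
  expect_setequal(g$support, c(100L, 96L))

  # monophyletic focal set collapses to a single group
  g1 <- split_focal_groups(tr, c("f1", "f2"))
  expect_equal(nrow(g1), 1)
  expect_equal(g1$size, 2)

  # scattered singletons are groups of size one, never distinct
  tr2 <- ape::read.tree(
    text = "(((f1:1,x1:1)99:1,(f2:1,x2:1)99:1)99:1,((f3:1,x3:1)99:1,x4:1)99:1);")
  g2 <- split_focal_groups(tr2, c("f1", "f2", "f3"))
  expect_equal(nrow(g2), 3)
  expect_true(all(g2$size == 1))
  expect_false(any(g2$distinct))
})

test_that("a focal leaf nested in a supported foreign clade is an HGT candidate", {
  tr <- ape::read.tree(
    text = "(((f1:1,f2:1)100:1,(m1:1,m2:1)90:1)100:1,((p1:1,p2:1)99:1,f_moved:1)98:1);")
  gmap <- c(f1 = "A", f2 = "A", f_moved = "B",
            m1 = "Myxococcota", m2 = "Myxococcota", p1 = "PVC", p2 = "PVC")
  v <- classify_hgt(tr, c("f1", "f2", "f_moved"), gmap)
  row <- v[v$sequence_id == "f_moved", ]
  expect_equal(row$verdict, "hgt_candidate")
  expect_equal(row$donor_group, "PVC")
  expect_equal(row$nest_support, 98L)
  expect_true(all(v$verdict[v$sequence_id != "f_moved"] == "vertical"))
})

test_that("HGT verdicts partition the focal set and never double-label", {
  set.seed(15)
  for (k in 1:20) {
    tr <- ape::rtree(12)
    tr$node.label <- as.character(sample(80:100, tr$Nnode, replace = TRUE))
    focal <- sample(tr$tip.label, 5)
    gmap <- setNames(ifelse(tr$tip.label %in% focal, "A", "PVC"), tr$tip.label)
    v <- classify_hgt(tr, focal, gmap)
    expect_equal(sort(v$sequence_id), sort(focal))
    expect_true(all(v$verdict %in% c("vertical", "hgt_candidate", "unresolved")))
  }
})

test_that("weak support yields unresolved, never vertical", {
  tr <- ape::read.tree(
    text = "(((f1:1,f2:1)100:1,x0:1)100:1,((p1:1,p2:1)99:1,f_moved:1)80:1);")
  gmap <- c(f1 = "A", f2 = "A", x0 = "other", f_moved = "B",
            p1 = "PVC", p2 = "PVC")
  v <- classify_hgt(tr, c("f1", "f2", "f_moved"), gmap)
  expect_equal(v$verdict[v$sequence_id == "f_moved"], "unresolved")
  # lowering the threshold resolves the same topology as a transfer
  v2 <- classify_hgt(tr, c("f1", "f2", "f_moved"), gmap,
                     thresholds(hgt_support_min = 75))
  expect_equal(v2$verdict[v2$sequence_id == "f_moved"], "hgt_candidate")
})

test_that("no supported majority donor yields unresolved", {
  tr <- ape::read.tree(
    text = "(((f1:1,f2:1)100:1,x0:1)100:1,((p1:1,n1:1)99:1,f_moved:1)97:1);")
  gmap <- c(f1 = "A", f2 = "A", x0 = "other", f_moved = "B",
            p1 = "PVC", n1 = "Nitrospirota")
  v <- classify_hgt(tr, c("f1", "f2", "f_moved"), gmap)
  # smallest supported enclosing clade is {p1,n1,f_moved}: 1 PVC vs 1 Nitrospirota
  expect_equal(v$verdict[v$sequence_id == "f_moved"], "unresolved")
})

test_that("classify_hgt requires a complete group map", {
  tr <- ape::read.tree(text = "((f1:1,f2:1)90:1,(x1:1,x2:1)90:1);")
  expect_error(classify_hgt(tr, c("f1", "f2"), c(f1 = "A", f2 = "A", x1 = "PVC")),
               "x2")
})

test_that("noiseless vertical gene trees classify every focal leaf vertical", {
  cfg <- sim_config(seed = 31, n_species = 15, loss_rate = 1, hgt_rate = 0)
  sp <- simulate_species_tree(cfg)
  for (enz in c("AcsA", "GCSPa", "FdhG")) {
    h <- simulate_trait_history(sp$tree, cfg, enz)
    g <- emit_gene_tree(sp$tree, h, cfg, enz)
    gmap <- c(g$group_map, setNames(unname(sp$clades[g$focal_leaves]), g$focal_leaves))
    expect_equal(test_monophyly(g$tree, g$focal_leaves)$status, "monophyletic")
    v <- classify_hgt(g$tree, g$focal_leaves, gmap)
    expect_true(all(v$verdict == "vertical"))
  }
})
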