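test_that("species tree simulation is deterministic and seed-sensitive", {
  cfg <- sim_config(seed = 1, n_species = 5)
  t1 <- simulate_species_tree(cfg)$tree
  t2 <- simulate_species_tree(cfg)$tree
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  t3 <- simulate_species_tree(sim_config(seed = 2, n_species = 5))$tree
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("simulated species trees have the requested shape and clade labels", {
  cfg <- sim_config(seed = 4, n_species = 50)
  sp <- simulate_species_tree(cfg)
  expect_equal(length(sp$tree$tip.label), 50)
  expect_equal(sp$tree$Nnode, 49)
  expect_true(ape::is.rooted(sp$tree) && ape::is.binary(sp$tree))
  expect_setequal(unique(sp$clades), LETTERS[1:5])
  # clades are monophyletic by construction
  for (cl in LETTERS[1:5]) {
    members <- names(sp$clades)[sp$clades == cl]
    if (length(members) > 1) {
      expect_equal(test_monophyly(sp$tree, members)$status, "monophyletic")
    }
  }
  expect_error(sim_config(seed = 1, n_species = 2), "n_species")
  expect_error(sim_config(1, dropout_rate = 2), "dropout_rate")
})

test_that("trait histories honour the null process and forced events", {
  cfg <- sim_config(seed = 6, n_species = 12, loss_rate = 0, hgt_rate = 0)
  sp <- simulate_species_tree(cfg)
  h <- simulate_trait_history(sp$tree, cfg, "quiet")
  expect_true(all(h$leaf_states))
  expect_equal(h$events$event, "gain")   # only the root gain is logged

  # forced loss on a known non-flank edge removes exactly that subtree
  n_tip <- length(sp$tree$tip.label)
  root <- n_tip + 1L
  pars <- sp$tree$edge[, 1]
  node <- sp$tree$edge[sp$tree$edge[, 2] > n_tip & pars != root, 2][2]
  sub <- ape::extract.clade(sp$tree, node)$tip.label
  hf <- simulate_trait_history(sp$tree, cfg, "forced", forced_loss_edges = node)
  expect_setequal(names(hf$leaf_states)[!hf$leaf_states], sub)
  expect_equal(sum(hf$events$event == "loss"), 1)
})

test_that("sampled loss counts match the Poisson expectation", {
  cfg <- sim_config(seed = 8, n_species = 40, loss_rate = 1.5, hgt_rate = 0)
  sp <- simulate_species_tree(cfg)
  draws <- vapply(1:200, function(i) {
    simulate_trait_history(sp$tree, cfg, paste0("t", i))$n_loss_drawn
  }, 1L)
  se <- sqrt(1.5 / 200)
  expect_lt(abs(mean(draws) - 1.5), 3 * se)
  # effective (post-masking, canonical) losses never exceed the draw
  eff <- vapply(1:200, function(i) {
    sum(simulate_trait_history(sp$tree, cfg, paste0("t", i))$events$event == "loss")
  }, 1)
  expect_true(all(eff <= draws))
})

test_that("trait history truth logs replay onto the leaf states", {
  cfg <- sim_config(seed = 9, n_species = 20, loss_rate = 2, hgt_rate = 0.6)
  sp <- simulate_species_tree(cfg)
  for (k in 1:10) {
    h <- simulate_trait_history(sp$tree, cfg, paste0("t", k))
    scen <- build_scenario(sp$tree, list(list(
      trait_id = paste0("t", k), leaf_states = h$leaf_states,
      hgt_recode = h$hgt_recode
    )))
    leaves <- sp$tree$tip.label
    replayed <- vapply(leaves, function(l) {
      ancestor_report(scen, l)$present
    }, logical(1))
    expect_equal(unname(replayed), unname(h$leaf_states[leaves]))
  }
})

test_that("gene trees mirror the species tree and embed planted transfers", {
  cfg <- sim_config(seed = 12, n_species = 15, loss_rate = 1, hgt_rate = 0)
  sp <- simulate_species_tree(cfg)
  h <- simulate_trait_history(sp$tree, cfg, "AcsB")
  g <- emit_gene_tree(sp$tree, h, cfg, "AcsB")
  expect_equal(test_monophyly(g$tree, g$focal_leaves)$status, "monophyletic")
  expect_true(all(tree_supports(g$tree) == 100, na.rm = TRUE))

  # plant one transfer: monophyly breaks and the donor is recoverable
  node <- length(sp$tree$tip.label) + 3L
  h2 <- simulate_trait_history(sp$tree, cfg, "AcsB", forced_loss_edges = node)
  lost <- names(h2$leaf_states)[!h2$leaf_states]
  expect_gt(length(lost), 0)
  forced <- tibble::tibble(species = lost[1], donor = "PVC")
  h2 <- simulate_trait_history(sp$tree, cfg, "AcsB",
                               forced_loss_edges = node, forced_hgt = forced)
  g2 <- emit_gene_tree(sp$tree, h2, cfg, "AcsB")
  expect_equal(test_monophyly(g2$tree, g2$focal_leaves)$status, "non-monophyletic")
  gmap <- c(g2$group_map, setNames(unname(sp$clades[g2$focal_leaves]), g2$focal_leaves))
  v <- classify_hgt(g2$tree, g2$focal_leaves, gmap)
  called <- v[v$verdict == "hgt_candidate", ]
  expect_equal(called$sequence_id, lost[1])
  expect_equal(called$donor_group, "PVC")
})

test_that("long-branch decoys are emitted and pruned as designed", {
  cfg <- sim_config(seed = 13, n_species = 10, loss_rate = 0, n_decoys = 2)
  sp <- simulate_species_tree(cfg)
  h <- simulate_trait_history(sp$tree, cfg, "x")
  g <- emit_gene_tree(sp$tree, h, cfg, "x")
  expect_true(all(paste0("decoy_", 1:2) %in% g$tree$tip.label))
  res <- prune_long_branches(g$tree)
  expect_setequal(res$removed, paste0("decoy_", 1:2))
})

test_that("emitted hits straddle the screening thresholds correctly", {
  cfg <- sim_config(seed = 14, n_species = 25, dropout_rate = 0,
                    false_hit_rate = 1, mag_fraction = 0,
                    enzymes = c("AcsA", "GCST"))
  sp <- simulate_species_tree(cfg)
  truth <- purrr::map_dfr(cfg$enzymes, function(e) {
    h <- simulate_trait_history(sp$tree, cfg, e)
    tibble::tibble(species = sp$tree$tip.label, enzyme = e,
                   present = unname(h$leaf_states))
  })
  truth$present[1:10] <- FALSE   # guarantee absent cells for decoy emission
  out <- emit_hit_table(truth, cfg)
  hits <- out$hits
  kept <- filter_hits(hits)
  # every decoy is removed by the threshold filter, every true hit kept
  expect_true(all(out$truth_hits$is_true[match(kept$subject_id,
                                               out$truth_hits$subject_id)]))
  expect_equal(sort(kept$subject_id),
               sort(out$truth_hits$subject_id[out$truth_hits$is_true]))
  # with the rate forced to one, both decoy failure modes appear
  decoys <- hits[grepl("_decoy$", hits$subject_id), ]
  expect_gte(nrow(decoys), 10)
  expect_true(any(decoys$evalue >= 1e-5))
  expect_true(any(decoys$query_coverage < 70))
})

test_that("MAG species emit extra weaker hits for the curation stage", {
  cfg <- sim_config(seed = 15, n_species = 10, dropout_rate = 0,
                    false_hit_rate = 0, mag_fraction = 0.5, enzymes = "AcsA")
  sp <- simulate_species_tree(cfg)
  meta <- tibble::tibble(species = sp$tree$tip.label, clade = "A",
                         is_mag = seq_len(10) <= 5, is_autotroph = FALSE)
  truth <- tibble::tibble(species = sp$tree$tip.label, enzyme = "AcsA",
                          present = TRUE)
  hits <- emit_hit_table(truth, cfg, meta)$hits
  expect_true(any(hits$is_mag_derived))
  per_sp <- table(hits$subject_species)
  expect_true(all(per_sp[meta$species[meta$is_mag]] == 2))
  expect_true(all(per_sp[meta$species[!meta$is_mag]] == 1))
})

test_that("annotation layouts realize the cluster truth", {
  cfg <- sim_config(seed = 16, n_species = 12, loss_rate = 0.5)
  sp <- simulate_species_tree(cfg)
  truth <- purrr::map_dfr(c("AcsA", "AcsB", "AcsC", "AcsD", "AcsE"), function(e) {
    h <- simulate_trait_history(sp$tree, cfg, e)
    tibble::tibble(species = sp$tree$tip.label, enzyme = e,
                   present = unname(h$leaf_states))
  })
  ann <- emit_annotation(truth, cfg)
  expect_gt(nrow(ann$truth_clusters), 0)
  calls <- detect_acsA_clusters(ann$loci)
  merged <- dplyr::left_join(ann$truth_clusters, calls, by = "species")
  expect_equal(merged$is_clustered, merged$clustered)
  eligible <- merged$clustered & merged$n_partners_expected >= 3
  expect_equal(merged$concat_eligible, eligible)
})

test_that("dataset emission is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 17, n_species = 10, enzymes = c("AcsA", "FdhG", "GCST"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
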