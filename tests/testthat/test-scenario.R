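test_that("Fitch counts match simple hand-checked cases", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  all_on <- setNames(rep(TRUE, 4), c("a", "b", "c", "d"))
  f <- fitch_min_changes(tr, all_on)
  expect_equal(f$min_changes, 0)
  expect_true(all(f$node_states))

  split2 <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  expect_equal(fitch_min_changes(tr, split2)$min_changes, 1)

  alt <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  expect_equal(fitch_min_changes(tr, alt)$min_changes, 2)

  expect_error(fitch_min_changes(tr, split2[1:3]), "missing a state")
})

test_that("Fitch equals the exhaustive labeling oracle on random 5-6 leaf trees", {
  set.seed(23)
  for (k in 1:25) {
    n <- sample(5:6, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), tr$tip.label)
    expect_equal(fitch_min_changes(tr, states)$min_changes,
                 oracle_min_changes(tr, states))
  }
})

test_that("a returned Fitch labeling achieves the reported change count", {
  set.seed(24)
  for (k in 1:20) {
    tr <- ape::rtree(8)
    states <- setNames(sample(c(TRUE, FALSE), 8, replace = TRUE), tr$tip.label)
    f <- fitch_min_changes(tr, states)
    realized <- sum(f$node_states[f$tree$edge[, 1]] != f$node_states[f$tree$edge[, 2]])
    expect_equal(realized, f$min_changes)
    expect_equal(unname(f$node_states[seq_along(tr$tip.label)]),
                 unname(states[f$tree$tip.label]))
  }
})

test_that("Dollo places the single gain above the MRCA and minimal losses below", {
  tr <- backbone()
  # trait everywhere: gain on the root stem, no losses
  all_on <- setNames(rep(TRUE, 6), tr$tip.label)
  d <- dollo_reconstruct(tr, all_on)
  expect_equal(sort(strsplit(d$gain_signature, "\\|")[[1]]), sort(tr$tip.label))
  expect_equal(length(d$loss_edges), 0)
  expect_equal(d$n_events, 1)

  # the carbonyl-branch complex pattern: absent in clade A and the outgroup
  d2 <- dollo_reconstruct(tr, backbone_states(A = FALSE))
  expect_equal(d2$gain_signature, "A|B|C|D|E")
  expect_equal(d2$loss_signatures, "A")

  # all absent
  d3 <- dollo_reconstruct(tr, setNames(rep(FALSE, 6), tr$tip.label))
  expect_true(d3$never_present)
  expect_equal(d3$n_events, 0)
})

test_that("Dollo equals a brute-force single-gain search on random trees", {
  set.seed(25)
  for (k in 1:25) {
    tr <- ape::rtree(7)
    states <- setNames(sample(c(TRUE, FALSE), 7, replace = TRUE,
                              prob = c(0.6, 0.4)), tr$tip.label)
    if (!any(states)) states[1] <- TRUE
    d <- dollo_reconstruct(tr, states)
    # oracle: over every candidate gain node, count absent-maximal subtrees
    sets <- oracle_tipsets(tr)
    fidx <- which(states[tr$tip.label])
    best <- Inf
    for (g in seq_along(sets)) {
      if (!all(fidx %in% sets[[g]])) next   # gain must cover all present leaves
      n_loss <- 0L
      ok <- TRUE
      # count maximal all-absent subtrees inside g
      for (v in seq_along(sets)) {
        if (v == g || !all(sets[[v]] %in% sets[[g]])) next
        par <- tr$edge[tr$edge[, 2] == v, 1]
        par_tips <- if (length(par)) sets[[par]] else integer()
        v_absent <- !any(sets[[v]] %in% fidx)
        par_absent <- length(par_tips) && !any(par_tips %in% fidx) &&
          all(par_tips %in% sets[[g]])
        if (v_absent && !par_absent) n_loss <- n_loss + 1L
      }
      if (ok) best <- min(best, 1L + n_loss)
    }
    expect_equal(d$n_events, best)
  }
})

test_that("Dollo count equals Fitch count when a single-gain labeling is optimal", {
  set.seed(26)
  for (k in 1:40) {
    tr <- ape::rtree(8)
    states <- setNames(sample(c(TRUE, FALSE), 8, replace = TRUE), tr$tip.label)
    if (!any(states)) states[1] <- TRUE
    d <- dollo_reconstruct(tr, states)
    f <- fitch_min_changes(tr, states)
    expect_gte(d$n_events, f$min_changes)
    if (d$n_events > f$min_changes) {
      # Fitch must then genuinely need multiple gains; verify with a
      # single-gain-constrained brute force over internal labelings
      n_int <- tr$Nnode
      leaf <- as.integer(states[tr$tip.label])
      single_gain_best <- Inf
      for (code in 0:(2^n_int - 1)) {
        full <- c(leaf, as.integer(intToBits(code))[seq_len(n_int)])
        gains <- sum(full[tr$edge[, 1]] == 0 & full[tr$edge[, 2]] == 1) +
          full[length(tr$tip.label) + 1]
        if (gains != 1) next
        single_gain_best <- min(single_gain_best,
                                sum(full[tr$edge[, 1]] != full[tr$edge[, 2]]) +
                                  full[length(tr$tip.label) + 1])
      }
      expect_lt(f$min_changes, single_gain_best)
    }
  }
})

test_that("the worked clade-level scenario recovers the published-style events", {
  tr <- backbone()
  traits <- list(
    list(trait_id = "CODH/ACS",
         leaf_states = backbone_states(A = FALSE)),
    list(trait_id = "GCS",
         leaf_states = backbone_states(),
         hgt_recode = tibble::tibble(species = "A", donor = "PVC"))
  )
  # GCS: B lost it; A carries only the transferred copy
  traits[[2]]$leaf_states["B"] <- FALSE
  scen <- build_scenario(tr, traits)

  codh <- scen$events[scen$events$trait_id == "CODH/ACS", ]
  expect_equal(codh$edge_signature[codh$event == "loss"], "A")
  expect_equal(codh$edge_signature[codh$event == "gain"], "A|B|C|D|E")

  gcs <- scen$events[scen$events$trait_id == "GCS", ]
  expect_equal(gcs$edge_signature[gcs$event == "loss"], "A|B")
  hgt <- gcs[gcs$event == "hgt_gain", ]
  expect_equal(hgt$edge_signature, "A")
  expect_equal(hgt$donor, "PVC")
})

test_that("scenario replay reproduces every observed leaf state", {
  set.seed(27)
  for (k in 1:12) {
    cfg <- sim_config(seed = 100 + k, n_species = 12, loss_rate = 2, hgt_rate = 0.8)
    sp <- simulate_species_tree(cfg)
    h <- simulate_trait_history(sp$tree, cfg, "t")
    scen <- build_scenario(sp$tree, list(list(
      trait_id = "t", leaf_states = h$leaf_states, hgt_recode = h$hgt_recode
    )))
    for (leaf in sp$tree$tip.label) {
      rep <- ancestor_report(scen, leaf)
      expect_equal(rep$present, unname(h$leaf_states[leaf]), label = leaf)
    }
  }
})

test_that("empty recode reduces build_scenario to plain Dollo", {
  tr <- backbone()
  st <- backbone_states(C = FALSE)
  scen <- build_scenario(tr, list(list(trait_id = "x", leaf_states = st)))
  d <- dollo_reconstruct(tr, st)
  ev <- scen$events
  expect_equal(sort(ev$edge_signature[ev$event == "loss"]), sort(d$loss_signatures))
  expect_equal(ev$edge_signature[ev$event == "gain"], d$gain_signature)
  expect_equal(sum(ev$event == "hgt_gain"), 0)
})

test_that("non-monophyletic transfer sets trigger per-subclade events with a warning", {
  tr <- backbone()
  st <- backbone_states(A = TRUE, C = TRUE)
  st[c("B", "D", "E")] <- FALSE
  expect_warning(
    scen <- build_scenario(tr, list(list(
      trait_id = "x", leaf_states = st,
      hgt_recode = tibble::tibble(species = c("A", "C"), donor = "PVC")
    ))),
    "not monophyletic"
  )
  hgt <- scen$events[scen$events$event == "hgt_gain", ]
  expect_setequal(hgt$edge_signature, c("A", "C"))
})

test_that("ancestral states replay correctly at internal nodes", {
  tr <- backbone()
  traits <- list(
    list(trait_id = "FdhG", leaf_states = backbone_states()),
    list(trait_id = "CODH/ACS", leaf_states = backbone_states(A = FALSE)),
    list(trait_id = "GCS", leaf_states = {
      s <- backbone_states(B = FALSE)
      s
    }, hgt_recode = tibble::tibble(species = "A", donor = "PVC"))
  )
  scen <- build_scenario(tr, traits)
  mrca <- ancestor_report(scen, c("A", "B", "C", "D", "E"))
  expect_true(all(mrca$present))
  expect_false(any(mrca$via_hgt))

  # at the tree root the focal gain (below the root) has not replayed
  root <- ancestor_report(scen, length(tr$tip.label) + 1L)
  expect_false(any(root$present))

  expect_error(ancestor_report(scen, "nonexistent_leaf"), "unknown node")
})

test_that("scenario tidiers expose events and totals", {
  tr <- backbone()
  scen <- build_scenario(tr, list(
    list(trait_id = "x", leaf_states = backbone_states(A = FALSE))
  ))
  expect_equal(nrow(tidy(scen)), 2)  # one gain + one loss
  g <- glance(scen)
  expect_equal(g$n_gain, 1)
  expect_equal(g$n_loss, 1)
  expect_equal(scen$counts$fitch_changes, 2)
})

test_that("scenario artifacts are written and the annotated tree parses", {
  tr <- backbone()
  scen <- build_scenario(tr, list(
    list(trait_id = "x", leaf_states = backbone_states(A = FALSE))
  ))
  dir <- withr::local_tempdir()
  write_scenario(scen, dir)
  expect_true(file.exists(file.path(dir, "scenario_events.tsv")))
  ann <- read_newick(file.path(dir, "species_tree_annotated.nwk"))
  expect_equal(sort(ann$tip.label), sort(tr$tip.label))
  states <- readr::read_tsv(file.path(dir, "ancestor_states.tsv"),
                            show_col_types = FALSE)
  leafA <- states[states$node_label == "A", ]
  expect_false(leafA$present)
})
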