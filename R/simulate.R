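#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the simulator with validated defaults. The
#' defaults describe the study conditions the pipeline is meant for: a
#' phylum-scale screen (55 representative species in five clades), traits
#' inherited vertically from a present root with on average 1.5 losses per
#' tree, rare horizontal regains from external donor groups, hit e-values
#' sampled log-uniformly so the screening cutoffs are exercised densely on
#' both sides, and a fifth of genomes flagged as metagenome-assembled.
#'
#' @param seed Integer seed; mandatory, drives every random choice.
#' @param n_species Number of focal species (leaves of the species tree).
#' @param n_clades Number of in-phylum clades to label (A, B, ...).
#' @param birth_rate Rate of the exponential branch-length distribution.
#' @param loss_rate Expected number of loss events per trait per tree.
#' @param hgt_rate Expected number of horizontal regains per trait.
#' @param false_hit_rate Probability that an absent cell emits a decoy hit.
#' @param dropout_rate Probability that a present cell emits no hit.
#' @param mag_fraction Fraction of species flagged as MAGs.
#' @param true_log10_evalue,false_log10_evalue Log10 e-value ranges for
#'   true homolog hits and decoy hits.
#' @param true_coverage,false_coverage Query-coverage ranges (percent) for
#'   true hits and coverage-failing decoys.
#' @param clustered_fraction Probability that a CODH/ACS-positive species
#'   lays its acs genes out as one synteny cluster (vs dispersed).
#' @param outgroup_size Leaves per external donor-group clade in emitted
#'   gene trees.
#' @param n_decoys Long-branch decoy leaves added per gene tree.
#' @param support_noise Probability of degrading a true-clade support
#'   below 95 in emitted gene trees.
#' @param enzymes Enzyme ids to simulate traits for.
#' @return A validated list of class `"pt_sim_config"`.
#' @export
sim_config <- function(seed,
                       n_species = 55L,
                       n_clades = 5L,
                       birth_rate = 1,
                       loss_rate = 1.5,
                       hgt_rate = 0.1,
                       false_hit_rate = 0.05,
                       dropout_rate = 0.02,
                       mag_fraction = 0.2,
                       true_log10_evalue = c(-50, -6),
                       false_log10_evalue = c(-5, 0),
                       true_coverage = c(70, 100),
                       false_coverage = c(30, 69.9),
                       clustered_fraction = 0.7,
                       outgroup_size = 3L,
                       n_decoys = 0L,
                       support_noise = 0,
                       enzymes = default_enzyme_defs()$enzyme_id) {
  if (missing(seed)) abort("sim_config requires an explicit seed")
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              n_clades = as.integer(n_clades), birth_rate = birth_rate,
              loss_rate = loss_rate, hgt_rate = hgt_rate,
              false_hit_rate = false_hit_rate, dropout_rate = dropout_rate,
              mag_fraction = mag_fraction,
              true_log10_evalue = true_log10_evalue,
              false_log10_evalue = false_log10_evalue,
              true_coverage = true_coverage, false_coverage = false_coverage,
              clustered_fraction = clustered_fraction,
              outgroup_size = as.integer(outgroup_size),
              n_decoys = as.integer(n_decoys), support_noise = support_noise,
              enzymes = enzymes)
  fracs <- c("hgt_rate", "false_hit_rate", "dropout_rate", "mag_fraction",
             "clustered_fraction", "support_noise")
  for (f in fracs) {
    if (cfg[[f]] < 0 || (f != "hgt_rate" && cfg[[f]] > 1)) {
      abort(paste0("sim_config: ", f, " out of range"))
    }
  }
  if (cfg$n_species < 3) abort("sim_config: n_species must be >= 3")
  if (cfg$loss_rate < 0) abort("sim_config: loss_rate must be >= 0")
  structure(cfg, class = "pt_sim_config")
}

# deterministic per-purpose sub-seed, kept below 2^31
sub_seed <- function(cfg, purpose) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  (as.numeric(cfg$seed) * 1009 + h) %% 2147483647
}

donor_groups <- function() c("PVC", "Myxococcota", "Nitrospirota")

#' Simulate a species tree with clade labels
#'
#' Draws a random rooted binary tree with exponentially distributed branch
#' lengths and cuts it into `n_clades` monophyletic groups by repeatedly
#' splitting the largest clade, labelling them A, B, ... in node order.
#' Fully deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `tree` (`phylo`, leaves `sp001`...) and `clades`
#'   (named character vector leaf -> clade label).
#' @export
simulate_species_tree <- function(cfg) {
  set.seed(sub_seed(cfg, "species_tree"))
  n <- cfg$n_species
  tree <- ape::rtree(n, br = function(k) stats::rexp(k, rate = cfg$birth_rate))
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  tree$node.label <- NULL
  sets <- node_tip_sets(tree)
  groups <- root_node(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(groups) < cfg$n_clades) {
    sizes <- vapply(groups, function(v) length(sets[[v]]), 1L)
    splittable <- groups[sizes > 1]
    if (!length(splittable)) break
    big <- splittable[which.max(sizes[match(splittable, groups)])]
    groups <- c(setdiff(groups, big), kids[[as.character(big)]])
  }
  groups <- sort(groups)
  clades <- character(n)
  for (i in seq_along(groups)) {
    clades[sets[[groups[i]]]] <- LETTERS[i]
  }
  list(tree = tree, clades = setNames(clades, tree$tip.label))
}

# maximal all-absent subtrees of `tree` given logical tip states
maximal_absent_clades <- function(tree, states) {
  absent <- all_absent_below(tree, states)
  pars <- parent_vec(tree)
  which(absent & vapply(seq_along(absent), function(v) {
    p <- pars[v]
    is.na(p) || !absent[p]
  }, logical(1)))
}

#' Simulate one trait's gain/loss/transfer history
#'
#' The trait starts present at the root; loss events are placed on edges
#' by a Poisson draw with expectation `loss_rate`, weighted by branch
#' length (Dollo-style: no spontaneous regain). Optionally, a lost lineage
#' regains the trait from a random external donor group (expected
#' `hgt_rate` regains). Forced mode plants exact events for targeted
#' tests. Every effective event is logged; the loss log is the canonical,
#' identifiable representation (stems of the maximal absent subtrees).
#'
#' @param tree Species tree (`phylo`).
#' @param cfg A [sim_config()].
#' @param trait_id Character id (also salts the RNG stream).
#' @param forced_loss_edges Optional integer child-node ids: plant exactly
#'   these losses and skip the random draw.
#' @param forced_hgt Optional tibble with columns `species`, `donor`:
#'   plant exactly these regains.
#' @return List with `leaf_states` (named logical, transfers included),
#'   `vertical_states` (transfers excluded), `hgt_recode` (tibble
#'   `species`, `donor`), and `events` (tibble `trait_id`, `edge_child`,
#'   `edge_signature`, `event`, `donor`).
#' @export
simulate_trait_history <- function(tree, cfg, trait_id,
                                   forced_loss_edges = NULL,
                                   forced_hgt = NULL) {
  set.seed(sub_seed(cfg, paste0("trait_", trait_id)))
  n_tip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)

  if (is.null(forced_loss_edges)) {
    n_loss <- rpois(1, cfg$loss_rate)
    n_loss <- min(n_loss, nrow(tree$edge))
    loss_children <- if (n_loss > 0) {
      tree$edge[sample.int(nrow(tree$edge), n_loss, prob = tree$edge.length), 2]
    } else integer()
  } else {
    loss_children <- as.integer(forced_loss_edges)
    n_loss <- length(loss_children)
  }
  absent_tips <- unique(unlist(lapply(loss_children, function(v) sets[[v]])))
  vertical <- rep(TRUE, n_tip)
  vertical[absent_tips] <- FALSE
  if (!any(vertical)) {
    # a draw that wipes the whole tree is redrawn as a single-subtree loss
    # below the root so the trait remains observable
    rt <- root_node(tree)
    keep <- split(tree$edge[, 2], tree$edge[, 1])[[as.character(rt)]][1]
    vertical <- rep(FALSE, n_tip)
    vertical[sets[[keep]]] <- TRUE
  }

  # canonical, identifiable truth representation: the gain is logged on the
  # stem of the smallest clade containing every surviving vertical carrier,
  # and losses on the stems of the maximal absent subtrees inside it --
  # losses that erased a whole flank above that clade leave no trace and
  # are not logged
  present_idx <- which(vertical)
  cand <- which(vapply(seq_along(sets), function(v) {
    all(present_idx %in% sets[[v]])
  }, logical(1)))
  gain_node <- cand[which.min(lengths(sets[cand]))]
  loss_nodes <- maximal_absent_clades(tree, vertical)
  loss_nodes <- loss_nodes[vapply(loss_nodes, function(v) {
    all(sets[[v]] %in% sets[[gain_node]])
  }, logical(1))]

  if (is.null(forced_hgt)) {
    n_hgt <- rpois(1, cfg$hgt_rate)
    hgt <- tibble(species = character(), donor = character())
    for (k in seq_len(n_hgt)) {
      lost_now <- maximal_absent_clades(
        tree, vertical | tree$tip.label %in% hgt$species)
      if (!length(lost_now)) break
      v <- lost_now[sample.int(length(lost_now), 1)]
      hgt <- bind_rows(hgt, tibble(
        species = tree$tip.label[sets[[v]]],
        donor = sample(donor_groups(), 1)
      ))
    }
  } else {
    hgt <- as_tibble(forced_hgt)
    bad <- intersect(hgt$species, tree$tip.label[vertical])
    if (length(bad)) abort(paste0("forced_hgt species still vertically present: ",
                                  paste(bad, collapse = ", ")))
  }

  leaf_states <- vertical | tree$tip.label %in% hgt$species
  hgt_events <- if (nrow(hgt)) {
    purrr::map_dfr(unique(hgt$donor), function(dn) {
      idx <- match(hgt$species[hgt$donor == dn], tree$tip.label)
      nodes <- seq_len(n_tip + tree$Nnode)
      in_grp <- vapply(nodes, function(v) all(sets[[v]] %in% idx), logical(1))
      pars <- parent_vec(tree)
      maximal <- which(in_grp & vapply(nodes, function(v) {
        is.na(pars[v]) || !in_grp[pars[v]]
      }, logical(1)))
      tibble(trait_id = trait_id, edge_child = maximal,
             edge_signature = vapply(maximal, function(v) edge_signature(tree, v, sets), ""),
             event = "hgt_gain", donor = dn)
    })
  } else NULL

  events <- bind_rows(
    tibble(trait_id = trait_id, edge_child = gain_node,
           edge_signature = edge_signature(tree, gain_node, sets),
           event = "gain", donor = NA_character_),
    if (length(loss_nodes)) tibble(
      trait_id = trait_id, edge_child = loss_nodes,
      edge_signature = vapply(loss_nodes, function(v) edge_signature(tree, v, sets), ""),
      event = "loss", donor = NA_character_
    ),
    hgt_events
  )
  list(
    leaf_states = setNames(leaf_states, tree$tip.label),
    vertical_states = setNames(vertical, tree$tip.label),
    hgt_recode = hgt,
    events = events,
    n_loss_drawn = n_loss
  )
}

clade_newick <- function(labels, pendant = 0.1) {
  paste0("(", paste0(labels, ":", pendant, collapse = ","), ")")
}

#' Emit a gene tree consistent with a trait history
#'
#' The vertical copies mirror the species tree restricted to the leaves
#' that still carry the trait; an outgroup scaffold of external-group
#' clades (the potential donors) is attached; and each horizontally
#' acquired copy is grafted as sister to a leaf of its donor clade. True
#' clades receive bootstrap support 100, optionally degraded at rate
#' `support_noise`; long-branch decoy leaves (pendant length 2) can be
#' added to exercise pruning.
#'
#' @param tree Species tree.
#' @param history Result of [simulate_trait_history()].
#' @param cfg A [sim_config()].
#' @param trait_id Character id (salts the RNG stream).
#' @return List with `tree` (the gene tree), `focal_leaves`, `group_map`
#'   (named vector leaf -> group), and `truth` (tibble `sequence_id`,
#'   `verdict`, `donor`).
#' @export
emit_gene_tree <- function(tree, history, cfg, trait_id = "trait") {
  set.seed(sub_seed(cfg, paste0("genetree_", trait_id)))
  vertical <- names(history$vertical_states)[history$vertical_states]
  transferred <- history$hgt_recode
  if (!length(vertical) && !nrow(transferred)) {
    abort("trait has no present leaves; cannot emit a gene tree")
  }

  out_labels <- lapply(donor_groups(), function(g) {
    paste0(g, "_", seq_len(cfg$outgroup_size))
  })
  names(out_labels) <- donor_groups()
  focal_part <- if (length(vertical) >= 2) {
    sub <- ape::keep.tip(tree, vertical)
    sub$node.label <- NULL
    paste0(sub(";$", "", ape::write.tree(sub)), ":0.2")
  } else if (length(vertical) == 1) {
    paste0(vertical, ":0.3")
  } else NULL
  parts <- c(
    list(focal_part),
    lapply(donor_groups(), function(g) paste0(clade_newick(out_labels[[g]]), ":0.2"))
  )
  parts <- parts[!vapply(parts, is.null, logical(1))]
  gt <- ape::read.tree(text = paste0("(", paste(unlist(parts), collapse = ","), ");"))

  if (nrow(transferred)) {
    donors_cycle <- stats::ave(seq_len(nrow(transferred)), transferred$donor,
                               FUN = seq_along)
    for (i in seq_len(nrow(transferred))) {
      host <- out_labels[[transferred$donor[i]]][
        ((donors_cycle[i] - 1) %% cfg$outgroup_size) + 1]
      graft <- ape::read.tree(text = paste0("(", transferred$species[i], ":0.05);"))
      graft$root.edge <- 0.05
      gt <- ape::bind.tree(gt, graft, where = which(gt$tip.label == host),
                           position = 0.05)
    }
    gt <- ape::collapse.singles(gt)
  }
  # keep ordinary branches safely below the long-branch cutoff so that only
  # deliberate decoys exceed it
  if (max(gt$edge.length) > 0.8) {
    gt$edge.length <- gt$edge.length * (0.8 / max(gt$edge.length))
  }
  if (cfg$n_decoys > 0) {
    for (k in seq_len(cfg$n_decoys)) {
      host <- sample(gt$tip.label, 1)
      host_idx <- which(gt$tip.label == host)
      pend <- gt$edge.length[gt$edge[, 2] == host_idx]
      graft <- ape::read.tree(text = paste0("(decoy_", k, ":2.0);"))
      graft$root.edge <- pend / 2
      gt <- ape::bind.tree(gt, graft, where = host_idx, position = pend / 2)
    }
    gt <- ape::collapse.singles(gt)
  }
  gt$edge.length <- gt$edge.length * runif(length(gt$edge.length), 0.9, 1.1)
  sup <- rep(100L, gt$Nnode)
  if (cfg$support_noise > 0) {
    hit <- runif(gt$Nnode) < cfg$support_noise
    sup[hit] <- sample(50:94, sum(hit), replace = TRUE)
  }
  gt$node.label <- as.character(sup)

  focal <- c(vertical, transferred$species)
  clades <- attr(history, "clades") %||% NULL
  group_map <- c(
    setNames(rep(names(out_labels), each = cfg$outgroup_size), unlist(out_labels)),
    if (cfg$n_decoys > 0) setNames(rep("other", cfg$n_decoys),
                                   paste0("decoy_", seq_len(cfg$n_decoys)))
  )
  truth <- bind_rows(
    if (length(vertical)) tibble(sequence_id = vertical, verdict = "vertical",
                                 donor = NA_character_),
    if (nrow(transferred)) tibble(sequence_id = transferred$species,
                                  verdict = "hgt_candidate",
                                  donor = transferred$donor)
  )
  list(tree = gt, focal_leaves = focal, group_map = group_map, truth = truth)
}

#' Emit a hit table realizing a truth presence matrix
#'
#' Every present cell emits one passing hit (e-value below 1e-5, coverage
#' at least 70), minus dropouts; absent cells emit decoy hits at
#' `false_hit_rate` that fail either the e-value bound or the coverage
#' bound, so correct filtering recovers the truth. MAG-flagged species
#' additionally emit weaker (but still passing) secondary hits so the
#' MAG e-value curation has something to remove.
#'
#' @param truth Long tibble `species`, `enzyme`, `present`.
#' @param cfg A [sim_config()].
#' @param meta Taxon metadata tibble (for the MAG flags); may be `NULL`.
#' @return List with `hits` (tibble in [read_hit_table()] shape) and
#'   `truth_hits` (tibble `subject_id`, `query_id`, `is_true`).
#' @export
emit_hit_table <- function(truth, cfg, meta = NULL) {
  set.seed(sub_seed(cfg, "hits"))
  truth <- arrange(truth, .data$enzyme, .data$species)
  species <- sort(unique(truth$species))
  taxids <- setNames(sprintf("tx%03d", seq_along(species)), species)
  mag_species <- if (!is.null(meta)) meta$species[meta$is_mag] else character()

  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    sp <- truth$species[i]; enz <- truth$enzyme[i]
    if (truth$present[i]) {
      if (runif(1) < cfg$dropout_rate) next
      e <- 10^runif(1, cfg$true_log10_evalue[1], cfg$true_log10_evalue[2])
      cov <- runif(1, cfg$true_coverage[1], cfg$true_coverage[2])
      r <- tibble(
        query_id = enz, subject_id = paste0(sp, "|", enz, "_1"),
        subject_species = sp, percent_identity = runif(1, 30, 90),
        align_length = as.integer(round(runif(1, 150, 900))),
        evalue = e, bitscore = round(runif(1, 80, 800), 1),
        query_coverage = round(cov, 1), is_mag_derived = sp %in% mag_species,
        taxid = unname(taxids[sp])
      )
      if (sp %in% mag_species) {
        e2 <- 10^runif(1, -8, cfg$true_log10_evalue[2])
        r <- bind_rows(r, mutate(r,
          subject_id = paste0(sp, "|", enz, "_2"), evalue = e2,
          bitscore = round(runif(1, 60, 200), 1)))
      }
      rows[[i]] <- r
    } else if (runif(1) < cfg$false_hit_rate) {
      fail_evalue <- runif(1) < 0.5
      e <- if (fail_evalue) {
        10^runif(1, cfg$false_log10_evalue[1], cfg$false_log10_evalue[2])
      } else 10^runif(1, cfg$true_log10_evalue[1], cfg$true_log10_evalue[2])
      cov <- if (fail_evalue) runif(1, 0, 100)
             else runif(1, cfg$false_coverage[1], cfg$false_coverage[2])
      rows[[i]] <- tibble(
        query_id = enz, subject_id = paste0(sp, "|", enz, "_decoy"),
        subject_species = sp, percent_identity = runif(1, 15, 40),
        align_length = as.integer(round(runif(1, 40, 300))),
        evalue = e, bitscore = round(runif(1, 20, 60), 1),
        query_coverage = round(min(cov, if (fail_evalue) 100 else 69.9), 1),
        is_mag_derived = sp %in% mag_species, taxid = unname(taxids[sp])
      )
    }
  }
  hits <- bind_rows(rows)
  if (!nrow(hits)) hits <- empty_hit_tbl()
  truth_hits <- tibble(
    subject_id = hits$subject_id, query_id = hits$query_id,
    is_true = !grepl("_decoy$", hits$subject_id)
  )
  list(hits = hits, truth_hits = truth_hits)
}

#' Emit a genome annotation table realizing CODH/ACS synteny choices
#'
#' Species carrying AcsA place their acs genes either as one contiguous
#' cluster (`clustered`) or with AcsA isolated from its partner subunits
#' (`dispersed`), the choice drawn per species with probability
#' `clustered_fraction` (or forced via `force_clustered`). Filler genes
#' (`hyp`) pad the contigs.
#'
#' @inheritParams emit_hit_table
#' @param force_clustered Optional named logical vector (species ->
#'   clustered) overriding the random choice.
#' @return List with `loci` (annotation tibble) and `truth_clusters`
#'   (tibble `species`, `clustered`, `n_partners_expected`).
#' @export
emit_annotation <- function(truth, cfg, force_clustered = NULL) {
  set.seed(sub_seed(cfg, "annotation"))
  acs <- acs_subunit_labels()
  enz_of <- setNames(c("AcsA", "AcsB", "AcsC", "AcsD", "AcsE"), acs)
  wide <- truth |>
    filter(.data$enzyme %in% enz_of) |>
    tidyr::pivot_wider(names_from = "enzyme", values_from = "present")
  loci <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(wide))) {
    sp <- wide$species[i]
    have <- acs[vapply(acs, function(a) isTRUE(wide[[enz_of[[a]]]][i]), logical(1))]
    if (!"acsA" %in% have) next
    partners <- setdiff(have, "acsA")
    clustered <- if (!is.null(force_clustered) && sp %in% names(force_clustered)) {
      force_clustered[[sp]]
    } else runif(1) < cfg$clustered_fraction
    if (!length(partners)) clustered <- FALSE
    gene <- function(contig, idx, prod) {
      start <- 1000L * idx
      tibble(species = sp, contig = contig, start = start,
             end = start + 899L, strand = sample(c("+", "-"), 1),
             locus_tag = sprintf("%s_L%03d", sp, idx + 1000L * match(contig, c("c1", "c2"))),
             product = prod)
    }
    idx <- 0L
    add <- function(contig, prod) {
      idx <<- idx + 1L
      loci[[length(loci) + 1L]] <<- gene(contig, idx, prod)
    }
    add("c1", "hyp"); add("c1", "hyp")
    if (clustered) {
      for (a in have) add("c1", a)
      add("c1", "hyp")
    } else {
      add("c1", "acsA")
      for (k in 1:6) add("c1", "hyp")   # gap wider than any sane cluster_max_gap
      idx <- 0L
      for (a in partners) add("c2", a)
    }
    truth_rows[[length(truth_rows) + 1L]] <- tibble(
      species = sp, clustered = clustered,
      n_partners_expected = if (clustered) length(partners) else 0L
    )
  }
  loci <- bind_rows(loci)
  if (nrow(loci)) {
    loci <- loci |>
      group_by(.data$species, .data$contig) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(locus_index = row_number()) |>
      ungroup()
  }
  list(loci = loci, truth_clusters = bind_rows(truth_rows))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs every emitter and writes the full input bundle the pipeline
#' consumes -- species tree, per-enzyme gene trees with group maps, hit
#' table, annotation table, taxon metadata, enzyme definitions -- together
#' with ground-truth logs (presence matrix, planted events, transfer
#' calls, cluster choices, per-hit truth flags).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, a list with all in-memory truth objects and the
#'   directory layout.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- simulate_species_tree(cfg)
  tree <- sp$tree
  clades <- sp$clades

  set.seed(sub_seed(cfg, "meta"))
  n_mag <- round(cfg$mag_fraction * cfg$n_species)
  mag <- sample(tree$tip.label, n_mag)
  histories <- lapply(cfg$enzymes, function(enz) {
    simulate_trait_history(tree, cfg, enz)
  })
  names(histories) <- cfg$enzymes
  truth_pm <- purrr::map_dfr(cfg$enzymes, function(enz) {
    tibble(species = tree$tip.label, enzyme = enz,
           present = unname(histories[[enz]]$leaf_states[tree$tip.label]))
  })

  set.seed(sub_seed(cfg, "autotroph"))
  meta <- tibble(
    species = tree$tip.label,
    clade = unname(clades[tree$tip.label]),
    is_mag = tree$tip.label %in% mag,
    is_autotroph = runif(cfg$n_species) < 0.3
  )

  ht <- emit_hit_table(truth_pm, cfg, meta)
  ann <- emit_annotation(truth_pm, cfg)

  gdir <- file.path(dir, "gene_trees")
  dir.create(gdir, showWarnings = FALSE)
  gene_truths <- list()
  for (enz in cfg$enzymes) {
    h <- histories[[enz]]
    if (!any(h$leaf_states)) next
    g <- emit_gene_tree(tree, h, cfg, enz)
    write_newick(g$tree, file.path(gdir, paste0(enz, ".nwk")))
    gm <- c(g$group_map, setNames(unname(clades[g$focal_leaves]), g$focal_leaves))
    readr::write_tsv(tibble(leaf = names(gm), group = unname(gm)),
                     file.path(gdir, paste0(enz, "_groups.tsv")), progress = FALSE)
    gene_truths[[enz]] <- mutate(g$truth, enzyme = enz)
  }

  write_newick(tree, file.path(dir, "species_tree.nwk"))
  write_taxon_meta(meta, file.path(dir, "taxa.tsv"))
  defs <- default_enzyme_defs()
  write_enzyme_defs(defs[defs$enzyme_id %in% cfg$enzymes |
                           defs$complex %in% c("FDH", "CODH/ACS", "GCS"), ],
                    file.path(dir, "enzymes.tsv"))
  write_hit_table(ht$hits, file.path(dir, "hits.tsv"))
  if (nrow(ann$loci)) write_annotation_table(ann$loci, file.path(dir, "annotation.tsv"))

  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  readr::write_tsv(truth_pm, file.path(tdir, "presence.tsv"), progress = FALSE)
  events <- purrr::map_dfr(histories, "events")
  readr::write_tsv(events, file.path(tdir, "events.tsv"), progress = FALSE)
  hgt <- purrr::map_dfr(cfg$enzymes, function(enz) {
    h <- histories[[enz]]$hgt_recode
    if (nrow(h)) mutate(h, enzyme = enz) else NULL
  })
  readr::write_tsv(hgt, file.path(tdir, "hgt.tsv"), progress = FALSE)
  readr::write_tsv(ann$truth_clusters, file.path(tdir, "clusters.tsv"), progress = FALSE)
  readr::write_tsv(ht$truth_hits, file.path(tdir, "hits.tsv"), progress = FALSE)
  readr::write_tsv(purrr::map_dfr(gene_truths, identity),
                   file.path(tdir, "gene_tree_verdicts.tsv"), progress = FALSE)

  invisible(list(
    dir = dir, tree = tree, clades = clades, meta = meta,
    histories = histories, truth_presence = truth_pm,
    truth_events = events, truth_hgt = hgt,
    truth_clusters = ann$truth_clusters, truth_hits = ht$truth_hits,
    gene_truths = gene_truths
  ))
}
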