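#' Pipeline run configuration
#'
#' @param input_dir Directory holding the input bundle (layout as written
#'   by [simulate_dataset()]): `species_tree.nwk`, `taxa.tsv`,
#'   `enzymes.tsv`, `hits.tsv`, optional `annotation.tsv` and
#'   `gene_trees/<enzyme>.nwk` + `<enzyme>_groups.tsv`.
#' @param out_dir Directory to write artifacts into (created).
#' @param thresholds A [thresholds()] object (echoed into the manifest).
#' @param stages Stages to run, in pipeline order; prerequisites of a
#'   requested stage run automatically. `"all"` (default) runs
#'   screen, pathways, synteny, trees, scenario, report.
#' @param verbose Emit stage-prefixed progress messages.
#' @return A validated list of class `"pt_run_config"`.
#' @export
run_config <- function(input_dir, out_dir,
                       thresholds = pathtracer::thresholds(),
                       stages = "all", verbose = TRUE) {
  all_stages <- c("screen", "pathways", "synteny", "trees", "scenario", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 thresholds = as_thresholds(thresholds),
                 stages = stages, verbose = verbose),
            class = "pt_run_config")
}

stage_msg <- function(cfg, stage, msg) {
  if (isTRUE(cfg$verbose)) message("[", stage, "] ", msg)
}

stage_abort <- function(stage, msg) {
  abort(paste0("[", stage, "] ", msg))
}

#' Run the full inference pipeline
#'
#' Executes the stages in order -- homolog screening, pathway calls,
#' synteny cluster detection, gene-tree screening (long-branch pruning,
#' monophyly, group splitting, HGT classification) and ancestral scenario
#' reconstruction -- and writes every artifact plus a manifest recording
#' input checksums and the effective thresholds. The pipeline itself uses
#' no randomness: reruns on identical inputs produce byte-identical
#' artifacts.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  t <- cfg$thresholds
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$input_dir, ...)
  o <- function(...) file.path(cfg$out_dir, ...)
  want <- function(stage) stage %in% cfg$stages
  res <- list()

  for (f in c("taxa.tsv", "enzymes.tsv", "hits.tsv")) {
    if (!file.exists(p(f))) stage_abort("screen", paste0("missing input ", f))
  }
  meta <- read_taxon_meta(p("taxa.tsv"))
  defs <- read_enzyme_defs(p("enzymes.tsv"))

  # screen
  stage_msg(cfg, "screen", "reading and filtering hit table")
  hits <- read_hit_table(p("hits.tsv"), mag_species = meta$species[meta$is_mag])
  filtered <- filter_hits(hits, t)
  pm <- build_presence_matrix(filtered, meta$species, defs$enzyme_id)
  write_presence_matrix(pm, o("presence.tsv"))
  res$presence <- pm
  stage_msg(cfg, "screen", paste0(sum(pm$present), " present cells from ",
                                  nrow(filtered), "/", nrow(hits), " surviving hits"))

  # pathways
  if (want("pathways") || want("scenario") || want("report")) {
    stage_msg(cfg, "pathways", "calling pathway completeness")
    calls <- tryCatch(call_pathways(pm, defs),
                      error = function(e) stage_abort("pathways", conditionMessage(e)))
    readr::write_tsv(calls, o("pathway_calls.tsv"), progress = FALSE)
    readr::write_tsv(autotrophy_consistency(calls, meta),
                     o("autotrophy_consistency.tsv"), progress = FALSE)
    res$pathway_calls <- calls
  }

  # synteny
  if (want("synteny") && file.exists(p("annotation.tsv"))) {
    stage_msg(cfg, "synteny", "detecting CODH/ACS clusters")
    loci <- read_annotation_table(p("annotation.tsv"))
    ccalls <- detect_acsA_clusters(loci, t)
    cls <- classify_acsA_copies(ccalls)
    out <- ccalls |>
      mutate(partner_subunits_found = vapply(.data$partner_subunits_found,
                                             paste, "", collapse = ",")) |>
      left_join(cls$copies[c("species", "anchor_locus", "functional_class")],
                by = c("species", "anchor_locus"))
    readr::write_tsv(out, o("cluster_calls.tsv"), progress = FALSE)
    res$cluster_calls <- ccalls
    res$acsA_classes <- cls
  }

  # trees
  if (want("trees") || want("scenario")) {
    gdir <- p("gene_trees")
    verdicts <- list()
    monos <- list()
    if (dir.exists(gdir)) {
      for (nwk in sort(list.files(gdir, pattern = "\\.nwk$", full.names = TRUE))) {
        enz <- sub("\\.nwk$", "", basename(nwk))
        gmap_path <- file.path(gdir, paste0(enz, "_groups.tsv"))
        if (!file.exists(gmap_path)) {
          stage_abort("trees", paste0("gene tree ", enz, " has no group map"))
        }
        stage_msg(cfg, "trees", paste0("screening gene tree ", enz))
        gt <- read_newick(nwk)
        gm_df <- readr::read_tsv(gmap_path, show_col_types = FALSE, progress = FALSE)
        gmap <- setNames(gm_df$group, gm_df$leaf)
        pruned <- prune_long_branches(gt, t)
        gt <- pruned$tree
        gmap <- gmap[gt$tip.label]
        focal <- gt$tip.label[gmap %in% LETTERS[1:5]]
        if (!length(focal)) next
        v <- classify_hgt(gt, focal, gmap, t)
        v$enzyme <- enz
        v$pruned_long_branches <- length(pruned$removed)
        verdicts[[enz]] <- v
        monos[[enz]] <- mutate(tidy(test_monophyly(gt, focal)), enzyme = enz)
      }
    }
    res$tree_verdicts <- bind_rows(verdicts)
    res$monophyly <- bind_rows(monos)
    if (nrow(res$tree_verdicts)) {
      readr::write_tsv(res$tree_verdicts, o("tree_verdicts.tsv"), progress = FALSE)
      readr::write_tsv(res$monophyly, o("monophyly.tsv"), progress = FALSE)
    }
  }

  # scenario
  if (want("scenario")) {
    if (!file.exists(p("species_tree.nwk"))) {
      stage_abort("scenario", "missing input species_tree.nwk")
    }
    stage_msg(cfg, "scenario", "reconstructing gain/loss/HGT events")
    stree <- read_newick(p("species_tree.nwk"))
    traits <- pipeline_traits(pm, res$pathway_calls, res$tree_verdicts, defs, stree)
    scen <- build_scenario(stree, traits)
    write_scenario(scen, cfg$out_dir)
    res$scenario <- scen
  }

  # report
  if (want("report")) {
    stage_msg(cfg, "report", "rendering presence report")
    rep <- render_presence_report(res$pathway_calls, meta)
    readr::write_tsv(rep, o("presence_report.tsv"), progress = FALSE)
    writeLines(format_presence_report(rep), o("presence_report.txt"))
    res$report <- rep
  }

  manifest <- bind_rows(
    tibble(key = paste0("threshold.", names(t)),
           value = vapply(t, function(x) format(x, scientific = TRUE), "")),
    {
      ins <- list.files(cfg$input_dir, recursive = TRUE, full.names = TRUE)
      tibble(key = paste0("md5.", list.files(cfg$input_dir, recursive = TRUE)),
             value = unname(tools::md5sum(ins)))
    }
  )
  readr::write_tsv(manifest, o("manifest.tsv"), progress = FALSE)
  invisible(res)
}

# Trait profiles for the scenario stage: the key gene sets of the two
# pathways. Complex traits use completeness; transfer recoding comes from
# the gene-tree verdicts of the trait's subunits (modal donor).
pipeline_traits <- function(pm, calls, verdicts, defs, stree) {
  sp <- intersect(stree$tip.label, unique(pm$species))
  if (!setequal(sp, stree$tip.label)) {
    abort("[scenario] species tree leaves do not match screened species")
  }
  state_of <- function(x) setNames(x, calls$species)[stree$tip.label]
  enz_state <- function(enz) {
    w <- pm[pm$enzyme == enz, ]
    setNames(w$present, w$species)[stree$tip.label]
  }
  recode_for <- function(enzymes, states) {
    if (is.null(verdicts) || !nrow(verdicts)) return(NULL)
    v <- verdicts[verdicts$enzyme %in% enzymes &
                    verdicts$verdict == "hgt_candidate", ]
    v <- v[v$sequence_id %in% stree$tip.label, ]
    v <- v[states[v$sequence_id], ]
    if (!nrow(v)) return(NULL)
    v |>
      group_by(species = .data$sequence_id) |>
      summarise(donor = names(sort(table(.data$donor_group), decreasing = TRUE))[1],
                .groups = "drop")
  }
  mk <- function(id, states, enzymes) {
    states[is.na(states)] <- FALSE
    list(trait_id = id, leaf_states = states,
         hgt_recode = recode_for(enzymes, states))
  }
  codh <- defs$enzyme_id[defs$complex == "CODH/ACS"]
  gcs <- defs$enzyme_id[defs$complex == "GCS"]
  list(
    mk("FdhG", enz_state("FdhG"), "FdhG"),
    mk("CODH/ACS", state_of(calls$codh_acs_complete), codh),
    mk("GCS", state_of(calls$gcs_complete), gcs)
  )
}

#' Render the per-species presence report
#'
#' Joins the pathway calls with the taxon metadata into the standard
#' summary table: one row per species ordered by clade, with `+`/`-`
#' columns for FDH, CODH/ACS, GCS, the WL and rGly pathway calls, and the
#' curated autotrophy flag. Purely a formatting function: no call is
#' recomputed.
#'
#' @param calls Pathway-call tibble from [call_pathways()].
#' @param meta Taxon metadata tibble.
#' @return Tibble: `species`, `clade`, `FDH`, `CODH_ACS`, `GCS`, `WL`,
#'   `rGly`, `autotroph`.
#' @export
render_presence_report <- function(calls, meta) {
  pm <- function(x) ifelse(x, "+", "-")
  calls |>
    left_join(meta[c("species", "clade", "is_autotroph")], by = "species") |>
    arrange(.data$clade, .data$species) |>
    mutate(
      FDH = pm(.data$fdh_present),
      CODH_ACS = pm(.data$codh_acs_complete),
      GCS = pm(.data$gcs_complete),
      WL = pm(.data$wl_called),
      rGly = pm(.data$rgly_called),
      autotroph = dplyr::case_when(is.na(.data$is_autotroph) ~ "?",
                                   .data$is_autotroph ~ "+", TRUE ~ "-")
    ) |>
    select("species", "clade", "FDH", "CODH_ACS", "GCS", "WL", "rGly", "autotroph")
}

#' @rdname render_presence_report
#' @param report Tibble from `render_presence_report()`.
#' @return For `format_presence_report()`: character vector of fixed-width
#'   text lines.
#' @export
format_presence_report <- function(report) {
  m <- as.matrix(report)
  m <- rbind(colnames(m), m)
  widths <- apply(nchar(m), 2, max)
  apply(m, 1, function(r) {
    paste(mapply(function(x, w) formatC(x, width = w, flag = "-"), r, widths),
          collapse = "  ")
  })
}
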