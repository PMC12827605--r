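#' Filter hits by e-value and query coverage
#'
#' Keeps a hit iff its e-value is strictly below `evalue_max` and its query
#' coverage is at least `min_query_coverage` percent. This is the homolog
#' definition applied at the screening stage; both bounds are exact (an
#' e-value equal to the cutoff is removed, a coverage equal to the cutoff is
#' kept). Row order is preserved and the operation is idempotent.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param t A [thresholds()] object.
#' @return The surviving rows, same columns, same order.
#' @examples
#' h <- tibble::tibble(
#'   query_id = "q", subject_id = c("a", "b"), subject_species = c("a", "b"),
#'   percent_identity = 50, align_length = 100L, evalue = c(1e-6, 1e-5),
#'   bitscore = 100, query_coverage = c(80, 99), is_mag_derived = FALSE,
#'   taxid = ""
#' )
#' filter_hits(h)  # keeps only the first row
#' @export
filter_hits <- function(hits, t = thresholds()) {
  t <- as_thresholds(t)
  hits[hits$evalue < t$evalue_max & hits$query_coverage >= t$min_query_coverage, ]
}

#' Curate MAG-derived hits by e-value rank
#'
#' For the hits of a single query enzyme, removes the bottom 90% (by
#' default) of hits derived from metagenome-assembled genomes: among the
#' `n` MAG-derived rows, the `ceiling(n * mag_keep_fraction)` best by
#' ascending e-value are kept (ceiling, so at least one MAG hit survives
#' whenever any exist). Ties are broken by descending bitscore, then
#' ascending `subject_id`, so reruns are bit-identical. Non-MAG hits are
#' never touched. Relative input order is preserved among survivors.
#'
#' @inheritParams filter_hits
#' @return The surviving rows.
#' @export
mag_evalue_filter <- function(hits, t = thresholds()) {
  t <- as_thresholds(t)
  is_mag <- hits$is_mag_derived
  n_mag <- sum(is_mag)
  if (n_mag == 0) return(hits)
  n_keep <- ceiling(n_mag * t$mag_keep_fraction)
  idx <- which(is_mag)
  ord <- idx[order(hits$evalue[idx], -hits$bitscore[idx], hits$subject_id[idx])]
  keep_mag <- ord[seq_len(min(n_keep, n_mag))]
  hits[sort(c(which(!is_mag), keep_mag)), ]
}

#' Select one representative hit per taxid
#'
#' Emulates the diversity-covering curation step: hits whose taxid is not
#' in the allowed set are dropped, and within each allowed taxid only the
#' best hit survives (ascending e-value; ties by descending bitscore then
#' ascending `subject_id`). Hits with an empty taxid are dropped with a
#' warning.
#'
#' @inheritParams filter_hits
#' @param allowed_taxids Character vector of taxids to retain.
#' @return At most one row per allowed taxid.
#' @export
select_representatives <- function(hits, allowed_taxids) {
  no_tax <- is.na(hits$taxid) | hits$taxid == ""
  if (any(no_tax)) {
    warn(paste0("dropping ", sum(no_tax), " hit(s) with empty taxid"))
    hits <- hits[!no_tax, ]
  }
  hits <- hits[hits$taxid %in% allowed_taxids, ]
  hits |>
    arrange(.data$evalue, desc(.data$bitscore), .data$subject_id) |>
    group_by(.data$taxid) |>
    slice(1) |>
    ungroup()
}

#' Build the species x enzyme presence/absence matrix
#'
#' A cell (species, enzyme) is present iff at least one surviving hit pairs
#' that query enzyme with that subject species; no copy-number threshold is
#' applied. Provenance (all supporting subject ids and the best e-value) is
#' recorded per present cell. Hits referencing species outside
#' `species` are ignored with a warning.
#'
#' @param hits Filtered hit tibble; `query_id` must name the enzyme.
#' @param species Character vector: every species to be screened (rows).
#' @param enzymes Character vector: every enzyme screened for (columns).
#' @return A tibble of class `"pt_presence"` in long form: `species`,
#'   `enzyme`, `present` (logical), `n_hits`, `best_evalue`, `subject_ids`
#'   (list-column). Use [presence_wide()] for the species x enzyme 0/1
#'   table.
#' @export
build_presence_matrix <- function(hits, species, enzymes) {
  unknown <- setdiff(unique(hits$subject_species), species)
  if (length(unknown)) {
    warn(paste0("ignoring hits for species not in the species list: ",
                paste(unknown, collapse = ", ")))
    hits <- hits[hits$subject_species %in% species, ]
  }
  unknown_e <- setdiff(unique(hits$query_id), enzymes)
  if (length(unknown_e)) {
    warn(paste0("ignoring hits for enzymes not in the enzyme list: ",
                paste(unknown_e, collapse = ", ")))
    hits <- hits[hits$query_id %in% enzymes, ]
  }
  prov <- if (nrow(hits)) {
    hits |>
      group_by(species = .data$subject_species, enzyme = .data$query_id) |>
      summarise(n_hits = n(),
                best_evalue = min(.data$evalue),
                subject_ids = list(sort(unique(.data$subject_id))),
                .groups = "drop")
  } else {
    tibble(species = character(), enzyme = character(), n_hits = integer(),
           best_evalue = numeric(), subject_ids = list())
  }
  grid <- tidyr::expand_grid(species = species, enzyme = enzymes)
  out <- grid |>
    left_join(prov, by = c("species", "enzyme")) |>
    mutate(
      present = !is.na(.data$n_hits),
      n_hits = ifelse(is.na(.data$n_hits), 0L, .data$n_hits),
      subject_ids = ifelse(vapply(.data$subject_ids, is.null, logical(1)),
                           list(character()), .data$subject_ids)
    ) |>
    select("species", "enzyme", "present", "n_hits", "best_evalue", "subject_ids")
  class(out) <- c("pt_presence", class(out))
  out
}

#' Pivot a presence matrix to wide 0/1 form
#'
#' @param pm Presence tibble from [build_presence_matrix()].
#' @return Tibble with one row per species and one 0/1 integer column per
#'   enzyme.
#' @export
presence_wide <- function(pm) {
  pm |>
    mutate(present = as.integer(.data$present)) |>
    select("species", "enzyme", "present") |>
    tidyr::pivot_wider(names_from = "enzyme", values_from = "present")
}

#' Rebuild the long presence form from a wide 0/1 table
#'
#' @param wide Tibble with a `species` column and 0/1 enzyme columns.
#' @return A `"pt_presence"` tibble (provenance columns empty).
#' @export
presence_from_wide <- function(wide) {
  out <- wide |>
    tidyr::pivot_longer(-"species", names_to = "enzyme", values_to = "present") |>
    mutate(present = .data$present > 0,
           n_hits = NA_integer_, best_evalue = NA_real_,
           subject_ids = list(character()))
  class(out) <- c("pt_presence", class(out))
  out
}

#' @rdname build_presence_matrix
#' @param pm Presence tibble.
#' @param path Output path for the wide 0/1 TSV; a companion provenance TSV
#'   is written next to it with suffix `"_provenance.tsv"`.
#' @export
write_presence_matrix <- function(pm, path) {
  readr::write_tsv(presence_wide(pm), path, progress = FALSE)
  prov <- pm |>
    filter(.data$present) |>
    mutate(subject_ids = vapply(.data$subject_ids, paste, "", collapse = ",")) |>
    select("species", "enzyme", "n_hits", "best_evalue", "subject_ids")
  readr::write_tsv(prov, sub("\\.tsv$", "_provenance.tsv", path), progress = FALSE)
  invisible(path)
}
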