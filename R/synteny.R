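acs_subunit_labels <- function() c("acsA", "acsB", "acsC", "acsD", "acsE")

normalize_product <- function(x) {
  lab <- acs_subunit_labels()
  lab[match(tolower(x), tolower(lab))]
}

#' Detect a CODH/ACS synteny cluster around one AcsA copy
#'
#' Decides whether a given AcsA gene copy is clustered with the other
#' CODH/ACS subunit genes (AcsB--AcsE) on its contig. A partner counts as
#' clustered with the anchor iff the chain of subunit genes starting at the
#' anchor can be extended gene-by-gene, in either direction, with at most
#' `cluster_max_gap` intervening non-subunit genes between consecutive
#' chain members. Strand is ignored (co-orientation is reported by the
#' caller where needed, but not required). A copy whose chain reaches at
#' least `cluster_min_partners` distinct partner subunits is eligible for
#' concatenated phylogenetic analysis.
#'
#' @param loci Annotation tibble for one species
#'   (see [read_annotation_table()]).
#' @param anchor Locus tag of the AcsA copy to anchor the chain on.
#' @param t A [thresholds()] object (`cluster_max_gap`,
#'   `cluster_min_partners`).
#' @return One-row tibble: `species`, `anchor_locus`,
#'   `partner_subunits_found` (list-column of labels among acsB--acsE),
#'   `n_partners`, `is_clustered`, `concat_eligible`.
#' @export
detect_cluster <- function(loci, anchor, t = thresholds()) {
  t <- as_thresholds(t)
  if (length(unique(loci$species)) > 1) abort("detect_cluster expects loci for a single species")
  arow <- loci[loci$locus_tag == anchor, ]
  if (nrow(arow) != 1) abort(paste0("anchor locus '", anchor, "' not found (or not unique) in loci"))
  contig <- loci[loci$contig == arow$contig, ] |> arrange(.data$locus_index)
  sub_lab <- normalize_product(contig$product)
  is_sub <- !is.na(sub_lab)
  pos <- which(is_sub)
  a_pos <- which(contig$locus_tag == anchor)

  members <- a_pos
  right <- pos[pos > a_pos]
  prev <- a_pos
  for (q in right) {
    if (q - prev - 1 <= t$cluster_max_gap) { members <- c(members, q); prev <- q } else break
  }
  left <- rev(pos[pos < a_pos])
  prev <- a_pos
  for (q in left) {
    if (prev - q - 1 <= t$cluster_max_gap) { members <- c(members, q); prev <- q } else break
  }
  partners <- sort(unique(sub_lab[setdiff(members, a_pos)]))
  partners <- setdiff(partners, "acsA")
  tibble(
    species = arow$species,
    anchor_locus = anchor,
    partner_subunits_found = list(partners),
    n_partners = length(partners),
    is_clustered = length(partners) >= 1,
    concat_eligible = length(partners) >= t$cluster_min_partners
  )
}

#' Detect clusters for every AcsA copy in an annotation table
#'
#' @param loci Annotation tibble (possibly many species).
#' @inheritParams detect_cluster
#' @return Tibble of cluster calls, one row per AcsA copy.
#' @export
detect_acsA_clusters <- function(loci, t = thresholds()) {
  anchors <- loci |> filter(tolower(.data$product) == "acsa")
  purrr::map_dfr(seq_len(nrow(anchors)), function(i) {
    sp <- anchors$species[i]
    detect_cluster(loci[loci$species == sp, ], anchors$locus_tag[i], t)
  })
}

#' Classify AcsA copies as WL-candidates or standalone CooS-like
#'
#' Clustered copies (those forming a synteny cluster with other CODH/ACS
#' subunits) are labelled `"WL-candidate"` -- consistent with a function in
#' acetyl-CoA synthesis; unclustered copies are labelled
#' `"standalone CooS-like"`. A per-species summary notes when both kinds
#' co-occur in the same genome.
#'
#' @param calls Cluster-call tibble from [detect_cluster()] /
#'   [detect_acsA_clusters()].
#' @return List with `copies` (per-copy tibble with a `functional_class`
#'   column) and `species_summary` (per-species tibble with `kind` among
#'   `"both kinds"`, `"clustered only"`, `"standalone only"`).
#' @export
classify_acsA_copies <- function(calls) {
  if (!nrow(calls)) {
    return(list(
      copies = tibble(species = character(), anchor_locus = character(),
                      is_clustered = logical(), functional_class = character()),
      species_summary = tibble(species = character(), kind = character())
    ))
  }
  copies <- calls |>
    mutate(functional_class = ifelse(.data$is_clustered, "WL-candidate",
                                     "standalone CooS-like")) |>
    select("species", "anchor_locus", "is_clustered", "functional_class")
  species_summary <- copies |>
    group_by(.data$species) |>
    summarise(kind = dplyr::case_when(
      any(.data$is_clustered) & any(!.data$is_clustered) ~ "both kinds",
      all(.data$is_clustered) ~ "clustered only",
      TRUE ~ "standalone only"
    ), .groups = "drop")
  list(copies = copies, species_summary = species_summary)
}

#' Export detected clusters as BED intervals
#'
#' Converts each clustered call into a BED record spanning the chain
#' members. Internal coordinates are 1-based inclusive; BED is 0-based
#' half-open, so `start - 1` / `end` is written.
#'
#' @param calls Cluster calls from [detect_acsA_clusters()].
#' @param loci The annotation tibble the calls came from.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(calls, loci, path) {
  rows <- calls |> filter(.data$is_clustered)
  bed <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    sp <- rows$species[i]
    lab <- c("acsA", rows$partner_subunits_found[[i]])
    arow <- loci[loci$species == sp & loci$locus_tag == rows$anchor_locus[i], ]
    members <- loci |>
      filter(.data$species == sp, .data$contig == arow$contig,
             tolower(.data$product) %in% tolower(lab))
    tibble(chrom = arow$contig, start = min(members$start) - 1L,
           end = max(members$end),
           name = paste0(sp, ":", rows$anchor_locus[i]))
  })
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
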