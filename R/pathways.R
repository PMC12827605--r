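presence_row <- function(pm, sp) {
  sub <- pm[pm$species == sp, ]
  setNames(sub$present, sub$enzyme)
}

#' Call formate dehydrogenase presence for one species
#'
#' FDH counts as present when the species encodes a homolog of either
#' catalytic-subunit family: cytoplasmic Fdh or FdhG.
#'
#' @param row Named logical vector of presence calls for one species
#'   (names are enzyme ids; must contain `cytFdh` and `FdhG`).
#' @return Logical scalar.
#' @export
call_fdh <- function(row) {
  if (!all(c("cytFdh", "FdhG") %in% names(row))) {
    abort("presence row must contain cells for cytFdh and FdhG")
  }
  unname(row[["cytFdh"]] || row[["FdhG"]])
}

#' Call completeness of a multi-subunit complex
#'
#' A complex (CODH/ACS, GCS or GR) is complete iff every subunit declared
#' for it in the enzyme definition table is present.
#'
#' @inheritParams call_fdh
#' @param complex_id Complex label as used in the `complex` column of the
#'   enzyme definitions.
#' @param defs Enzyme definition tibble (see [default_enzyme_defs()]).
#' @return Logical scalar.
#' @export
call_complex_complete <- function(row, complex_id, defs = default_enzyme_defs()) {
  subunits <- defs$enzyme_id[defs$complex == complex_id]
  if (!length(subunits)) abort(paste0("complex '", complex_id, "' has no declared subunits"))
  miss <- setdiff(subunits, names(row))
  if (length(miss)) {
    abort(paste0("presence row is missing subunit cell(s): ", paste(miss, collapse = ", ")))
  }
  all(row[subunits])
}

#' Call the WL and rGly pathways for every species
#'
#' Applies the completeness rules per species: the Wood-Ljungdahl (WL)
#' pathway is called when FDH (either family) and all five CODH/ACS
#' subunits are present; the reductive glycine (rGly) pathway when FDH and
#' all five glycine-cleavage-system subunits are present. Downstream
#' consistency columns record whether the serine/pyruvate route (PFO, PSP
#' and SHMT all present) and the glycine reductase complex are complete.
#'
#' @param pm Presence tibble from [build_presence_matrix()] (or
#'   [presence_from_wide()]).
#' @param defs Enzyme definition tibble.
#' @return A tibble of class `"pt_pathway_calls"`, one row per species:
#'   `species`, `fdh_present`, `codh_acs_complete`, `gcs_complete`,
#'   `wl_called`, `rgly_called`, `downstream_wl_ok`, `gr_complete`.
#' @export
call_pathways <- function(pm, defs = default_enzyme_defs()) {
  species <- unique(pm$species)
  need <- c("cytFdh", "FdhG", defs$enzyme_id[defs$complex %in% c("CODH/ACS", "GCS")],
            "PFO", "PSP", "SHMT")
  miss <- setdiff(need, unique(pm$enzyme))
  if (length(miss)) {
    abort(paste0("presence matrix is missing enzyme column(s): ", paste(miss, collapse = ", ")))
  }
  has_gr <- any(defs$complex == "GR") && all(defs$enzyme_id[defs$complex == "GR"] %in% pm$enzyme)
  out <- purrr::map_dfr(species, function(sp) {
    row <- presence_row(pm, sp)
    fdh <- call_fdh(row)
    codh <- call_complex_complete(row, "CODH/ACS", defs)
    gcs <- call_complex_complete(row, "GCS", defs)
    tibble(
      species = sp,
      fdh_present = fdh,
      codh_acs_complete = codh,
      gcs_complete = gcs,
      wl_called = fdh && codh,
      rgly_called = fdh && gcs,
      downstream_wl_ok = all(row[c("PFO", "PSP", "SHMT")]),
      gr_complete = if (has_gr) call_complex_complete(row, "GR", defs) else NA
    )
  })
  class(out) <- c("pt_pathway_calls", class(out))
  out
}

#' Check pathway calls against curated autotrophy flags
#'
#' For each species flagged autotrophic in the taxon metadata, reports
#' whether at least one carbon-fixation pathway is called and whether a
#' downstream route to biomass is complete: for WL the serine/pyruvate
#' route (PFO + PSP + SHMT), for rGly either the glycine reductase complex
#' or the SHMT-then-PFO serine route. No new presence calls are made;
#' this is purely a consistency table. Heterotrophs with at least one
#' called pathway are reported as carrying genes without demonstrated
#' autotrophy; species with unknown autotrophy are marked not applicable.
#'
#' @param calls Pathway-call tibble from [call_pathways()].
#' @param meta Taxon metadata tibble (see [read_taxon_meta()]).
#' @return Tibble: `species`, `is_autotroph`, `any_pathway_called`,
#'   `downstream_ok`, `status` (one of `"consistent"`, `"inconsistent"`,
#'   `"genes_without_demonstrated_autotrophy"`, `"no_pathway_genes"`,
#'   `"not_applicable"`).
#' @export
autotrophy_consistency <- function(calls, meta) {
  df <- left_join(calls, meta[c("species", "is_autotroph")], by = "species")
  df |>
    mutate(
      any_pathway_called = .data$wl_called | .data$rgly_called,
      rgly_downstream_ok = (!is.na(.data$gr_complete) & .data$gr_complete) |
        .data$downstream_wl_ok,
      downstream_ok = (.data$wl_called & .data$downstream_wl_ok) |
        (.data$rgly_called & .data$rgly_downstream_ok),
      status = dplyr::case_when(
        is.na(.data$is_autotroph) ~ "not_applicable",
        .data$is_autotroph & .data$any_pathway_called & .data$downstream_ok ~ "consistent",
        .data$is_autotroph ~ "inconsistent",
        .data$any_pathway_called ~ "genes_without_demonstrated_autotrophy",
        TRUE ~ "no_pathway_genes"
      )
    ) |>
    select("species", "is_autotroph", "any_pathway_called", "downstream_ok", "status")
}
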