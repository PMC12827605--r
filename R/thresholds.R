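#' Screening and inference thresholds
#'
#' Bundles every numeric cutoff used along the pipeline into a single
#' validated object, so that each stage receives the same, explicit set and a
#' run log can echo them. Defaults are the standard operating values for this
#' kind of comparative-genomics screen:
#'
#' * `evalue_max`: homologs must have e-value strictly below this (default
#'   `1e-5`).
#' * `min_query_coverage`: homologs must cover at least this percentage of
#'   the query (default `70`, inclusive, on the 0--100 scale).
#' * `mag_keep_fraction`: among hits derived from metagenome-assembled
#'   genomes (MAGs), only the top fraction by e-value is kept per query
#'   enzyme (default `0.10`, i.e. the bottom 90% is removed).
#' * `long_branch_cutoff`: leaves whose pendant branch exceeds this many
#'   substitutions per site are pruned from gene trees (default `1.5`,
#'   strict).
#' * `hgt_support_min`: minimum bootstrap support for a nestedness-based
#'   horizontal-transfer call (default `95`).
#' * `group_support_min`: minimum bootstrap support for a focal clade to be
#'   flagged a "distinct group" (default `95`).
#' * `cluster_max_gap`: maximum number of intervening non-subunit genes
#'   between consecutive members of a synteny cluster (default `2`).
#' * `cluster_min_partners`: partner subunits required for a clustered copy
#'   to be eligible for concatenated phylogenetics (default `3`).
#' * `hgt_majority`: fraction of non-focal leaves in the enclosing clade
#'   that a single foreign group must exceed (strictly) to be named donor
#'   (default `0.5`).
#'
#' @param ... Named overrides of the defaults above.
#' @return An object of class `"pt_thresholds"` (a named list).
#' @examples
#' thresholds()
#' thresholds(min_query_coverage = 80)
#' @export
thresholds <- function(...) {
  t <- list(
    evalue_max = 1e-5,
    min_query_coverage = 70,
    mag_keep_fraction = 0.10,
    long_branch_cutoff = 1.5,
    hgt_support_min = 95L,
    group_support_min = 95L,
    cluster_max_gap = 2L,
    cluster_min_partners = 3L,
    hgt_majority = 0.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(t))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown threshold name(s): ", paste(bad, collapse = ", ")))
    }
    t[names(dots)] <- dots
  }
  validate_thresholds(t)
}

validate_thresholds <- function(t) {
  stop_unless <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("invalid thresholds: ", msg))
  stop_unless(is.numeric(t$evalue_max) && t$evalue_max > 0, "evalue_max must be > 0")
  stop_unless(t$min_query_coverage >= 0 && t$min_query_coverage <= 100,
              "min_query_coverage must lie in [0, 100]")
  stop_unless(t$mag_keep_fraction >= 0 && t$mag_keep_fraction <= 1,
              "mag_keep_fraction must lie in [0, 1]")
  stop_unless(t$long_branch_cutoff > 0, "long_branch_cutoff must be > 0")
  stop_unless(t$hgt_support_min >= 0 && t$hgt_support_min <= 100,
              "hgt_support_min must lie in [0, 100]")
  stop_unless(t$group_support_min >= 0 && t$group_support_min <= 100,
              "group_support_min must lie in [0, 100]")
  stop_unless(t$cluster_max_gap >= 0, "cluster_max_gap must be >= 0")
  stop_unless(t$cluster_min_partners >= 1, "cluster_min_partners must be >= 1")
  stop_unless(t$hgt_majority >= 0 && t$hgt_majority < 1, "hgt_majority must lie in [0, 1)")
  structure(t, class = "pt_thresholds")
}

#' @export
print.pt_thresholds <- function(x, ...) {
  cat("<pt_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_thresholds <- function(t) {
  if (inherits(t, "pt_thresholds")) return(t)
  if (is.null(t)) return(thresholds())
  do.call(thresholds, as.list(t))
}
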