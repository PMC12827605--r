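#' Read a protein similarity-search hit table
#'
#' Parses a BLAST-style tabular file (outfmt-6 style: 12 standard columns)
#' extended with a mandatory query-coverage column `qcov` and, optionally,
#' `species` and `taxid` columns. Lines starting with `#` are ignored. A
#' header line is detected automatically (its e-value field is non-numeric);
#' without a header the columns are read positionally as
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qcov [species] [taxid]`. When no `species` column is
#' present the subject species is taken as the part of `sseqid` before the
#' first `|` (the whole id if there is none).
#'
#' Query coverage must be on the 0--100 percent scale; values that all lie
#' in \[0, 1\] are rejected rather than rescaled, to avoid silent unit bugs.
#'
#' @param path Path to the tab-separated hit table.
#' @param mag_species Character vector of species names whose genomes are
#'   metagenome-assembled (MAGs); hits from them get `is_mag_derived = TRUE`.
#' @return A tibble with one row per hit: `query_id`, `subject_id`,
#'   `subject_species`, `percent_identity`, `align_length`, `evalue`,
#'   `bitscore`, `query_coverage`, `is_mag_derived`, `taxid`. Malformed
#'   lines (wrong field count) are skipped with a warning giving their line
#'   numbers and are recorded in the `"bad_lines"` attribute, so
#'   `rows-in = rows-parsed + rows-reported`.
#' @export
read_hit_table <- function(path, mag_species = character()) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- seq_along(raw)[keep]
  if (!length(lines)) {
    warn(paste0("hit table is empty: ", path))
    return(empty_hit_tbl())
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  first <- fields[[1]]
  has_header <- length(first) >= 11 && is.na(suppressWarnings(as.numeric(first[11])))
  if (has_header) {
    header <- first
    if (!"qcov" %in% header) {
      abort("hit table is missing the required query-coverage column 'qcov'")
    }
    fields <- fields[-1]
    line_no <- line_no[-1]
  } else {
    if (length(first) < 13) {
      abort("hit table is missing the required query-coverage column 'qcov' (need >= 13 columns without a header)")
    }
    header <- c(std, "qcov", "species", "taxid")[seq_len(max(lengths(fields)))]
  }
  if (!length(fields)) {
    warn(paste0("hit table has a header but no records: ", path))
    return(empty_hit_tbl())
  }

  ok <- lengths(fields) == length(header)
  if (any(!ok)) {
    warn(paste0("skipping ", sum(!ok), " malformed hit-table line(s): ",
                paste(line_no[!ok], collapse = ", ")))
  }
  bad <- tibble(line = line_no[!ok], text = lines[if (has_header) which(!ok) + 1L else which(!ok)])
  m <- do.call(rbind, fields[ok])
  colnames(m) <- header
  col <- function(nm) if (nm %in% header) m[, nm] else rep(NA_character_, nrow(m))

  evalue <- suppressWarnings(as.numeric(col("evalue")))
  if (anyNA(evalue)) {
    abort(paste0("non-numeric evalue at line(s): ",
                 paste(line_no[ok][is.na(evalue)], collapse = ", ")))
  }
  qcov <- suppressWarnings(as.numeric(col("qcov")))
  if (anyNA(qcov)) abort("non-numeric qcov value in hit table")
  if (all(qcov >= 0 & qcov <= 1) && any(qcov > 0)) {
    abort("query coverage looks like a 0-1 fraction; pathtracer requires the 0-100 percent scale")
  }
  if (any(qcov < 0 | qcov > 100)) abort("query coverage outside [0, 100]")
  if (any(evalue < 0)) abort("negative evalue in hit table")

  species <- col("species")
  no_sp <- is.na(species) | species == ""
  species[no_sp] <- sub("\\|.*$", "", col("sseqid")[no_sp])
  taxid <- col("taxid")
  taxid[is.na(taxid)] <- ""

  out <- tibble(
    query_id = col("qseqid"),
    subject_id = col("sseqid"),
    subject_species = species,
    percent_identity = as.numeric(col("pident")),
    align_length = as.integer(col("length")),
    evalue = evalue,
    bitscore = as.numeric(col("bitscore")),
    query_coverage = qcov,
    is_mag_derived = species %in% mag_species,
    taxid = taxid
  )
  if (any(!nzchar(out$query_id)) || any(!nzchar(out$subject_id))) {
    abort("empty query_id or subject_id in hit table")
  }
  attr(out, "bad_lines") <- bad
  out
}

empty_hit_tbl <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    subject_species = character(), percent_identity = numeric(),
    align_length = integer(), evalue = numeric(), bitscore = numeric(),
    query_coverage = numeric(), is_mag_derived = logical(), taxid = character()
  )
}

#' Write a hit table
#'
#' Inverse of [read_hit_table()]: writes the extended BLAST tabular format
#' with a header line (`qseqid ... bitscore qcov species taxid`). Standard
#' alignment-coordinate columns not tracked by the in-memory representation
#' are written as 0 placeholders.
#'
#' @param hits Tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$percent_identity, length = hits$align_length,
    mismatch = 0L, gapopen = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = format(hits$evalue, digits = 15, scientific = TRUE, trim = TRUE),
    bitscore = hits$bitscore, qcov = hits$query_coverage,
    species = hits$subject_species, taxid = hits$taxid
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write Newick trees
#'
#' `read_newick()` parses a Newick file into an [ape::phylo] object and
#' interprets internal-node labels as integer bootstrap supports where they
#' are numeric. `write_newick()` writes supports back as internal-node
#' labels, so the pair round-trips topology, branch lengths (to printed
#' precision) and supports. Unrooted trees are represented the way `ape`
#' represents them, as a basal multifurcation; `ape::is.rooted()` is the
#' rootedness flag and all monophyly logic in this package consults it.
#'
#' @param path Path to a Newick file (first tree is read).
#' @param supports Dialect for support values: `"label"` (default) reads the
#'   internal-node label directly; `"slash-last"` additionally splits
#'   compound labels like `"97.3/100"` and keeps the last numeric field.
#' @return A `phylo` object. Numeric supports are available via
#'   [tree_supports()].
#' @export
read_newick <- function(path, supports = c("label", "slash-last")) {
  supports <- match.arg(supports)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_parens(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort(paste0("could not parse Newick in ", path))
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (supports == "slash-last" && !is.null(tree$node.label)) {
    tree$node.label <- vapply(strsplit(tree$node.label, "/", fixed = TRUE),
                              function(p) if (length(p)) p[[length(p)]] else "",
                              character(1))
  }
  tree
}

check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(paste0("unbalanced ')' in Newick at character ", i))
    }
  }
  if (depth != 0L) {
    abort(paste0("unbalanced '(' in Newick: ", depth,
                 " unclosed at end of input (length ", length(chars), ")"))
  }
  invisible(TRUE)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @return For `write_newick()`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Extract bootstrap supports from internal-node labels
#'
#' @param tree A `phylo` object.
#' @return Integer vector of length `tree$Nnode` (internal nodes in `ape`
#'   numbering order); `NA` where the label is absent or non-numeric (e.g.
#'   the root of an unrooted representation).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_integer_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  as.integer(round(sup))
}

#' Read a genome annotation table
#'
#' Accepts either a tab-separated locus table with header columns `species`,
#' `contig`, `start`, `end`, `strand`, `locus_tag`, `product`, or a GFF3
#' subset (`format = "gff3"`: CDS features with `locus_tag` and `product`
#' attributes; the seqid column is `contig` and the species is passed via
#' `species`). Coordinates are 1-based inclusive. After reading, genes are
#' ranked along each contig by start coordinate into `locus_index`.
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @param species Species name used for every record when reading GFF3.
#' @return A tibble with columns `species`, `contig`, `start`, `end`,
#'   `strand`, `locus_tag`, `product`, `locus_index`.
#' @export
read_annotation_table <- function(path, format = c("tsv", "gff3"), species = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
    need <- c("species", "contig", "start", "end", "strand", "locus_tag", "product")
    miss <- setdiff(need, names(df))
    if (length(miss)) abort(paste0("annotation table missing column(s): ", paste(miss, collapse = ", ")))
    df <- df[need]
  } else {
    if (is.null(species)) abort("species must be supplied when reading GFF3")
    ln <- readLines(path, warn = FALSE)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) == 9L]
    f <- f[vapply(f, function(x) x[3] == "CDS", logical(1))]
    attr_get <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    df <- tibble(
      species = species,
      contig = vapply(f, `[`, "", 1),
      start = as.integer(vapply(f, `[`, "", 4)),
      end = as.integer(vapply(f, `[`, "", 5)),
      strand = vapply(f, `[`, "", 7),
      locus_tag = vapply(f, function(x) attr_get(x[9], "locus_tag"), ""),
      product = vapply(f, function(x) attr_get(x[9], "product"), "")
    )
  }
  if (any(df$end < df$start)) {
    abort("annotation record with end < start (coordinates are 1-based inclusive)")
  }
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  dup <- duplicated(df[c("species", "locus_tag")])
  if (any(dup)) {
    abort(paste0("duplicate (species, locus_tag): ",
                 paste(unique(paste(df$species[dup], df$locus_tag[dup])), collapse = "; ")))
  }
  df |>
    group_by(.data$species, .data$contig) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(locus_index = row_number()) |>
    ungroup() |>
    arrange(.data$species, .data$contig, .data$locus_index)
}

#' @rdname read_annotation_table
#' @param loci Annotation tibble as returned by `read_annotation_table()`.
#' @export
write_annotation_table <- function(loci, path) {
  readr::write_tsv(
    loci[c("species", "contig", "start", "end", "strand", "locus_tag", "product")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Controlled vocabulary of taxon group labels
#'
#' In-phylum clades are single letters A--E; everything else is an external
#' group used as potential HGT donor or outgroup scaffold.
#'
#' @return Character vector of accepted `clade` labels.
#' @export
clade_vocabulary <- function() {
  c("A", "B", "C", "D", "E",
    "Myxococcota", "PVC", "Nitrospirota", "Epsilonproteobacteria",
    "Chloroflexota", "other")
}

#' Read the taxon metadata table
#'
#' Tab-separated with header `species`, `clade`, `is_mag`, `is_autotroph`.
#' `is_autotroph` accepts `true`/`false`/`unknown` (case-insensitive; also
#' `TRUE`/`FALSE`/`NA`). Clade labels must come from [clade_vocabulary()].
#'
#' @param path Input path.
#' @param vocabulary Accepted clade labels.
#' @return Tibble with columns `species`, `clade`, `is_mag` (logical),
#'   `is_autotroph` (logical, `NA` = unknown).
#' @export
read_taxon_meta <- function(path, vocabulary = clade_vocabulary()) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("species", "clade", "is_mag", "is_autotroph")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("taxon table missing column(s): ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(df$clade), vocabulary)
  if (length(bad)) {
    abort(paste0("unknown clade label(s): ", paste(bad, collapse = ", "),
                 "; accepted: ", paste(vocabulary, collapse = ", ")))
  }
  parse_flag <- function(x, allow_na) {
    lx <- tolower(x)
    out <- rep(NA, length(x))
    out[lx %in% c("true", "t", "1", "yes")] <- TRUE
    out[lx %in% c("false", "f", "0", "no")] <- FALSE
    if (!allow_na && anyNA(out)) abort("is_mag must be true/false")
    out
  }
  tibble(
    species = df$species,
    clade = df$clade,
    is_mag = parse_flag(df$is_mag, allow_na = FALSE),
    is_autotroph = parse_flag(df$is_autotroph, allow_na = TRUE)
  )
}

#' @rdname read_taxon_meta
#' @param meta Taxon tibble as returned by `read_taxon_meta()`.
#' @export
write_taxon_meta <- function(meta, path) {
  out <- meta
  out$is_mag <- tolower(as.character(out$is_mag))
  out$is_autotroph <- ifelse(is.na(meta$is_autotroph), "unknown",
                             tolower(as.character(meta$is_autotroph)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Enzyme and complex definitions
#'
#' `default_enzyme_defs()` returns the built-in role table covering both
#' formate dehydrogenase families (cytoplasmic Fdh and FdhG), the five
#' CODH/ACS subunits (AcsA--AcsE), the five glycine cleavage system subunits
#' (GCSP alpha/beta, GCST, GCSL, GCSH), the shared methyl-branch enzymes,
#' the downstream serine/pyruvate route (PFO, PSP, SHMT) and the five
#' glycine reductase subunits. `read_enzyme_defs()` reads the same shape
#' from a tab-separated file with header `enzyme_id`, `complex`,
#' `pathway_roles` (comma-separated subset of `WL`, `rGly`, `downstream`).
#'
#' Validation requires each of the five CODH/ACS and five GCS subunits to
#' appear exactly once.
#'
#' @param path Input path.
#' @return Tibble with columns `enzyme_id`, `complex`, `pathway_roles`
#'   (list-column of character vectors).
#' @export
read_enzyme_defs <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("enzyme_id", "complex", "pathway_roles")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("enzyme table missing column(s): ", paste(miss, collapse = ", ")))
  defs <- tibble(
    enzyme_id = df$enzyme_id,
    complex = df$complex,
    pathway_roles = lapply(strsplit(df$pathway_roles, ","), trimws)
  )
  validate_enzyme_defs(defs)
}

validate_enzyme_defs <- function(defs) {
  check_complex <- function(cx, subunits) {
    have <- defs$enzyme_id[defs$complex == cx]
    counts <- table(factor(have, levels = subunits))
    if (any(counts != 1)) {
      abort(paste0("incomplete ", cx, " complex definition: need exactly one each of ",
                   paste(subunits, collapse = ", ")))
    }
  }
  check_complex("CODH/ACS", c("AcsA", "AcsB", "AcsC", "AcsD", "AcsE"))
  check_complex("GCS", c("GCSPa", "GCSPb", "GCST", "GCSL", "GCSH"))
  bad <- setdiff(unlist(defs$pathway_roles), c("WL", "rGly", "downstream"))
  if (length(bad)) abort(paste0("unknown pathway role(s): ", paste(bad, collapse = ", ")))
  defs
}

#' @rdname read_enzyme_defs
#' @export
default_enzyme_defs <- function() {
  d <- function(id, cx, roles) tibble(enzyme_id = id, complex = cx,
                                      pathway_roles = list(roles))
  bind_rows(
    d("cytFdh", "FDH", c("WL", "rGly")),
    d("FdhG", "FDH", c("WL", "rGly")),
    d("AcsA", "CODH/ACS", "WL"), d("AcsB", "CODH/ACS", "WL"),
    d("AcsC", "CODH/ACS", "WL"), d("AcsD", "CODH/ACS", "WL"),
    d("AcsE", "CODH/ACS", "WL"),
    d("GCSPa", "GCS", "rGly"), d("GCSPb", "GCS", "rGly"),
    d("GCST", "GCS", "rGly"), d("GCSL", "GCS", "rGly"),
    d("GCSH", "GCS", "rGly"),
    d("FTL", "none", c("WL", "rGly")),   # formate--THF ligase
    d("MTC", "none", c("WL", "rGly")),   # methenyl-THF cyclohydrolase
    d("MTD", "none", c("WL", "rGly")),   # methylene-THF dehydrogenase
    d("MTR", "none", "WL"),              # methylene-THF reductase
    d("PFO", "none", "downstream"),
    d("PSP", "none", "downstream"),
    d("SHMT", "none", "downstream"),
    d("GR1", "GR", "downstream"), d("GR2", "GR", "downstream"),
    d("GR3", "GR", "downstream"), d("GR4", "GR", "downstream"),
    d("GR5", "GR", "downstream")
  )
}

#' @rdname read_enzyme_defs
#' @param defs Enzyme definition tibble.
#' @export
write_enzyme_defs <- function(defs, path) {
  out <- tibble(
    enzyme_id = defs$enzyme_id,
    complex = defs$complex,
    pathway_roles = vapply(defs$pathway_roles, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
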