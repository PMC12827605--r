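# fixtures shared across test files; everything is built in code

make_hits <- function(evalue, qcov, species = paste0("s", seq_along(evalue)),
                      query = "enzX", bitscore = rep(100, length(evalue)),
                      is_mag = rep(FALSE, length(evalue)),
                      taxid = paste0("tx", seq_along(evalue)),
                      subject_id = paste0(species, "|h", seq_along(evalue))) {
  tibble::tibble(
    query_id = query, subject_id = subject_id, subject_species = species,
    percent_identity = 50, align_length = 200L, evalue = evalue,
    bitscore = bitscore, query_coverage = qcov, is_mag_derived = is_mag,
    taxid = taxid
  )
}

# backbone fixture with named internal nodes removed, supports settable
backbone <- function() clade_backbone_tree()

backbone_states <- function(...) {
  st <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, E = TRUE, OUT = FALSE)
  over <- c(...)
  st[names(over)] <- over
  st
}

# presence row covering every default enzyme, everything absent except `on`
presence_row_fixture <- function(on = character()) {
  ids <- default_enzyme_defs()$enzyme_id
  setNames(ids %in% on, ids)
}

# a wide truth matrix -> long presence tibble for call_pathways
presence_fixture <- function(rows) {
  ids <- default_enzyme_defs()$enzyme_id
  purrr::map_dfr(names(rows), function(sp) {
    tibble::tibble(species = sp, enzyme = ids, present = ids %in% rows[[sp]])
  }) |> presence_from_long()
}

presence_from_long <- function(x) {
  x$n_hits <- NA_integer_
  x$best_evalue <- NA_real_
  x$subject_ids <- list(character())
  class(x) <- c("pt_presence", class(x))
  x
}

# independent oracle: tip descendants per node by plain recursion on the
# (unordered) edge matrix -- deliberately not the package's postorder sweep
oracle_tipsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(v) {
    if (v <= n_tip) return(v)
    sort(unlist(lapply(kids[[as.character(v)]], rec)))
  }
  lapply(seq_len(n_tip + tree$Nnode), rec)
}

# oracle monophyly: exhaustive check over all edges' bipartitions
oracle_monophyletic <- function(tree, focal) {
  n_tip <- length(tree$tip.label)
  fidx <- sort(match(focal, tree$tip.label))
  if (length(fidx) == n_tip) return(TRUE)
  sets <- oracle_tipsets(tree)
  for (ch in tree$edge[, 2]) {
    below <- sets[[ch]]
    if (identical(below, fidx)) return(TRUE)
    if (identical(sort(setdiff(seq_len(n_tip), below)), fidx)) return(TRUE)
  }
  FALSE
}

# oracle largest all-focal side size
oracle_largest_focal <- function(tree, focal) {
  n_tip <- length(tree$tip.label)
  fidx <- match(focal, tree$tip.label)
  sets <- oracle_tipsets(tree)
  best <- 1L
  for (ch in tree$edge[, 2]) {
    for (side in list(sets[[ch]], setdiff(seq_len(n_tip), sets[[ch]]))) {
      if (length(side) && all(side %in% fidx)) best <- max(best, length(side))
    }
  }
  best
}

# brute-force minimum changes over all internal labelings
oracle_min_changes <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  leaf <- as.integer(states[tree$tip.label])
  best <- Inf
  for (code in 0:(2^n_int - 1)) {
    internal <- as.integer(intToBits(code))[seq_len(n_int)]
    full <- c(leaf, internal)
    ch <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}
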