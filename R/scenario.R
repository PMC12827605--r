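# Edges are identified by their child node; the signature (sorted leaf set
# below the child) is stable across tree re-reads and is how truth logs and
# reconstructions are matched.
edge_signature <- function(tree, child, sets = NULL) {
  sets <- sets %||% node_tip_sets(tree)
  paste(sort(tree$tip.label[sets[[child]]]), collapse = "|")
}

check_leaf_states <- function(tree, leaf_states) {
  miss <- setdiff(tree$tip.label, names(leaf_states))
  if (length(miss)) {
    abort(paste0("leaf(s) missing a state: ", paste(miss, collapse = ", ")))
  }
  as.logical(leaf_states[tree$tip.label])
}

#' Minimum-change (Fitch) parsimony for a binary trait
#'
#' Counts the minimal number of presence/absence state changes needed to
#' explain the leaf states on a rooted tree, with unrestricted gains and
#' losses, and returns one optimal internal labeling. Polytomies are soft:
#' they are resolved arbitrarily (via [ape::multi2di()]) before the count
#' and the resolution is flagged in the result.
#'
#' @param tree Rooted `phylo` object.
#' @param leaf_states Named logical (or 0/1) vector over all tip labels.
#' @return List with `min_changes`, `node_states` (logical vector over
#'   tips then internal nodes, in `ape` numbering of the possibly resolved
#'   tree), `tree` (the tree the labeling refers to) and `resolved`
#'   (`TRUE` if polytomies were resolved).
#' @export
fitch_min_changes <- function(tree, leaf_states) {
  states <- check_leaf_states(tree, leaf_states)
  if (anyNA(states)) abort("leaf states must be TRUE/FALSE with no NA")
  resolved <- FALSE
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree)
    resolved <- TRUE
    states <- as.logical(leaf_states[tree$tip.label])
  }
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  # state sets as bitmasks: 1 = absent, 2 = present, 3 = either
  mask <- integer(n_all)
  mask[seq_len(n_tip)] <- ifelse(states, 2L, 1L)
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  kids <- split(eo[, 2], eo[, 1])
  # process each parent only once all of its edges (and hence all child
  # masks) have been seen
  last_pos <- tapply(seq_len(nrow(eo)), eo[, 1], max)
  for (p in as.integer(names(sort(last_pos)))) {
    acc <- 3L
    for (ch in kids[[as.character(p)]]) acc <- bitwAnd(acc, mask[ch])
    if (acc == 0L) {
      acc <- 3L
      for (ch in kids[[as.character(p)]]) acc <- bitwOr(acc, mask[ch])
      changes <- changes + 1L
    }
    mask[p] <- acc
  }
  # top-down pass: pick a concrete optimal state per node (prefer present
  # on ties at the root; children copy the parent state when allowed)
  node_states <- logical(n_all)
  rt <- root_node(tree)
  node_states[rt] <- bitwAnd(mask[rt], 2L) > 0L
  pre <- eo[rev(seq_len(nrow(eo))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1]; ch <- pre[k, 2]
    want <- if (node_states[p]) 2L else 1L
    node_states[ch] <- if (bitwAnd(mask[ch], want) > 0L) node_states[p]
                       else bitwAnd(mask[ch], 2L) > 0L
  }
  list(min_changes = changes, node_states = node_states, tree = tree,
       resolved = resolved)
}

# all-absent flags per node (TRUE iff every leaf below is absent)
all_absent_below <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  absent <- logical(n_tip + tree$Nnode)
  absent[seq_len(n_tip)] <- !states
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  first <- !duplicated(eo[, 1])
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]
    absent[p] <- if (first[k]) absent[eo[k, 2]] else absent[p] && absent[eo[k, 2]]
  }
  absent
}

#' Dollo parsimony reconstruction for a binary trait
#'
#' Under the Dollo constraint the trait is gained exactly once -- on the
#' stem edge above the most recent common ancestor (MRCA) of all leaves
#' carrying it -- and every absence is explained by a loss. The losses are
#' the minimal edge set below the gain: one loss on the stem of each
#' maximal all-absent subtree. Edges are identified by their child node
#' and by their leaf-set signature.
#'
#' @inheritParams fitch_min_changes
#' @return List with `never_present` flag, `gain_edge` (child node id of
#'   the gain stem, the MRCA of present leaves), `gain_signature`,
#'   `loss_edges` (integer child ids), `loss_signatures`, `n_events`
#'   (1 + number of losses).
#' @export
dollo_reconstruct <- function(tree, leaf_states) {
  states <- check_leaf_states(tree, leaf_states)
  if (anyNA(states)) abort("leaf states must be TRUE/FALSE with no NA")
  n_tip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  if (!any(states)) {
    return(list(never_present = TRUE, gain_edge = NA_integer_,
                gain_signature = NA_character_, loss_edges = integer(),
                loss_signatures = character(), n_events = 0L))
  }
  present_tips <- which(states)
  mrca <- if (length(present_tips) == 1L) present_tips else {
    ape::getMRCA(tree, tree$tip.label[present_tips])
  }
  absent <- all_absent_below(tree, states)
  pars <- parent_vec(tree)
  # maximal all-absent subtrees inside the gained subtree
  in_sub <- sets[[mrca]]
  nodes <- seq_len(n_tip + tree$Nnode)
  inside <- vapply(nodes, function(v) {
    v != mrca && all(sets[[v]] %in% in_sub)
  }, logical(1))
  loss <- which(inside & absent & vapply(nodes, function(v) {
    p <- pars[v]
    !is.na(p) && !absent[p]
  }, logical(1)))
  list(
    never_present = FALSE,
    gain_edge = mrca,
    gain_signature = edge_signature(tree, mrca, sets),
    loss_edges = loss,
    loss_signatures = vapply(loss, function(v) edge_signature(tree, v, sets), ""),
    n_events = 1L + length(loss)
  )
}

#' Build a gain/loss/HGT event scenario for a set of traits
#'
#' For each trait the presence of leaves flagged as horizontally acquired
#' is first recoded to absent (the vertical copy is genuinely missing
#' there), a Dollo reconstruction is run on the recoded states, and then an
#' `hgt_gain` event carrying the donor group is placed on the stem edge of
#' each maximal recoded clade. If the recoded set is not monophyletic on
#' the species tree, events are placed per maximal sub-clade with a
#' warning. Replaying the events from the root reproduces every observed
#' (pre-recoding) leaf state.
#'
#' @param tree Rooted species tree (`phylo`).
#' @param traits A list of trait profiles; each element is a list with
#'   `trait_id`, `leaf_states` (named logical over tips) and optionally
#'   `hgt_recode`, a tibble/data.frame with columns `species` and `donor`.
#' @return An object of class `"pt_scenario"`: list with `tree`, `events`
#'   (tibble: `trait_id`, `edge_child`, `edge_signature`, `event`,
#'   `donor`), and `counts` (tibble: `trait_id`, `n_gain`, `n_loss`,
#'   `n_hgt`, `n_events`, `fitch_changes`, `never_present`).
#' @export
build_scenario <- function(tree, traits) {
  sets <- node_tip_sets(tree)
  pars <- parent_vec(tree)
  n_tip <- length(tree$tip.label)
  events <- list()
  counts <- list()

  for (tr in traits) {
    id <- tr$trait_id
    states <- check_leaf_states(tree, tr$leaf_states)
    recode <- tr$hgt_recode
    if (!is.null(recode) && nrow(recode)) {
      bad <- setdiff(recode$species, tree$tip.label[states])
      if (length(bad)) {
        abort(paste0("trait ", id, ": hgt_recode species not present at the leaves: ",
                     paste(bad, collapse = ", ")))
      }
    }
    recoded <- states
    ev <- tibble(trait_id = character(), edge_child = integer(),
                 edge_signature = character(), event = character(),
                 donor = character())
    if (!is.null(recode) && nrow(recode)) {
      recoded[match(recode$species, tree$tip.label)] <- FALSE
      for (dn in unique(recode$donor)) {
        grp <- recode$species[recode$donor == dn]
        grp_idx <- match(grp, tree$tip.label)
        # maximal subtrees whose leaves all belong to this recode set
        nodes <- seq_len(n_tip + tree$Nnode)
        in_grp <- vapply(nodes, function(v) all(sets[[v]] %in% grp_idx), logical(1))
        maximal <- which(in_grp & vapply(nodes, function(v) {
          p <- pars[v]
          is.na(p) || !in_grp[p]
        }, logical(1)))
        if (length(maximal) > 1L) {
          warn(paste0("trait ", id, ": horizontally acquired set from donor ", dn,
                      " is not monophyletic; placing ", length(maximal),
                      " separate hgt_gain events"))
        }
        for (v in maximal) {
          ev <- bind_rows(ev, tibble(
            trait_id = id, edge_child = v,
            edge_signature = edge_signature(tree, v, sets),
            event = "hgt_gain", donor = dn
          ))
        }
      }
    }
    dollo <- dollo_reconstruct(tree, setNames(recoded, tree$tip.label))
    if (!dollo$never_present) {
      ev <- bind_rows(
        tibble(trait_id = id, edge_child = dollo$gain_edge,
               edge_signature = dollo$gain_signature, event = "gain",
               donor = NA_character_),
        tibble(trait_id = id, edge_child = dollo$loss_edges,
               edge_signature = dollo$loss_signatures, event = "loss",
               donor = NA_character_),
        ev
      )
    }
    fitch <- fitch_min_changes(tree, setNames(states, tree$tip.label))
    events[[id]] <- ev
    counts[[id]] <- tibble(
      trait_id = id,
      n_gain = sum(ev$event == "gain"),
      n_loss = sum(ev$event == "loss"),
      n_hgt = sum(ev$event == "hgt_gain"),
      n_events = nrow(ev),
      fitch_changes = fitch$min_changes,
      never_present = dollo$never_present
    )
  }
  out <- list(tree = tree, events = bind_rows(events), counts = bind_rows(counts))
  class(out) <- "pt_scenario"
  out
}

#' @export
print.pt_scenario <- function(x, ...) {
  cat("<pt_scenario> ", nrow(x$counts), " trait(s), ",
      nrow(x$events), " event(s) on a ", length(x$tree$tip.label),
      "-leaf species tree\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @method tidy pt_scenario
#' @export
tidy.pt_scenario <- function(x, ...) x$events

#' @method glance pt_scenario
#' @export
glance.pt_scenario <- function(x, ...) {
  tibble(
    n_traits = nrow(x$counts),
    n_gain = sum(x$counts$n_gain),
    n_loss = sum(x$counts$n_loss),
    n_hgt = sum(x$counts$n_hgt),
    n_events = sum(x$counts$n_events)
  )
}

# nodes on the path from the root to `node`, inclusive; each entry is the
# child node of an edge that gets replayed.
path_from_root <- function(tree, node) {
  pars <- parent_vec(tree)
  path <- integer()
  v <- node
  while (!is.na(v)) {
    path <- c(v, path)
    v <- pars[v]
  }
  path
}

resolve_node <- function(tree, node) {
  n_all <- length(tree$tip.label) + tree$Nnode
  if (is.numeric(node)) {
    if (node < 1 || node > n_all) abort(paste0("unknown node id: ", node))
    return(as.integer(node))
  }
  if (is.character(node) && length(node) == 1 && node %in% tree$tip.label) {
    return(match(node, tree$tip.label))
  }
  if (is.character(node) && all(node %in% tree$tip.label)) {
    if (length(node) == 1) return(match(node, tree$tip.label))
    return(ape::getMRCA(tree, node))
  }
  abort(paste0("unknown node: ", paste(node, collapse = ", ")))
}

#' Reconstructed trait states at an ancestral node
#'
#' Replays the scenario's events from the root down to `node` (inclusive
#' of the node's own stem edge; events on one edge replay in the order
#' gain, loss, hgt_gain) and reports the resulting presence/absence of
#' every trait at that node.
#'
#' @param scenario A `"pt_scenario"` from [build_scenario()].
#' @param node A node id, a tip label, or a character vector of tip labels
#'   (their MRCA is used).
#' @return Tibble: `trait_id`, `present`, `via_hgt` (whether the state was
#'   last turned on by a transfer on the path).
#' @export
ancestor_report <- function(scenario, node) {
  tree <- scenario$tree
  nd <- resolve_node(tree, node)
  path <- path_from_root(tree, nd)
  ev_rank <- c(gain = 1L, loss = 2L, hgt_gain = 3L)
  purrr::map_dfr(unique(scenario$counts$trait_id), function(id) {
    ev <- scenario$events[scenario$events$trait_id == id, ]
    state <- FALSE
    via_hgt <- FALSE
    for (v in path) {
      here <- ev[ev$edge_child == v, ]
      if (!nrow(here)) next
      here <- here[order(ev_rank[here$event]), ]
      for (k in seq_len(nrow(here))) {
        state <- switch(here$event[k], gain = TRUE, loss = FALSE, hgt_gain = TRUE)
        via_hgt <- here$event[k] == "hgt_gain"
      }
    }
    tibble(trait_id = id, present = state, via_hgt = state && via_hgt)
  })
}

#' Write scenario artifacts
#'
#' Writes the per-edge event table as TSV, a per-node ancestor report, and
#' an annotated Newick whose internal-node labels carry per-node total
#' event counts (events on the node's stem, summed over traits).
#'
#' @param scenario A `"pt_scenario"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(scenario$events, file.path(dir, "scenario_events.tsv"), progress = FALSE)
  tree <- scenario$tree
  n_tip <- length(tree$tip.label)
  nodes <- seq_len(n_tip + tree$Nnode)
  report <- purrr::map_dfr(nodes, function(v) {
    r <- ancestor_report(scenario, v)
    r$node <- v
    r$node_label <- if (v <= n_tip) tree$tip.label[v] else paste0("node", v)
    r[c("node", "node_label", "trait_id", "present", "via_hgt")]
  })
  readr::write_tsv(report, file.path(dir, "ancestor_states.tsv"), progress = FALSE)
  counts <- vapply((n_tip + 1):(n_tip + tree$Nnode), function(v) {
    sum(scenario$events$edge_child == v)
  }, 1L)
  annotated <- tree
  annotated$node.label <- paste0("events_", counts)
  write_newick(annotated, file.path(dir, "species_tree_annotated.nwk"))
  invisible(dir)
}
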