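# Tip sets below every node, computed by one postorder sweep over the edge
# matrix; index i of the returned list holds the tip indices of node i.
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  }
  sets
}

root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
}

parent_vec <- function(tree) {
  p <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# Every bipartition side of the tree: for each edge, the tip set below the
# child and its complement, with the child node's label as the edge support
# for both orientations. In a rooted tree the two root-child edges are the
# same unrooted edge but may carry different labels; sides are therefore
# deduplicated by tip set keeping the minimum support, which is the
# conservative choice (a call is never made on the more optimistic label).
tree_sides <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  sup <- tree_supports(tree)
  all_tips <- seq_len(n_tip)
  children <- tree$edge[, 2]
  sides <- vector("list", 2L * length(children))
  j <- 0L
  for (ch in children) {
    below <- sets[[ch]]
    s <- if (ch > n_tip) sup[ch - n_tip] else NA_integer_
    j <- j + 1L
    sides[[j]] <- list(tips = below, support = s, node = ch, orient = "below")
    j <- j + 1L
    sides[[j]] <- list(tips = setdiff(all_tips, below), support = s, node = ch,
                       orient = "above")
  }
  keys <- vapply(sides, function(s) paste(sort(s$tips), collapse = ","), "")
  out <- list()
  for (j in seq_along(sides)) {
    k <- keys[j]
    prev <- out[[k]]
    if (is.null(prev)) {
      out[[k]] <- sides[[j]]
    } else {
      s_old <- prev$support
      s_new <- sides[[j]]$support
      if (is.na(s_old) || (!is.na(s_new) && s_new < s_old)) {
        out[[k]] <- sides[[j]]
      }
    }
  }
  unname(out)
}

#' Prune long-branch leaves from a gene tree
#'
#' Removes every leaf whose pendant branch is strictly longer than
#' `long_branch_cutoff` substitutions per site, then suppresses the
#' resulting degree-2 nodes with branch lengths summed (via
#' [ape::drop.tip()]). Applied once, not iteratively, and only to pendant
#' branches; long internal branches are reported in the `long_internal`
#' attribute but never pruned.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param t A [thresholds()] object.
#' @return List with `tree` (pruned) and `removed` (character vector of
#'   pruned leaf labels).
#' @export
prune_long_branches <- function(tree, t = thresholds()) {
  t <- as_thresholds(t)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths; cannot prune long branches")
  n_tip <- length(tree$tip.label)
  pendant <- tree$edge[, 2] <= n_tip
  long <- tree$edge.length > t$long_branch_cutoff
  drop <- tree$tip.label[tree$edge[pendant & long, 2]]
  long_internal <- sum(!pendant & long)
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  structure(list(tree = out, removed = drop), long_internal = long_internal)
}

#' Test monophyly of a focal leaf set
#'
#' A focal set is monophyletic iff some edge's bipartition separates
#' exactly the focal leaves from the rest -- a formulation that needs no
#' root and is invariant under re-rooting. The verdict also reports the
#' largest clade (over all bipartition sides) containing only focal
#' leaves, together with that edge's bootstrap support.
#'
#' @param tree A `phylo` object.
#' @param focal_leaves Character vector of leaf labels (non-empty, all
#'   present in the tree).
#' @return An object of class `"pt_monophyly"`: list with `focal_leaves`,
#'   `status` (`"monophyletic"` / `"non-monophyletic"`),
#'   `largest_focal_clade` (leaf labels) and `clade_support`.
#' @export
test_monophyly <- function(tree, focal_leaves) {
  if (!length(focal_leaves)) abort("focal_leaves must be non-empty")
  miss <- setdiff(focal_leaves, tree$tip.label)
  if (length(miss)) abort(paste0("focal leaves not in tree: ", paste(miss, collapse = ", ")))
  n_tip <- length(tree$tip.label)
  focal_idx <- match(focal_leaves, tree$tip.label)

  if (length(focal_idx) == n_tip) {
    res <- list(focal_leaves = focal_leaves, status = "monophyletic",
                largest_focal_clade = focal_leaves, clade_support = NA_integer_)
    class(res) <- "pt_monophyly"
    return(res)
  }

  best <- focal_idx[1]
  best_sup <- NA_integer_
  for (s in tree_sides(tree)) {
    if (all(s$tips %in% focal_idx) && length(s$tips) > length(best)) {
      best <- s$tips
      best_sup <- s$support
    }
  }
  status <- if (length(best) == length(focal_idx)) "monophyletic" else "non-monophyletic"
  res <- list(
    focal_leaves = focal_leaves,
    status = status,
    largest_focal_clade = tree$tip.label[best],
    clade_support = best_sup
  )
  class(res) <- "pt_monophyly"
  res
}

#' @export
print.pt_monophyly <- function(x, ...) {
  cat("<pt_monophyly> ", x$status, "\n",
      "  focal: ", length(x$focal_leaves), " leaves; largest focal clade: ",
      length(x$largest_focal_clade), " leaves (support ",
      ifelse(is.na(x$clade_support), "none", x$clade_support), ")\n", sep = "")
  invisible(x)
}

#' @method tidy pt_monophyly
#' @export
tidy.pt_monophyly <- function(x, ...) {
  tibble(
    status = x$status,
    n_focal = length(x$focal_leaves),
    largest_clade_size = length(x$largest_focal_clade),
    clade_support = x$clade_support
  )
}

#' Split a focal leaf set into its maximal focal clades
#'
#' Finds the minimal set of maximal bipartition sides whose leaves are all
#' focal (these are pairwise disjoint and cover the focal set), reports
#' each with the support of its defining edge, and flags clades whose
#' support reaches `group_support_min` as "distinct groups". Groups are
#' numbered 1, 2, ... by decreasing size.
#'
#' @inheritParams test_monophyly
#' @param t A [thresholds()] object.
#' @return Tibble: `group`, `leaves` (list-column), `size`, `support`,
#'   `distinct` (logical).
#' @export
split_focal_groups <- function(tree, focal_leaves, t = thresholds()) {
  t <- as_thresholds(t)
  miss <- setdiff(focal_leaves, tree$tip.label)
  if (length(miss)) abort(paste0("focal leaves not in tree: ", paste(miss, collapse = ", ")))
  n_tip <- length(tree$tip.label)
  focal_idx <- match(focal_leaves, tree$tip.label)

  if (length(focal_idx) == n_tip) {
    return(tibble(group = 1L, leaves = list(sort(focal_leaves)),
                  size = length(focal_leaves), support = NA_integer_,
                  distinct = FALSE))
  }
  cand <- Filter(function(s) all(s$tips %in% focal_idx), tree_sides(tree))
  # singletons as fallback sides so every focal leaf belongs to some group
  for (i in focal_idx) {
    cand <- c(cand, list(list(tips = i, support = NA_integer_)))
  }
  keys <- vapply(cand, function(s) paste(sort(s$tips), collapse = ","), "")
  cand <- cand[!duplicated(keys)]
  sizes <- vapply(cand, function(s) length(s$tips), 1L)
  maximal <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && sizes[j] > sizes[i] && all(cand[[i]]$tips %in% cand[[j]]$tips)
    }, logical(1)))
  }, logical(1))
  groups <- cand[maximal]
  ord <- order(-vapply(groups, function(s) length(s$tips), 1L),
               vapply(groups, function(s) min(s$tips), 1L))
  groups <- groups[ord]
  tibble(
    group = seq_along(groups),
    leaves = lapply(groups, function(s) sort(tree$tip.label[s$tips])),
    size = vapply(groups, function(s) length(s$tips), 1L),
    support = vapply(groups, function(s) s$support %||% NA_integer_, NA_integer_),
    distinct = vapply(groups, function(s) {
      !is.na(s$support) && s$support >= t$group_support_min
    }, logical(1))
  )
}

#' Classify focal sequences as vertical or horizontally acquired
#'
#' Operationalizes the gene-tree/species-tree conflict criterion: a focal
#' sequence is called horizontally acquired when it nests, with strong
#' support, inside a distantly related (non-focal) part of the gene tree.
#' Concretely, focal leaves inside the largest all-focal clade are
#' `vertical`; any other focal leaf is examined through the smallest
#' bipartition side that contains it together with at least one non-focal
#' leaf. If that side's support reaches `hgt_support_min` and a single
#' foreign group holds a strict majority (fraction > `hgt_majority`) of
#' its non-focal leaves, the verdict is `hgt_candidate` with that group as
#' donor; in every other case -- insufficient support or no majority donor
#' -- the verdict is `unresolved`, never silently `vertical`.
#'
#' @inheritParams test_monophyly
#' @param group_map Named character vector mapping every leaf label to its
#'   group label (focal clades A--E or a foreign group).
#' @param t A [thresholds()] object.
#' @return Tibble with one row per focal leaf: `sequence_id`,
#'   `recipient_group`, `donor_group`, `nest_support`, `verdict`.
#' @export
classify_hgt <- function(tree, focal_leaves, group_map, t = thresholds()) {
  t <- as_thresholds(t)
  unmapped <- setdiff(tree$tip.label, names(group_map))
  if (length(unmapped)) {
    abort(paste0("leaves missing from group_map: ", paste(unmapped, collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  focal_idx <- match(focal_leaves, tree$tip.label)
  mono <- test_monophyly(tree, focal_leaves)
  vertical_set <- match(mono$largest_focal_clade, tree$tip.label)

  sides <- Filter(function(s) any(!(s$tips %in% focal_idx)), tree_sides(tree))
  side_sizes <- vapply(sides, function(s) length(s$tips), 1L)

  purrr::map_dfr(focal_idx, function(f) {
    leaf <- tree$tip.label[f]
    rec <- unname(group_map[[leaf]])
    if (f %in% vertical_set) {
      return(tibble(sequence_id = leaf, recipient_group = rec,
                    donor_group = NA_character_, nest_support = NA_integer_,
                    verdict = "vertical"))
    }
    holds <- vapply(sides, function(s) f %in% s$tips, logical(1))
    if (!any(holds)) {
      return(tibble(sequence_id = leaf, recipient_group = rec,
                    donor_group = NA_character_, nest_support = NA_integer_,
                    verdict = "unresolved"))
    }
    smallest <- which(holds)[which.min(side_sizes[holds])]
    s <- sides[[smallest]]
    nonfocal <- setdiff(s$tips, focal_idx)
    grp <- unname(group_map[tree$tip.label[nonfocal]])
    tab <- sort(table(grp), decreasing = TRUE)
    has_majority <- length(tab) > 0 && tab[1] > t$hgt_majority * length(grp)
    supported <- !is.na(s$support) && s$support >= t$hgt_support_min
    if (supported && has_majority) {
      tibble(sequence_id = leaf, recipient_group = rec,
             donor_group = names(tab)[1], nest_support = s$support,
             verdict = "hgt_candidate")
    } else {
      tibble(sequence_id = leaf, recipient_group = rec,
             donor_group = NA_character_,
             nest_support = s$support %||% NA_integer_,
             verdict = "unresolved")
    }
  })
}
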