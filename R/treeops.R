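# Bipartition algebra over unrooted trees: canonical splits, clade
# support counting across tree collections, Robinson-Foulds distance.

# Canonical key of a split: the side NOT containing the alphabetically
# smallest taxon of the roster, sorted and collapsed with a separator
# that cannot occur in labels. A split and its complement share the key.
canonical_split_key <- function(side, roster) {
  ref <- min(roster)
  if (ref %in% side) side <- setdiff(roster, side)
  paste(sort(side), collapse = "\x1f")
}

#' Bipartitions induced by the internal edges of a tree
#'
#' One bipartition per internal edge; a binary unrooted tree on n taxa
#' yields n - 3. Multifurcating trees simply contribute fewer. Rooted
#' trees are unrooted first (the root edge would otherwise duplicate a
#' split).
#'
#' @param tree A `phylo` with >= 4 tips.
#' @return Object of class `bipartition_set`: list with `keys` (canonical
#'   split keys), `sides` (taxon vectors, canonical side), `taxa`
#'   (roster).
#' @export
bipartition_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("bipartitions require at least 4 taxa")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  roster <- tree$tip.label
  tree <- stats::reorder(tree, "postorder")
  E <- tree$edge
  M <- ntip + tree$Nnode
  below <- vector("list", M)
  for (i in seq_len(ntip)) below[[i]] <- roster[i]
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]; ch <- E[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- E[nrow(E), 1]
  internal_child <- E[, 2] > ntip
  sides <- lapply(which(internal_child), function(e) below[[E[e, 2]]])
  sides <- sides[vapply(sides, length, integer(1)) >= 2 &
                 vapply(sides, length, integer(1)) <= ntip - 2]
  keys <- vapply(sides, canonical_split_key, character(1), roster = roster)
  keep <- !duplicated(keys)
  structure(list(keys = keys[keep],
                 sides = lapply(sides[keep], sort),
                 taxa = sort(roster)),
            class = "bipartition_set")
}

#' @export
print.bipartition_set <- function(x, ...) {
  cat(sprintf("Bipartition set: %d splits over %d taxa\n",
              length(x$keys), length(x$taxa)))
  invisible(x)
}

#' Bootstrap-style clade support across a collection of trees
#'
#' Counts the percentage of trees whose bipartition set contains the
#' split separating `clade` from the remaining taxa. With `restrict`,
#' both the trees and the clade are first restricted to that taxon
#' subset (the usual convention when comparing taxon-deletion schemes).
#' Support is complement-invariant.
#'
#' @param trees List of `phylo` trees (or a `multiPhylo`).
#' @param clade Character vector of taxon labels.
#' @param restrict Optional character vector; evaluation is performed on
#'   the intersection of each tree's tips with this set.
#' @return Support percentage in [0, 100].
#' @export
clade_support <- function(trees, clade, restrict = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  hits <- vapply(trees, function(tr) {
    taxa <- tr$tip.label
    if (!is.null(restrict)) taxa <- intersect(taxa, restrict)
    cl <- intersect(clade, taxa)
    comp <- setdiff(taxa, cl)
    if (length(cl) < 2 || length(comp) < 2)
      stop("clade and its complement must each have >= 2 taxa after restriction")
    if (length(taxa) < length(tr$tip.label))
      tr <- ape::keep.tip(tr, taxa)
    key <- canonical_split_key(cl, taxa)
    key %in% bipartition_set(tr)$keys
  }, logical(1))
  100 * mean(hits)
}

#' Robinson-Foulds distance
#'
#' Cardinality of the symmetric difference between the bipartition sets
#' of two trees on the same leaf set.
#'
#' @param t1,t2 `phylo` trees with identical leaf sets.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  k1 <- bipartition_set(t1)$keys
  k2 <- bipartition_set(t2)$keys
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Is a clade (as a subset of `taxa`) compatible with a split given by
# `side`? Incompatible iff all four pairwise intersections are nonempty.
split_conflicts_clade <- function(side, clade, taxa) {
  a <- intersect(side, clade)
  b <- setdiff(side, clade)
  cs <- setdiff(clade, side)
  d <- setdiff(setdiff(taxa, side), clade)
  length(a) > 0 && length(b) > 0 && length(cs) > 0 && length(d) > 0
}
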