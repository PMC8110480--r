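## shared tree helpers (ape 'phylo' is the tree representation throughout)

## all descendant node ids of `node` (tips and internal), excluding `node`
.descendants <- function(tree, node) {
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- edge[edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ape::Ntip(tree)])
  }
  out
}

## parent node id, or NA for the root
.parent_node <- function(tree, node) {
  i <- match(node, tree$edge[, 2])
  if (is.na(i)) NA_integer_ else tree$edge[i, 1]
}

#' MRCA node of the focal clade, with a monophyly check
#'
#' @param tree an `ape::phylo`.
#' @param partition a [LineagePartition-class].
#' @return The MRCA node id of the focal taxa. Errors if the focal set is
#'   not monophyletic on the tree (lineage-specific validation is undefined
#'   in that case) or if focal taxa are missing from the tree.
#' @export
focalMrca <- function(tree, partition) {
  focal <- focalTaxa(partition)
  if (!all(focal %in% tree$tip.label))
    stop("focal taxa absent from tree: ",
         paste(setdiff(focal, tree$tip.label), collapse = ", "))
  if (!ape::is.monophyletic(tree, focal))
    stop("focal clade is not monophyletic on the tree")
  ape::getMRCA(tree, focal)
}

#' Foreground branches for a focal clade
#'
#' The foreground (appointed) branch set of the two-ratio branch model: all
#' branches inside the focal clade plus, optionally, the stem branch leading
#' to its MRCA.
#'
#' @param tree an `ape::phylo`.
#' @param partition a [LineagePartition-class].
#' @param includeStem include the branch leading into the focal MRCA
#'   (default TRUE).
#' @return Integer vector of child node ids identifying foreground edges
#'   (stable under edge reordering).
#' @export
foregroundEdges <- function(tree, partition, includeStem = TRUE) {
  mrca <- focalMrca(tree, partition)
  nodes <- .descendants(tree, mrca)
  if (includeStem) nodes <- c(mrca, nodes)
  sort(unique(nodes))
}
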