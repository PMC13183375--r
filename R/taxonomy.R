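# Taxonomy container: a rooted, branch-length-annotated tree (ape "phylo")
# whose internal node labels are clade (lineage) names. Lineage paths for a
# tip are the labels of its ancestors from the root down.

#' Build a taxonomy from a rooted tree
#'
#' @param tree An `ape::phylo` tree, rooted, with branch lengths in expected
#'   substitutions per site and unique tip labels. Internal nodes should be
#'   labelled with clade names; unlabelled internal nodes are auto-named
#'   `cladeN`.
#' @return An object of class `"taxonomy"`: the tree plus a `lineage` list
#'   mapping each tip to its ordered root-to-tip clade labels.
#' @export
taxonomy <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("taxonomy() expects an ape 'phylo' tree")
  if (is.null(tree$edge.length)) stopf("taxonomy tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stopf("branch lengths must be >= 0")
  if (anyDuplicated(tree$tip.label)) stopf("tip labels must be unique")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  if (is.null(tree$node.label) || !length(tree$node.label))
    tree$node.label <- paste0("clade", seq_len(n_node))
  blank <- !nzchar(tree$node.label) | is.na(tree$node.label)
  tree$node.label[blank] <- paste0("clade", which(blank))
  parent <- integer(n_tip + n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  lineage <- lapply(seq_len(n_tip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      node <- parent[node]
      path <- c(node, path)
    }
    tree$node.label[path - n_tip]
  })
  names(lineage) <- tree$tip.label
  structure(list(tree = tree, lineage = lineage), class = "taxonomy")
}

#' Toy taxonomy with named lineages
#'
#' A small fixed-topology taxonomy used by the synthetic pipeline: a rooted
#' bifurcating tree over `n_organisms` tips (the first tip is named
#' `"human"`), every branch of length `branch_length`, and internal nodes
#' labelled with nested clade names so lineage selection can be exercised.
#'
#' @param n_organisms Number of tips (>= 2).
#' @param branch_length Length of every branch, expected substitutions/site.
#' @return A `"taxonomy"` object.
#' @export
toy_taxonomy <- function(n_organisms = 8, branch_length = 0.3) {
  stopifnot(n_organisms >= 2)
  tree <- ape::stree(n_organisms, type = "balanced")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(branch_length, nrow(tree$edge))
  else tree$edge.length[] <- branch_length
  tree$tip.label <- c("human", sprintf("org%02d", seq_len(n_organisms - 1L)))
  tree$node.label <- c("Eukaryota",
                       paste0("clade", LETTERS[seq_len(tree$Nnode - 1L)]))
  taxonomy(tree)
}

#' Read / write a taxonomy as Newick
#'
#' Internal node labels carry the lineage (clade) names.
#'
#' @param path Newick file path.
#' @return `read_taxonomy()`: a `"taxonomy"`; `write_taxonomy()`: `path`,
#'   invisibly.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("taxonomy file not found: %s", path)
  taxonomy(ape::read.tree(path))
}

#' @rdname read_taxonomy
#' @param tax A `"taxonomy"` object.
#' @export
write_taxonomy <- function(tax, path) {
  ape::write.tree(tax$tree, file = path)
  invisible(path)
}

#' Organisms belonging to a lineage
#'
#' @param tax A `"taxonomy"`.
#' @param lineage A clade label appearing among the internal node labels.
#' @return Character vector of tip (organism) identifiers whose root-to-tip
#'   path passes through `lineage`.
#' @export
lineage_organisms <- function(tax, lineage) {
  hit <- vapply(tax$lineage, function(p) lineage %in% p, logical(1))
  if (!any(hit)) stopf("lineage '%s' selects no organism", lineage)
  names(tax$lineage)[hit]
}
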