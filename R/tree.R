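# Species-tree helpers. Trees are ape "phylo" objects, rooted, with unique
# tip labels. Every branch is identified by the label of its child node:
# the tip label for terminal branches, the node label (auto-filled as
# "N<number>" when absent) for internal ones.

#' Ensure a rooted tree has labels on every internal node
#'
#' Missing or empty internal node labels are replaced by "N<node number>".
#'
#' @param tree an [ape::phylo] object, rooted.
#' @return the tree with complete `node.label`.
#' @export
label_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tree tip labels must be unique", call. = FALSE)
  }
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  fill <- which(is.na(nl) | nl == "")
  nl[fill] <- paste0("N", ape::Ntip(tree) + fill)
  if (anyDuplicated(c(tree$tip.label, nl))) {
    stop("branch labels (tips + node labels) must be unique", call. = FALSE)
  }
  tree$node.label <- nl
  tree
}

#' Branch identifiers of a rooted tree
#'
#' One id per edge, the label of the edge's child node.
#'
#' @param tree a labelled rooted tree (see [label_nodes()]).
#' @return character vector parallel to `tree$edge` rows.
#' @export
branch_ids <- function(tree) {
  tree <- label_nodes(tree)
  .node_label(tree, tree$edge[, 2L])
}

#' @noRd
.node_label <- function(tree, node) {
  c(tree$tip.label, tree$node.label)[node]
}

#' @noRd
.node_of_branch <- function(tree, branch_id) {
  all_lab <- c(tree$tip.label, tree$node.label)
  idx <- match(branch_id, all_lab)
  if (is.na(idx)) stop("branch '", branch_id, "' not found in tree",
                       call. = FALSE)
  idx
}

#' Tip labels subtended by a branch
#'
#' @param tree labelled rooted tree.
#' @param branch_id a branch identifier (child-node label).
#' @return character vector of tip labels of the clade below the branch.
#' @export
clade_tips <- function(tree, branch_id) {
  tree <- label_nodes(tree)
  node <- .node_of_branch(tree, branch_id)
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  # iterative descent over the edge table
  desc <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    desc <- c(desc, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[sort(desc)]
}

#' @noRd
.children <- function(tree, node) tree$edge[tree$edge[, 1L] == node, 2L]

#' @noRd
.parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (length(p)) p else NA_integer_
}

#' Local quartet groupings around an internal branch
#'
#' For the branch above internal node N with children clades X and Y and
#' sister clade S, the concordant grouping is X+Y; the two discordant
#' alternatives produced by incomplete lineage sorting across the branch are
#' X+S and Y+S. Returns NULL when the branch is terminal or has no sister
#' (child of a unifurcating root).
#'
#' @param tree labelled rooted tree.
#' @param branch_id internal branch identifier.
#' @return NULL, or a list with tip-label vectors `concordant`, `alt1`,
#'   `alt2`.
#' @export
quartet_alternatives <- function(tree, branch_id) {
  tree <- label_nodes(tree)
  node <- .node_of_branch(tree, branch_id)
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(NULL)
  kids <- .children(tree, node)
  if (length(kids) != 2L) return(NULL)
  parent <- .parent(tree, node)
  if (is.na(parent)) return(NULL)
  sibs <- setdiff(.children(tree, parent), node)
  if (length(sibs) != 1L) return(NULL)
  x <- clade_tips(tree, .node_label(tree, kids[1L]))
  y <- clade_tips(tree, .node_label(tree, kids[2L]))
  s <- clade_tips(tree, .node_label(tree, sibs))
  list(concordant = sort(c(x, y)), alt1 = sort(c(x, s)), alt2 = sort(c(y, s)))
}
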