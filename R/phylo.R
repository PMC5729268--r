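# Presence/absence matrix, Dollo-consistent marker mapping, and branch
# support under a hard-polytomy null. A retroposon insertion is gained once
# and never precisely regained, so the presence taxa of a concordant marker
# must form a clade; markers whose presence set is not a clade are reported
# as conflicts (incomplete lineage sorting or, rarely, homoplasy) and never
# resolved automatically.

#' Build a presence/absence matrix from validated marker records
#'
#' One column per valid marker; invalid or uninformative markers are
#' excluded and recorded in the `excluded` attribute.
#'
#' @param records list of [validate_marker()] results.
#' @return character matrix of class `pa_matrix` (taxa rows x marker
#'   columns) over {"1", "0", "?"}.
#' @export
build_matrix <- function(records) {
  stopifnot(is.list(records), length(records) >= 1L)
  ids <- vapply(records, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) {
    stop("duplicate locus_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  excluded <- data.frame(locus_id = character(0), reason = character(0))
  cols <- list()
  classes <- character(0)
  taxa <- character(0)
  for (rec in records) {
    if (!rec$valid) {
      excluded <- rbind(excluded,
                        data.frame(locus_id = rec$locus_id,
                                   reason = paste(rec$failure_reasons,
                                                  collapse = ";")))
      next
    }
    st <- vapply(rec$calls, `[[`, character(1), "state")
    names(st) <- vapply(rec$calls, `[[`, character(1), "taxon")
    col <- c(present = "1", absent = "0", ambiguous = "?")[st]
    names(col) <- names(st)
    cols[[rec$locus_id]] <- col
    classes[rec$locus_id] <- rec$re_class
    taxa <- union(taxa, names(col))
  }
  if (!length(cols)) stop("no valid markers", call. = FALSE)
  m <- matrix("?", nrow = length(taxa), ncol = length(cols),
              dimnames = list(taxa, names(cols)))
  for (id in names(cols)) m[names(cols[[id]]), id] <- cols[[id]]
  structure(m, class = c("pa_matrix", "matrix", "array"),
            re_class = classes, excluded = excluded)
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("Presence/absence matrix: ", nrow(x), " taxa x ", ncol(x),
      " markers\n", sep = "")
  excl <- attr(x, "excluded")
  if (!is.null(excl) && nrow(excl)) {
    cat("  (", nrow(excl), " invalid marker(s) excluded)\n", sep = "")
  }
  print(unclass(x)[, seq_len(min(ncol(x), 10L)), drop = FALSE], quote = FALSE)
  if (ncol(x) > 10L) cat("  ... ", ncol(x) - 10L, " more columns\n", sep = "")
  invisible(x)
}

#' Map presence/absence markers onto a rooted species tree
#'
#' A marker maps to branch b when its presence taxa equal the clade of b
#' restricted to the marker's scored (non-?) taxa and none of its absence
#' taxa fall inside the clade. When "?" entries leave several nested
#' branches compatible, all are listed and the most recent (smallest clade)
#' is reported as the supported branch. A marker compatible with no branch
#' violates Dollo consistency and is flagged as a conflict.
#'
#' @param matrix a [build_matrix()] result (or character matrix over
#'   {"1","0","?"} with taxa rownames and marker colnames).
#' @param tree rooted [ape::phylo]; matrix taxa must be among its tips.
#' @return data.frame: `marker_id`, `supported_branch`, `conflict`,
#'   `compatible_branches` (";"-joined).
#' @export
map_markers <- function(matrix, tree) {
  stopifnot(is.matrix(matrix))
  tree <- label_nodes(tree)
  missing <- setdiff(rownames(matrix), tree$tip.label)
  if (length(missing)) {
    stop("taxa in matrix absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bids <- branch_ids(tree)
  clades <- lapply(bids, function(b) clade_tips(tree, b))
  names(clades) <- bids
  sizes <- lengths(clades)
  out <- lapply(colnames(matrix), function(id) {
    col <- matrix[, id]
    p <- rownames(matrix)[col == "1"]
    a <- rownames(matrix)[col == "0"]
    scored <- c(p, a)
    compatible <- bids[vapply(bids, function(b) {
      k <- clades[[b]]
      setequal(p, intersect(k, scored)) && !any(a %in% k)
    }, logical(1))]
    if (length(p) == 0L) compatible <- character(0)
    if (length(compatible)) {
      supported <- compatible[which.min(sizes[compatible])]
      data.frame(marker_id = id, supported_branch = supported,
                 conflict = FALSE,
                 compatible_branches = paste(compatible, collapse = ";"))
    } else {
      data.frame(marker_id = id, supported_branch = NA_character_,
                 conflict = TRUE, compatible_branches = "")
    }
  })
  do.call(rbind, out)
}

#' Exact polytomy test for retroposon branch support
#'
#' Under a hard-polytomy null every marker falls on one of the three
#' resolutions of a quartet with equal probability 1/3. The p-value is the
#' exact binomial tail P(X >= n1) with X ~ Binomial(n1+n2+n3, 1/3): the
#' probability of at least the observed support for the focal resolution.
#'
#' @param n1 markers supporting the branch.
#' @param n2,n3 markers supporting the two alternative quartet resolutions.
#' @return object of class `branch_support` with fields `n_support`,
#'   `n_conflict_a`, `n_conflict_b`, `p_value`.
#' @export
#' @examples
#' branch_support_test(3, 0, 0)$p_value  # 1/27
branch_support_test <- function(n1, n2, n3) {
  counts <- c(n1, n2, n3)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- n1 + n2 + n3
  p <- if (n1 == 0) 1 else sum(stats::dbinom(n1:n, n, 1 / 3))
  structure(list(n_support = n1, n_conflict_a = n2, n_conflict_b = n3,
                 p_value = min(1, p)),
            class = "branch_support")
}

#' @export
print.branch_support <- function(x, ...) {
  cat("Markers ", x$n_support, "/", x$n_conflict_a, "/", x$n_conflict_b,
      "; polytomy-null p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Marker support counts for every internal branch of a tree
#'
#' For each internal branch with a local quartet, counts markers whose
#' scored presence set matches the branch's clade (n1) or one of the two
#' alternative resolutions (n2, n3), and applies [branch_support_test()].
#'
#' @inheritParams map_markers
#' @return data.frame: `branch`, `n_support`, `n_conflict_a`,
#'   `n_conflict_b`, `p_value`.
#' @export
branch_support_table <- function(matrix, tree) {
  tree <- label_nodes(tree)
  bids <- branch_ids(tree)
  internal <- bids[vapply(bids, function(b) {
    !is.null(quartet_alternatives(tree, b))
  }, logical(1))]
  matches_set <- function(col, target) {
    p <- rownames(matrix)[col == "1"]
    a <- rownames(matrix)[col == "0"]
    length(p) > 0L &&
      setequal(p, intersect(target, c(p, a))) && !any(a %in% target)
  }
  out <- lapply(internal, function(b) {
    alt <- quartet_alternatives(tree, b)
    n <- vapply(list(alt$concordant, alt$alt1, alt$alt2), function(set) {
      sum(apply(matrix, 2L, matches_set, target = set))
    }, numeric(1))
    bs <- branch_support_test(n[1L], n[2L], n[3L])
    data.frame(branch = b, n_support = bs$n_support,
               n_conflict_a = bs$n_conflict_a, n_conflict_b = bs$n_conflict_b,
               p_value = bs$p_value)
  })
  do.call(rbind, out)
}

#' Annotate a tree's internal branches with marker support counts
#'
#' Replaces internal node labels by "n1/n2/n3" strings suitable for newick
#' export.
#'
#' @inheritParams map_markers
#' @return the tree with support-count node labels.
#' @export
annotate_tree_support <- function(tree, matrix) {
  tree <- label_nodes(tree)
  supp <- branch_support_table(matrix, tree)
  lab <- tree$node.label
  for (i in seq_len(nrow(supp))) {
    node <- .node_of_branch(tree, supp$branch[i]) - ape::Ntip(tree)
    lab[node] <- sprintf("%d/%d/%d", supp$n_support[i],
                         supp$n_conflict_a[i], supp$n_conflict_b[i])
  }
  tree$node.label <- lab
  tree
}
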