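# File interfaces. Sequences travel as FASTA (via Biostrings), trees as
# newick (via ape), tables as TSV. All coordinates in files are 0-based
# half-open alignment columns; every sidecar header says so.

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a simulated or curated locus set to a directory
#'
#' One aligned FASTA per locus plus a `spans.tsv` sidecar (locus_id, file,
#' ref_taxon, element_start, element_end; 0-based half-open alignment
#' columns) and, when truth records are given, a `truth.tsv` table.
#'
#' @param loci list of [locus_alignment()] objects.
#' @param dir output directory (created if needed).
#' @param truth optional list of `sim_truth` records.
#' @return invisibly, the directory.
#' @export
write_locus_set <- function(loci, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spans <- do.call(rbind, lapply(loci, function(l) {
    file <- paste0(l$locus_id, ".fa")
    write_fasta(l$rows, file.path(dir, file))
    data.frame(locus_id = l$locus_id, file = file, ref_taxon = l$ref_taxon,
               element_start = l$element_span[1L],
               element_end = l$element_span[2L])
  }))
  utils::write.table(spans, file.path(dir, "spans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) write_truth_table(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a locus set written by [write_locus_set()]
#'
#' @param dir directory containing per-locus FASTA files and `spans.tsv`.
#' @return named list of [locus_alignment()] objects.
#' @export
read_locus_set <- function(dir) {
  spans <- utils::read.table(file.path(dir, "spans.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(spans)), function(i) {
    s <- spans[i, ]
    locus_alignment(s$locus_id, read_fasta(file.path(dir, s$file)),
                    element_span = c(s$element_start, s$element_end),
                    ref_taxon = s$ref_taxon)
  })
  stats::setNames(out, spans$locus_id)
}

#' Write simulation truth records as TSV
#'
#' Wide format: locus_id, insertion_branch, tsd_sequence, is_ils, then one
#' column per taxon with its true state.
#'
#' @param truth list of `sim_truth` records.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
write_truth_table <- function(truth, path) {
  taxa <- names(truth[[1L]]$per_taxon_state)
  df <- do.call(rbind, lapply(truth, function(tr) {
    cbind(data.frame(locus_id = tr$locus_id,
                     insertion_branch = tr$insertion_branch,
                     tsd_sequence = tr$tsd_sequence, is_ils = tr$is_ils),
          as.data.frame(as.list(tr$per_taxon_state)))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a presence/absence matrix as TSV (taxa rows, marker columns)
#' @param matrix a [build_matrix()] result.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(taxon = rownames(matrix),
                   unclass(matrix)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix TSV written by [write_matrix_tsv()]
#' @param path TSV file.
#' @return `pa_matrix` character matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, class = c("pa_matrix", "matrix", "array"))
}

#' Write a supermatrix as FASTA
#' @param x a [concatenate()] result.
#' @param path output FASTA.
#' @return invisibly, the path.
#' @export
write_supermatrix_fasta <- function(x, path) {
  stopifnot(inherits(x, "supermatrix"))
  write_fasta(x$rows, path)
}

#' Write a supermatrix as relaxed PHYLIP
#' @inheritParams write_supermatrix_fasta
#' @export
write_supermatrix_phylip <- function(x, path) {
  stopifnot(inherits(x, "supermatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(x$rows), nchar(x$rows[[1L]])), con)
  writeLines(paste(names(x$rows), x$rows), con)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One line per locus, `DNA, <locus> = <start>-<end>` with 1-based inclusive
#' coordinates (converted from the internal 0-based half-open spans).
#'
#' @inheritParams write_supermatrix_fasta
#' @export
write_partitions <- function(x, path) {
  stopifnot(inherits(x, "supermatrix"))
  p <- x$partitions
  writeLines(sprintf("DNA, %s = %d-%d", p$locus_id, p$start + 1L, p$end),
             path)
  invisible(path)
}

#' Write a tree annotated with branch support labels as newick
#'
#' @param tree an [annotate_tree_support()] result (or any phylo).
#' @param path output newick file.
#' @return invisibly, the path.
#' @export
write_annotated_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
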