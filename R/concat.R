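# Flank extraction and supermatrix concatenation: remove the element
# columns from each marker alignment (optionally also the reference taxon's
# target-site duplication) and concatenate the remaining flanks into a
# partitioned multilocus alignment for external tree inference.

#' Strip element columns from a marker locus
#'
#' Removes the annotated element columns; with `drop_tsd`, the columns of
#' the reference taxon's target-site duplicate (the direct-repeat copy
#' created 3' of the element at insertion) are removed as well. Row order
#' is preserved.
#'
#' @param locus a [locus_alignment()].
#' @param drop_tsd also remove the reference taxon's TSD-duplicate columns.
#' @param max_tsd,min_tsd TSD length bounds used when `drop_tsd` is TRUE.
#' @return object of class `flank_alignment`: `locus_id`, `rows` (named
#'   aligned strings).
#' @export
strip_elements <- function(locus, drop_tsd = FALSE, max_tsd = 20L,
                           min_tsd = 4L) {
  stopifnot(inherits(locus, "locus_alignment"))
  span <- locus$element_span
  width <- nchar(locus$rows[[1L]])
  drop <- seq(span[1L] + 1L, span[2L])
  if (drop_tsd) {
    ref_row <- locus$rows[[locus$ref_taxon]]
    u <- .ungapped_span(ref_row, span)
    tsd <- if (!is.null(u)) {
      suppressWarnings(detect_tsd(u$seq, u$start, u$end, max_len = max_tsd,
                                  min_len = min_tsd))
    }
    if (!is.null(tsd)) {
      # map ungapped positions of the 3' duplicate back to alignment columns
      chars <- .chars(ref_row)
      keep_mask <- !(chars %in% c("-", "?"))
      ungapped_of_col <- cumsum(keep_mask)
      dup_u <- seq(u$end + 1L, u$end + nchar(tsd))
      dup_cols <- which(keep_mask & ungapped_of_col %in% dup_u)
      drop <- sort(unique(c(drop, dup_cols)))
    }
  }
  if (length(drop) >= width) stop("no flanks: span covers whole alignment",
                                  call. = FALSE)
  keep <- setdiff(seq_len(width), drop)
  rows <- vapply(locus$rows, function(s) {
    .collapse(.chars(s)[keep])
  }, character(1))
  structure(list(locus_id = locus$locus_id, rows = rows),
            class = "flank_alignment")
}

#' Concatenate flank alignments into a partitioned supermatrix
#'
#' Loci are ordered by locus_id; taxa are the sorted union over loci, with
#' missing taxa padded by '?' (distinguishing missing data from indels).
#'
#' @param loci list of [strip_elements()] results (or any objects with
#'   `locus_id` and `rows`).
#' @return object of class `supermatrix`: `rows` (named strings),
#'   `partitions` data.frame (`locus_id`, `start`, `end`; 0-based
#'   half-open).
#' @export
concatenate <- function(loci) {
  stopifnot(is.list(loci), length(loci) >= 1L)
  ids <- vapply(loci, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) stop("duplicate locus_id", call. = FALSE)
  loci <- loci[order(ids)]
  ids <- sort(ids)
  taxa <- sort(unique(unlist(lapply(loci, function(l) names(l$rows)))))
  pieces <- matrix("", nrow = length(taxa), ncol = length(loci),
                   dimnames = list(taxa, ids))
  starts <- integer(length(loci)); ends <- integer(length(loci))
  pos <- 0L
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    w <- unique(nchar(l$rows))
    if (length(w) != 1L) stop("ragged rows in locus ", l$locus_id,
                              call. = FALSE)
    if (anyDuplicated(names(l$rows))) {
      dup <- names(l$rows)[duplicated(names(l$rows))][1L]
      if (length(unique(l$rows[names(l$rows) == dup])) > 1L) {
        stop("taxon '", dup, "' has conflicting sequences in locus ",
             l$locus_id, call. = FALSE)
      }
      l$rows <- l$rows[!duplicated(names(l$rows))]
    }
    fill <- stats::setNames(rep(strrep("?", w), length(taxa)), taxa)
    fill[names(l$rows)] <- unname(l$rows)
    pieces[, i] <- fill
    starts[i] <- pos; ends[i] <- pos + w; pos <- pos + w
  }
  rows <- stats::setNames(apply(pieces, 1L, paste, collapse = ""), taxa)
  structure(list(rows = rows,
                 partitions = data.frame(locus_id = ids, start = starts,
                                         end = ends)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix: ", length(x$rows), " taxa x ", nchar(x$rows[[1L]]),
      " columns in ", nrow(x$partitions), " partitions\n", sep = "")
  invisible(x)
}

#' Supermatrix width in alignment columns
#' @param x a `supermatrix`.
#' @return integer column count.
#' @export
supermatrix_width <- function(x) {
  stopifnot(inherits(x, "supermatrix"))
  nchar(x$rows[[1L]])
}

#' Slice a supermatrix back into its per-locus alignments
#'
#' @param x a `supermatrix`.
#' @return named list of `flank_alignment` objects (all taxa, including
#'   '?'-padded ones).
#' @export
split_supermatrix <- function(x) {
  stopifnot(inherits(x, "supermatrix"))
  out <- lapply(seq_len(nrow(x$partitions)), function(i) {
    p <- x$partitions[i, ]
    rows <- vapply(x$rows, substr, character(1), p$start + 1L, p$end)
    structure(list(locus_id = p$locus_id, rows = rows),
              class = "flank_alignment")
  })
  stats::setNames(out, x$partitions$locus_id)
}
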