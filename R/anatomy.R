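# SINE family anatomy: majority-rule consensus, chimeric head/tail
# partition against tRNA and CR1 reference libraries, diagnostic sites
# distinguishing SINE tails from their source LINE, and the terminal
# microsatellite required for target-primed reverse transcription.

# aligned named character vector -> character matrix (copies x columns)
.aln_matrix <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences are not in one alignment frame ",
                            "(unequal lengths)", call. = FALSE)
  t(vapply(seqs, function(s) .chars(toupper(s)), character(w)))
}

#' Majority-rule consensus of aligned family copies
#'
#' A column is emitted when more than half of the copies have a non-gap
#' character there; the consensus state is the most frequent non-gap base,
#' with ties encoded as the IUPAC ambiguity code of the tied bases.
#'
#' @param copies named character vector of aligned sequences (gaps "-"),
#'   length >= 2.
#' @return the consensus DNA string.
#' @export
#' @examples
#' majority_consensus(c(a = "ACGT", b = "ACGT", c = "ACTT"))
majority_consensus <- function(copies) {
  if (length(copies) < 2L) stop(">= 2 aligned copies required", call. = FALSE)
  m <- .aln_matrix(copies)
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    bases <- col[col %in% .BASES]
    if (length(bases) <= length(col) / 2) next  # gap-majority column dropped
    tab <- table(bases)
    top <- names(tab)[tab == max(tab)]
    out <- c(out, if (length(top) == 1L) top else .iupac_code(top))
  }
  if (!length(out)) stop("empty alignment: no consensus columns",
                         call. = FALSE)
  .collapse(out)
}

#' Partition a chimeric SINE consensus into tRNA head and CR1 tail
#'
#' Locally aligns every tRNA and every CR1 reference against the consensus;
#' the best-scoring hit of each library gives the head and tail source. The
#' head/tail boundary is the midpoint of the gap between the two hit spans,
#' or the crossover midpoint when they overlap.
#'
#' @param consensus SINE consensus DNA string.
#' @param trna_lib,cr1_lib named character vectors (or DNAStringSets) of
#'   tRNA gene and CR1 3'-end reference sequences.
#' @param min_score minimum local alignment score for a hit to count; below
#'   it the consensus is not partitionable.
#' @param name family name recorded on the model.
#' @return object of class `sine_family_model`: `name`, `consensus`,
#'   `head_span`, `tail_span` (0-based half-open), `head_source`,
#'   `tail_source`, `head_score`, `tail_score`, `microsat_present`.
#' @export
partition_sine <- function(consensus, trna_lib, cr1_lib, min_score = 20,
                           name = "SINE") {
  consensus <- .check_dna(consensus, "consensus")
  trna_lib <- .as_library(trna_lib)
  cr1_lib <- .as_library(cr1_lib)
  if (!length(trna_lib) || !length(cr1_lib)) {
    stop("reference libraries must be non-empty", call. = FALSE)
  }
  best_of <- function(lib) {
    hits <- lapply(lib, function(s) .best_local_hit(s, consensus))
    scores <- vapply(hits, `[[`, numeric(1), "score")
    i <- which.max(scores)
    c(hits[[i]], list(source = names(lib)[i]))
  }
  head_hit <- best_of(trna_lib)
  tail_hit <- best_of(cr1_lib)
  if (head_hit$score < min_score || tail_hit$score < min_score) {
    stop("unpartitionable: no ",
         if (head_hit$score < min_score) "tRNA head" else "CR1 tail",
         " hit above score ", min_score, call. = FALSE)
  }
  if (head_hit$start >= tail_hit$start) {
    stop("unpartitionable: tRNA hit does not precede CR1 hit", call. = FALSE)
  }
  boundary <- if (head_hit$end <= tail_hit$start) {
    floor((head_hit$end + tail_hit$start) / 2)
  } else {
    floor((tail_hit$start + head_hit$end) / 2)  # overlap: crossover midpoint
  }
  structure(list(name = name, consensus = consensus,
                 head_span = c(0L, as.integer(boundary)),
                 tail_span = c(as.integer(boundary), nchar(consensus)),
                 head_source = head_hit$source, tail_source = tail_hit$source,
                 head_score = head_hit$score, tail_score = tail_hit$score,
                 head_hit_span = c(head_hit$start, head_hit$end),
                 tail_hit_span = c(tail_hit$start, tail_hit$end),
                 microsat_present = check_terminal_microsat(consensus)$match),
            class = "sine_family_model")
}

#' @export
print.sine_family_model <- function(x, ...) {
  cat("SINE family model '", x$name, "' (", nchar(x$consensus), " nt)\n",
      "  head [", x$head_span[1L], ",", x$head_span[2L], "): ",
      x$head_source, " (score ", x$head_score, ")\n",
      "  tail [", x$tail_span[1L], ",", x$tail_span[2L], "): ",
      x$tail_source, " (score ", x$tail_score, ")\n",
      "  terminal microsatellite: ",
      if (x$microsat_present) "present" else "absent", "\n", sep = "")
  invisible(x)
}

#' Diagnostic sites separating SINE tails from their source CR1
#'
#' Positions (0-based alignment columns) where all SINE tail consensi share
#' one non-gap state and the CR1 reference carries a different non-gap
#' state. Columns where the tails disagree among themselves are excluded.
#'
#' @param tails named character vector of >= 2 aligned SINE tail consensi.
#' @param cr1_ref aligned CR1 3'-end reference in the same frame.
#' @return data.frame: `position` (0-based), `sine_state`, `cr1_state`.
#' @export
diagnostic_sites <- function(tails, cr1_ref) {
  if (length(tails) < 1L) stop("at least one SINE tail required",
                               call. = FALSE)
  if (nchar(cr1_ref) != unique(nchar(tails))[1L] ||
      length(unique(nchar(tails))) != 1L) {
    stop("tails and cr1_ref must share one alignment frame", call. = FALSE)
  }
  m <- .aln_matrix(tails)
  ref <- .chars(toupper(cr1_ref))
  pos <- integer(0); s_state <- character(0); c_state <- character(0)
  for (j in seq_len(ncol(m))) {
    states <- unique(m[, j])
    if (length(states) != 1L) next            # tails disagree
    if (!states %in% .BASES) next             # gap/ambiguous in tails
    if (!ref[j] %in% .BASES) next             # gap in reference
    if (states != ref[j]) {
      pos <- c(pos, j - 1L)
      s_state <- c(s_state, states)
      c_state <- c(c_state, ref[j])
    }
  }
  data.frame(position = pos, sine_state = s_state, cr1_state = c_state)
}

#' Count copies carrying all diagnostic states
#'
#' @param copies named character vector of aligned copies, in the same frame
#'   as the positions in `sites`.
#' @param sites data.frame as returned by [diagnostic_sites()] (columns
#'   `position`, `sine_state`).
#' @return list: `count` of copies matching every site, and `per_copy`
#'   data.frame (`copy`, `n_matched`, `all_matched`).
#' @export
screen_copies <- function(copies, sites) {
  m <- .aln_matrix(copies)
  stopifnot(is.data.frame(sites), all(c("position", "sine_state") %in%
                                        names(sites)))
  if (nrow(sites) && max(sites$position) >= ncol(m)) {
    stop("diagnostic positions outside alignment frame", call. = FALSE)
  }
  matched <- vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, sites$position + 1L] == sites$sine_state)
  }, integer(1))
  per_copy <- data.frame(copy = rownames(m), n_matched = matched,
                         all_matched = matched == nrow(sites))
  list(count = sum(per_copy$all_matched), per_copy = per_copy)
}

#' Check for the CR1 terminal 8-bp microsatellite
#'
#' CR1 elements and the SINEs they mobilize end in the 8-bp motif
#' 5'-AUUCURUG-3' (DNA: ATTCTRTG, R = A/G), the substrate of target-primed
#' reverse transcription.
#'
#' @param seq DNA string, >= 8 nt.
#' @return list: `match` (logical), `position` (0-based start of the motif,
#'   NA when absent).
#' @export
check_terminal_microsat <- function(seq) {
  seq <- .check_dna(seq)
  if (nchar(seq) < 8L) stop("sequence shorter than the 8-nt motif",
                            call. = FALSE)
  tail8 <- substr(seq, nchar(seq) - 7L, nchar(seq))
  ok <- grepl("^ATTCT[AG]TG$", tail8)
  list(match = ok, position = if (ok) nchar(seq) - 8L else NA_integer_)
}
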