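#' @keywords internal
"_PACKAGE"

.BASES <- c("A", "C", "G", "T")

# transition / transversion partner tables (purine<->purine, pyrimidine<->pyrimidine)
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNER1 <- c(A = "C", G = "C", C = "A", T = "A")
.TV_PARTNER2 <- c(A = "T", G = "T", C = "G", T = "G")

.IUPAC <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

#' Split a sequence string into a character vector of single bases
#' @noRd
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' @noRd
.collapse <- function(x) paste(x, collapse = "")

#' Validate that a string is strict ACGT DNA
#'
#' @param seq character scalar.
#' @param what label used in the error message.
#' @return invisibly, the uppercased sequence.
#' @noRd
.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  seq <- toupper(seq)
  bad <- which(!.chars(seq) %in% .BASES)
  if (length(bad)) {
    stop(what, " contains non-ACGT character '",
         substr(seq, bad[1L], bad[1L]), "' at position ", bad[1L],
         call. = FALSE)
  }
  invisible(seq)
}

#' Random DNA string
#' @noRd
.random_dna <- function(n) .collapse(sample(.BASES, n, replace = TRUE))

#' Reverse complement of a plain DNA string (gaps preserved)
#'
#' @param seq character scalar over A,C,G,T,-,N.
#' @return the reverse complement string.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .collapse(rev(.chars(chartr("ACGTacgt", "TGCAtgca", seq))))
}

#' IUPAC ambiguity code for a set of bases
#' @noRd
.iupac_code <- function(bases) {
  key <- .collapse(sort(unique(bases)))
  code <- .IUPAC[key]
  if (is.na(code)) "N" else unname(code)
}

#' Fraction of gap characters in a string segment
#' @noRd
.gap_frac <- function(chars) {
  if (!length(chars)) return(1)
  mean(chars %in% c("-", "?"))
}

# local-alignment scoring shared by subtype assignment, locus discovery and
# family partitioning: match +1, mismatch -1, gap open -5, gap extend -1
.submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Best local alignment score of `query` against `subject` on both strands
#'
#' @return list(score, start, end, strand) with 0-based half-open span on the
#'   subject's forward coordinates of the forward-strand hit (reverse hits
#'   report the span on the reversed subject).
#' @noRd
.best_local_hit <- function(query, subject) {
  q <- Biostrings::DNAString(gsub("[^ACGTacgt]", "N", query))
  s_fwd <- Biostrings::DNAString(gsub("[^ACGTacgt]", "N", subject))
  s_rev <- Biostrings::reverseComplement(s_fwd)
  hit <- function(s, strand) {
    al <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                        substitutionMatrix = .submat(),
                                        gapOpening = 5, gapExtension = 1)
    sp <- Biostrings::subject(al)
    list(score = Biostrings::score(al),
         start = Biostrings::start(sp) - 1L,
         end = Biostrings::end(sp),
         q_start = Biostrings::start(Biostrings::pattern(al)) - 1L,
         q_end = Biostrings::end(Biostrings::pattern(al)),
         pid = Biostrings::pid(al, type = "PID2"),
         strand = strand)
  }
  fwd <- hit(s_fwd, "forward")
  rev <- hit(s_rev, "reverse")
  if (fwd$score >= rev$score) fwd else rev
}
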