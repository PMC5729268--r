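# CpG-excluded Kimura 2-parameter divergence of element copies to their
# family consensus, and binned divergence landscapes. CpG dinucleotides are
# methylation-mutation hotspots; all columns belonging to a consensus CpG
# are excluded before distances are computed.

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Counts transition (P) and transversion (Q) fractions over comparable
#' columns and applies the closed form
#' d = -1/2 ln\[(1 - 2P - Q) sqrt(1 - 2Q)\].
#' Columns where either sequence is a gap or ambiguity are excluded pairwise;
#' when a consensus is supplied, both positions of every CpG dinucleotide in
#' the consensus are excluded as well. Rates are uniform among sites (no
#' gamma correction).
#'
#' @param a,b aligned sequences of equal length.
#' @param exclude_cpg_in consensus sequence in the same alignment frame
#'   whose CpG columns are excluded, or NULL for no CpG exclusion.
#' @return object of class `k2p_estimate`: `p_transitions`,
#'   `q_transversions`, `distance`, `n_sites`.
#' @export
#' @examples
#' k2p_distance("ACGTACGT", "ACGTACGT")$distance  # 0
k2p_distance <- function(a, b, exclude_cpg_in = NULL) {
  xa <- .chars(toupper(a)); xb <- .chars(toupper(b))
  if (length(xa) != length(xb)) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  keep <- xa %in% .BASES & xb %in% .BASES
  if (!is.null(exclude_cpg_in)) {
    cons <- toupper(exclude_cpg_in)
    if (nchar(cons) != length(xa)) {
      stop("consensus must be in the same alignment frame", call. = FALSE)
    }
    keep[.cpg_positions(cons)] <- FALSE
  }
  n <- sum(keep)
  if (n == 0L) stop("zero comparable sites", call. = FALSE)
  xa <- xa[keep]; xb <- xb[keep]
  diff <- xa != xb
  ts <- diff & (.TS_PARTNER[xa] == xb)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop("saturated: K2P distance undefined for P=", signif(P, 4),
         ", Q=", signif(Q, 4), call. = FALSE)
  }
  structure(list(p_transitions = P, q_transversions = Q,
                 distance = -0.5 * log(arg1 * sqrt(arg2)) + 0,  # avoid -0
                 n_sites = n),
            class = "k2p_estimate")
}

#' @export
print.k2p_estimate <- function(x, ...) {
  cat("K2P distance ", format(x$distance, digits = 4), " (P = ",
      format(x$p_transitions, digits = 4), ", Q = ",
      format(x$q_transversions, digits = 4), ", n = ", x$n_sites,
      " sites)\n", sep = "")
  invisible(x)
}

#' Divergence landscape of a retroposon family
#'
#' Computes the CpG-excluded K2P distance of every copy to the family
#' consensus and bins the distances (in percent) into a landscape, the
#' standard proxy for element activity through time: young families pile up
#' near 0%, extinct ones sit at high divergence.
#'
#' @param copies named character vector of copies aligned to the consensus
#'   frame.
#' @param consensus consensus sequence in the same frame.
#' @param bin_width histogram bin width in percent divergence.
#' @return object of class `re_landscape`: `per_copy` data.frame (`copy`,
#'   `p`, `q`, `distance_pct`, `n_sites`), `bins` data.frame (`bin_lower`,
#'   `bin_width`, `copy_count`), `summary` (mean/min/max percent),
#'   `saturated` (copy names dropped).
#' @export
family_landscape <- function(copies, consensus, bin_width = 1.0) {
  stopifnot(length(copies) >= 1L, bin_width > 0)
  est <- lapply(names(copies), function(nm) {
    tryCatch(k2p_distance(copies[[nm]], consensus,
                          exclude_cpg_in = consensus),
             error = function(e) e)
  })
  names(est) <- names(copies)
  bad <- vapply(est, inherits, logical(1), "error")
  if (any(bad)) {
    warning(sum(bad), " copy(ies) dropped (saturated or uncomparable): ",
            paste(names(est)[bad], collapse = ", "), call. = FALSE)
  }
  est <- est[!bad]
  if (!length(est)) stop("no copy yielded a defined distance", call. = FALSE)
  per_copy <- data.frame(
    copy = names(est),
    p = vapply(est, `[[`, numeric(1), "p_transitions"),
    q = vapply(est, `[[`, numeric(1), "q_transversions"),
    distance_pct = 100 * vapply(est, `[[`, numeric(1), "distance"),
    n_sites = vapply(est, `[[`, numeric(1), "n_sites"),
    row.names = NULL)
  top <- max(per_copy$distance_pct)
  breaks <- seq(0, bin_width * (floor(top / bin_width) + 1L), by = bin_width)
  counts <- tabulate(findInterval(per_copy$distance_pct, breaks,
                                  rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  bins <- data.frame(bin_lower = breaks[-length(breaks)],
                     bin_width = bin_width, copy_count = counts)
  structure(list(per_copy = per_copy, bins = bins,
                 summary = c(mean = mean(per_copy$distance_pct),
                             min = min(per_copy$distance_pct),
                             max = max(per_copy$distance_pct)),
                 saturated = names(copies)[bad]),
            class = "re_landscape")
}

#' @export
print.re_landscape <- function(x, ...) {
  cat("Divergence landscape: ", nrow(x$per_copy), " copies, mean ",
      format(x$summary[["mean"]], digits = 3), "%, range ",
      format(x$summary[["min"]], digits = 3), "-",
      format(x$summary[["max"]], digits = 3), "%\n", sep = "")
  if (length(x$saturated)) {
    cat("  saturated copies dropped: ", paste(x$saturated, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.re_landscape <- function(x, main = "Retroposon divergence landscape",
                              ...) {
  graphics::barplot(x$bins$copy_count,
                    names.arg = sprintf("%g", x$bins$bin_lower),
                    xlab = "K2P distance to consensus (%, CpG excluded)",
                    ylab = "copies", main = main, space = 0, ...)
  invisible(x)
}
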