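# Presence/absence marker calling. A marker is phylogenetically reliable
# only when every presence shares the orthologous insertion point, element
# orientation, element subtype and target-site duplication, and at least one
# taxon shows the clean empty site. Numeric surrogates for these by-eye
# criteria (gap-occupancy thresholds, junction tolerance, TSD length bounds)
# are stated defaults and configurable.

# reason codes that constitute violations of the validity criteria, as
# opposed to soft ambiguity (missing/partial data)
.VIOLATION_CODES <- c("shifted_junction", "subtype_mismatch",
                      "orientation_flip", "tsd_mismatch")

#' One marker locus: aligned taxa plus the annotated element span
#'
#' @param locus_id unique identifier.
#' @param rows named character vector, taxon -> aligned sequence (gaps "-";
#'   "?"/"N" allowed as missing data).
#' @param element_span integer [start, end), 0-based half-open, in alignment
#'   columns, of the element in the reference taxon.
#' @param ref_taxon taxon whose annotation defined the span.
#' @return object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, rows, element_span, ref_taxon) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)),
            length(element_span) == 2L)
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows must all have equal length", call. = FALSE)
  }
  element_span <- as.integer(element_span)
  if (element_span[1L] < 0L || element_span[2L] > widths[1L] ||
      element_span[1L] >= element_span[2L]) {
    stop("element_span out of bounds", call. = FALSE)
  }
  if (!ref_taxon %in% names(rows)) {
    stop("ref_taxon '", ref_taxon, "' not among alignment rows",
         call. = FALSE)
  }
  ref_chars <- .chars(rows[[ref_taxon]])
  span_idx <- seq(element_span[1L] + 1L, element_span[2L])
  if (.gap_frac(ref_chars[span_idx]) >= 0.10) {
    stop("ref_taxon row has >= 10% gaps inside element_span", call. = FALSE)
  }
  structure(list(locus_id = locus_id, rows = rows,
                 element_span = element_span, ref_taxon = ref_taxon),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus ", x$locus_id, ": ", length(x$rows), " taxa x ",
      nchar(x$rows[[1L]]), " columns; element [",
      x$element_span[1L], ",", x$element_span[2L], ") annotated on ",
      x$ref_taxon, "\n", sep = "")
  invisible(x)
}

#' Detect a target-site duplication around an element
#'
#' Finds the longest exact direct repeat that immediately precedes the
#' element start and begins again at the element end, in an ungapped
#' sequence. TSDs are the hallmark of target-primed reverse transcription.
#'
#' @param row ungapped DNA string.
#' @param element_start,element_end 0-based half-open element span in `row`.
#' @param max_len,min_len length bounds of the duplication (nt).
#' @return the TSD string, or NULL when no exact repeat of an allowed length
#'   exists (with a warning when the element abuts the sequence boundary).
#' @export
detect_tsd <- function(row, element_start, element_end,
                       max_len = 20L, min_len = 4L) {
  stopifnot(is.character(row), length(row) == 1L,
            element_start >= 0L, element_end >= element_start,
            element_end <= nchar(row), min_len >= 1L, max_len >= min_len)
  n <- nchar(row)
  if (element_start == 0L || element_end == n) {
    warning("element at sequence boundary; TSD undetectable", call. = FALSE)
    return(NULL)
  }
  top <- min(max_len, element_start, n - element_end)
  if (top < min_len) return(NULL)
  for (len in seq(top, min_len)) {
    left <- substr(row, element_start - len + 1L, element_start)
    right <- substr(row, element_end + 1L, element_end + len)
    if (left == right) return(left)
  }
  NULL
}

# ungapped coordinates of the element span within a row, plus the ungapped
# sequence; NULL when the row has no sequence
.ungapped_span <- function(row, span) {
  chars <- .chars(row)
  keep <- !(chars %in% c("-", "?"))
  if (!any(keep)) return(NULL)
  start_u <- sum(keep[seq_len(span[1L])])
  end_u <- sum(keep[seq_len(span[2L])])
  list(seq = .collapse(chars[keep]), start = start_u, end = end_u)
}

# per-row characterization used by classify_taxon: occupancy, junction
# columns, best library hit, TSD
.characterize_row <- function(locus, taxon, library, max_tsd, min_tsd) {
  row <- locus$rows[[taxon]]
  chars <- .chars(row)
  span <- locus$element_span
  span_idx <- seq(span[1L] + 1L, span[2L])
  gaps <- .gap_frac(chars[span_idx])
  occupied <- which(!(chars[span_idx] %in% c("-", "?")))
  left_j <- if (length(occupied)) span[1L] + occupied[1L] - 1L else NA_integer_
  right_j <- if (length(occupied)) span[1L] + occupied[length(occupied)]
             else NA_integer_
  elem_seq <- if (length(occupied)) {
    .collapse(chars[span_idx][occupied])
  } else ""
  subtype <- NA_character_
  orientation <- NA_character_
  if (nchar(elem_seq) >= 20L && length(library)) {
    scores <- vapply(seq_along(library), function(i) {
      hit <- .best_local_hit(elem_seq, library[[i]])
      c(hit$score, if (hit$strand == "forward") 1 else -1)
    }, numeric(2))
    best <- which.max(scores[1L, ])  # ties: first library entry wins
    subtype <- names(library)[best]
    orientation <- if (scores[2L, best] > 0) "forward" else "reverse"
  }
  tsd <- NULL
  u <- .ungapped_span(row, span)
  if (!is.null(u) && gaps <= 0.5) {
    tsd <- suppressWarnings(
      detect_tsd(u$seq, u$start, u$end, max_len = max_tsd, min_len = min_tsd))
  }
  list(gap_frac = gaps, left_junction = left_j, right_junction = right_j,
       subtype = subtype, orientation = orientation, tsd = tsd,
       element_seq = elem_seq, chars = chars)
}

#' Call the presence/absence state of one taxon at a marker locus
#'
#' A taxon is called present when the element span is occupied (at most
#' `max_gap_present` gaps), its junctions sit within `junction_tol` columns
#' of the reference taxon's, its best library hit matches the reference
#' subtype and orientation, and (when detected in both) its TSD is identical
#' to the reference TSD. It is called absent when the span is at least
#' `min_gap_absent` gaps and the flanks align contiguously. Anything else is
#' ambiguous, with machine-readable reason codes.
#'
#' @param locus a [locus_alignment()].
#' @param taxon taxon to call.
#' @param library named character vector (or [Biostrings::DNAStringSet]) of
#'   reference element consensi for subtype assignment.
#' @param junction_tol tolerated junction shift, alignment columns.
#' @param max_gap_present,min_gap_absent occupancy thresholds.
#' @param max_tsd,min_tsd TSD length bounds (nt).
#' @param .ref_info precomputed reference-taxon characterization (internal,
#'   used by [call_locus()] to avoid recomputation).
#' @return object of class `insertion_call`.
#' @export
classify_taxon <- function(locus, taxon, library, junction_tol = 2L,
                           max_gap_present = 0.10, min_gap_absent = 0.90,
                           max_tsd = 20L, min_tsd = 4L, .ref_info = NULL) {
  stopifnot(inherits(locus, "locus_alignment"))
  if (!taxon %in% names(locus$rows)) {
    stop("taxon '", taxon, "' not in alignment of ", locus$locus_id,
         call. = FALSE)
  }
  library <- .as_library(library)
  me <- .characterize_row(locus, taxon, library, max_tsd, min_tsd)
  reasons <- character(0)
  state <- "ambiguous"
  # no usable sequence at all -> missing, never absent
  if (all(me$chars %in% c("-", "?", "N"))) {
    return(.insertion_call(taxon, "ambiguous", me, "missing_sequence"))
  }
  if (me$gap_frac <= max_gap_present) {
    state <- "present"
    if (taxon != locus$ref_taxon) {
      ref <- if (!is.null(.ref_info)) .ref_info
             else .characterize_row(locus, locus$ref_taxon, library, max_tsd,
                                    min_tsd)
      if (is.na(me$left_junction) ||
          abs(me$left_junction - ref$left_junction) > junction_tol ||
          abs(me$right_junction - ref$right_junction) > junction_tol) {
        reasons <- c(reasons, "shifted_junction")
      }
      if (!is.na(me$subtype) && !is.na(ref$subtype) &&
          me$subtype != ref$subtype) {
        reasons <- c(reasons, "subtype_mismatch")
      }
      if (!is.na(me$orientation) && !is.na(ref$orientation) &&
          me$orientation != ref$orientation) {
        reasons <- c(reasons, "orientation_flip")
      }
      # "if present": the TSD criterion only applies when detected in both
      if (!is.null(me$tsd) && !is.null(ref$tsd) && me$tsd != ref$tsd) {
        reasons <- c(reasons, "tsd_mismatch")
      }
      if (length(reasons)) state <- "ambiguous"
    }
  } else if (me$gap_frac >= min_gap_absent) {
    if (.flanks_contiguous(me$chars, locus$element_span)) {
      state <- "absent"
    } else {
      reasons <- "flank_gap"
    }
  } else {
    reasons <- "partial_element"
  }
  .insertion_call(taxon, state, me, reasons)
}

# flanks are contiguous when the 30 columns adjacent to each side of the
# span are mostly sequence, not gap
.flanks_contiguous <- function(chars, span, window = 30L, min_occ = 0.5) {
  n <- length(chars)
  left_idx <- seq(max(1L, span[1L] - window + 1L), max(1L, span[1L]))
  right_idx <- seq(min(n, span[2L] + 1L), min(n, span[2L] + window))
  (1 - .gap_frac(chars[left_idx])) >= min_occ &&
    (1 - .gap_frac(chars[right_idx])) >= min_occ
}

.insertion_call <- function(taxon, state, info, reasons) {
  structure(list(taxon = taxon, state = state,
                 left_junction = info$left_junction,
                 right_junction = info$right_junction,
                 tsd = info$tsd, orientation = info$orientation,
                 subtype = info$subtype, reasons = reasons),
            class = "insertion_call")
}

#' @export
print.insertion_call <- function(x, ...) {
  cat(x$taxon, ": ", x$state,
      if (!is.na(x$subtype)) paste0(" [", x$subtype, ", ", x$orientation, "]"),
      if (!is.null(x$tsd)) paste0(" TSD=", x$tsd),
      if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ","),
                                    ")"),
      "\n", sep = "")
  invisible(x)
}

.as_library <- function(library) {
  if (inherits(library, "DNAStringSet") || inherits(library, "BStringSet")) {
    library <- stats::setNames(as.character(library), names(library))
  }
  stopifnot(is.character(library), !is.null(names(library)))
  library
}

# default mapping from library subtype names to marker classes
.re_class_of <- function(subtype) {
  if (is.na(subtype)) return("other")
  if (grepl("TguSINE1", subtype, ignore.case = TRUE)) return("SINE-TguSINE1")
  if (grepl("PittSINE", subtype, ignore.case = TRUE)) return("SINE-PittSINE")
  if (grepl("CR1", subtype, ignore.case = TRUE)) return("CR1")
  if (grepl("LTR|ERV", subtype, ignore.case = TRUE)) return("LTR")
  "other"
}

#' Validate a marker locus from its per-taxon calls
#'
#' A marker is valid when at least one taxon is present, at least one is
#' cleanly absent, and no call violates any validity criterion (junction,
#' subtype, orientation, TSD). Soft ambiguity (missing or partial sequence)
#' does not invalidate a marker.
#'
#' @param locus a [locus_alignment()].
#' @param calls list of [classify_taxon()] results (>= 3 taxa).
#' @return object of class `marker_record` with fields `locus_id`, `calls`,
#'   `valid`, `re_class`, `failure_reasons`.
#' @export
validate_marker <- function(locus, calls) {
  stopifnot(inherits(locus, "locus_alignment"), is.list(calls))
  if (length(calls) < 3L) stop(">= 3 taxa must be called", call. = FALSE)
  states <- vapply(calls, `[[`, character(1), "state")
  reasons <- unlist(lapply(calls, `[[`, "reasons"))
  violations <- intersect(reasons, .VIOLATION_CODES)
  failure <- character(0)
  if (all(states == "ambiguous")) failure <- c(failure, "uninformative")
  if (!any(states == "present")) failure <- c(failure, "no_presence")
  if (!any(states == "absent")) failure <- c(failure, "no_clear_absence")
  failure <- c(failure, violations)
  ref_idx <- match(locus$ref_taxon, vapply(calls, `[[`, character(1), "taxon"))
  re_class <- .re_class_of(if (is.na(ref_idx)) NA_character_
                           else calls[[ref_idx]]$subtype)
  structure(list(locus_id = locus$locus_id, calls = calls,
                 valid = length(failure) == 0L, re_class = re_class,
                 failure_reasons = unique(failure)),
            class = "marker_record")
}

#' @export
print.marker_record <- function(x, ...) {
  cat("Marker ", x$locus_id, " [", x$re_class, "]: ",
      if (x$valid) "VALID" else paste0("invalid (",
                                       paste(x$failure_reasons,
                                             collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Classify every taxon of a locus and validate the marker
#'
#' @inheritParams classify_taxon
#' @param ... passed to [classify_taxon()].
#' @return a `marker_record`.
#' @export
call_locus <- function(locus, library, ...) {
  library <- .as_library(library)
  dots <- list(...)
  ref_info <- .characterize_row(
    locus, locus$ref_taxon, library,
    max_tsd = if (is.null(dots$max_tsd)) 20L else dots$max_tsd,
    min_tsd = if (is.null(dots$min_tsd)) 4L else dots$min_tsd)
  calls <- lapply(names(locus$rows), function(t) {
    classify_taxon(locus, t, library, ..., .ref_info = ref_info)
  })
  validate_marker(locus, calls)
}

#' Discover candidate presence/absence loci from an ingroup/outgroup pair
#'
#' For each annotated element in the ingroup sequence, extracts both flanks
#' and maps them onto the outgroup by local alignment. A candidate empty
#' site is emitted when both flanks map co-linearly on the same strand with
#' at least `min_flank_identity` identity and the outgroup inter-flank gap
#' is shorter than half the element (the element is missing there).
#'
#' @param ingroup_seq ingroup DNA string.
#' @param annotations data.frame with columns `name`, `start`, `end`
#'   (0-based half-open element spans in `ingroup_seq`).
#' @param outgroup_seq outgroup DNA string.
#' @param flank_len nucleotides of flank used on each side.
#' @param min_flank_identity minimum fractional identity of each mapped
#'   flank.
#' @param min_flank_coverage minimum fraction of the flank that the local
#'   alignment must cover.
#' @param max_overlap tolerated overlap (nt) of the two flank hits in the
#'   outgroup; at a true empty site they overlap by the target-site length.
#' @return data.frame, one row per annotation: `name`, `candidate` (logical),
#'   `reason`, `out_gap` (signed outgroup inter-flank distance, negative for
#'   overlapping hits, NA unless both flanks mapped co-linearly).
#' @export
discover_candidates <- function(ingroup_seq, annotations, outgroup_seq,
                                flank_len = 300L, min_flank_identity = 0.75,
                                min_flank_coverage = 0.5, max_overlap = 25L) {
  ingroup_seq <- .check_dna(ingroup_seq, "ingroup_seq")
  outgroup_seq <- .check_dna(outgroup_seq, "outgroup_seq")
  stopifnot(is.data.frame(annotations),
            all(c("name", "start", "end") %in% names(annotations)))
  out <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    elem_len <- a$end - a$start
    left <- substr(ingroup_seq, max(1L, a$start - flank_len + 1L), a$start)
    right <- substr(ingroup_seq, a$end + 1L,
                    min(nchar(ingroup_seq), a$end + flank_len))
    lh <- .best_local_hit(left, outgroup_seq)
    rh <- .best_local_hit(right, outgroup_seq)
    ok <- function(h, flank) {
      h$pid / 100 >= min_flank_identity &&
        (h$q_end - h$q_start) >= min_flank_coverage * nchar(flank)
    }
    res <- list(name = a$name, candidate = FALSE, reason = "",
                out_gap = NA_integer_)
    if (!ok(lh, left) || !ok(rh, right)) {
      res$reason <- "flank_unmapped"
    } else if (lh$strand != rh$strand) {
      res$reason <- "strand_mismatch"
    } else if (rh$start < lh$end - max_overlap) {
      # a small overlap is expected: at an empty site both flank hits share
      # the single copy of the target site (the would-be TSD)
      res$reason <- "not_colinear"
    } else {
      gap <- rh$start - lh$end
      res$out_gap <- gap
      if (gap < elem_len / 2) {
        res$candidate <- TRUE
        res$reason <- "empty_site"
      } else {
        res$reason <- "site_occupied"
      }
    }
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
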