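# Synthetic data: sequence evolution under a two-parameter (Kimura)
# substitution process, chimeric SINE templates, and whole marker-locus sets
# with truth tables.

#' Evolve a DNA sequence under the Kimura two-parameter process
#'
#' Applies independent per-site substitutions drawn from the K80 transition
#' probability matrix at the requested expected number of substitutions per
#' site. The process is the generative conjugate of [k2p_distance()]: over
#' long sequences the estimated distance converges to `distance`.
#'
#' @param seq DNA string (strict ACGT).
#' @param distance expected substitutions per site along the branch (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param seed optional integer; when given the call is deterministic.
#'   When NULL the current RNG stream is used (so callers can chain).
#' @return a string of the same length.
#' @export
#' @examples
#' evolve_sequence("ACGTACGT", 0, kappa = 2, seed = 1)
evolve_sequence <- function(seq, distance, kappa = 2, seed = NULL) {
  seq <- .check_dna(seq)
  stopifnot(is.numeric(distance), length(distance) == 1L, distance >= 0,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  if (distance == 0 || nchar(seq) == 0L) return(seq)
  pr <- .k80_site_probs(distance, kappa)
  x <- .chars(seq)
  u <- stats::runif(length(x))
  out <- x
  ts <- u < pr$ts
  tv1 <- !ts & u < pr$ts + pr$tv
  tv2 <- !ts & !tv1 & u < pr$ts + 2 * pr$tv
  out[ts] <- .TS_PARTNER[x[ts]]
  out[tv1] <- .TV_PARTNER1[x[tv1]]
  out[tv2] <- .TV_PARTNER2[x[tv2]]
  .collapse(out)
}

#' Per-site substitution probabilities of the K80 chain
#'
#' @param distance expected substitutions/site, kappa ts/tv rate ratio.
#' @return list(ts = P(transition), tv = P(one given transversion)).
#' @noRd
.k80_site_probs <- function(distance, kappa) {
  bt <- distance / (kappa + 2)   # beta * t
  at <- kappa * bt               # alpha * t
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  list(ts = 0.25 + 0.25 * e1 - 0.5 * e2,
       tv = 0.25 - 0.25 * e1)
}

#' Expected transition / transversion fractions at a K80 distance
#'
#' @return list(P = transition fraction, Q = total transversion fraction).
#' @noRd
.k80_expected_pq <- function(distance, kappa) {
  pr <- .k80_site_probs(distance, kappa)
  list(P = pr$ts, Q = 2 * pr$tv)
}

#' Plant an exact Kimura divergence into a copy of a sequence
#'
#' Deterministic-divergence variant of [evolve_sequence()]: instead of
#' sampling per-site, it chooses site sets whose transition and transversion
#' counts realize the requested K2P distance exactly (up to count rounding)
#' when the copy is compared back to `seq` with [k2p_distance()] under
#' consensus-CpG exclusion. Substitutions are placed only at non-CpG columns
#' of `seq`, so CpG exclusion does not eat them.
#'
#' @inheritParams evolve_sequence
#' @return a string of the same length.
#' @export
plant_divergence <- function(seq, distance, kappa = 2, seed = NULL) {
  seq <- .check_dna(seq)
  stopifnot(distance >= 0, kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  if (distance == 0) return(seq)
  x <- .chars(seq)
  eligible <- setdiff(seq_along(x), .cpg_positions(seq))
  n <- length(eligible)
  if (n < 4L) stop("sequence too short to plant divergence", call. = FALSE)
  # realized ts:tv ratio of the K80 chain at this distance
  pq <- .k80_expected_pq(distance, kappa)
  r <- pq$P / pq$Q
  # solve for the (P, Q) with P = r*Q whose K2P closed form equals `distance`
  f <- function(q) {
    p <- r * q
    -0.5 * log((1 - 2 * p - q) * sqrt(1 - 2 * q)) - distance
  }
  qmax <- min(0.49, 0.999 / (2 * r + 1))
  q <- stats::uniroot(f, c(1e-12, qmax), tol = 1e-12)$root
  p <- r * q
  n_ts <- round(p * n)
  n_tv <- round(q * n)
  sites <- sample(eligible, n_ts + n_tv)
  ts_sites <- sites[seq_len(n_ts)]
  tv_sites <- sites[n_ts + seq_len(n_tv)]
  x[ts_sites] <- .TS_PARTNER[x[ts_sites]]
  pick2 <- stats::runif(length(tv_sites)) < 0.5
  x[tv_sites] <- ifelse(pick2, .TV_PARTNER1[x[tv_sites]],
                        .TV_PARTNER2[x[tv_sites]])
  .collapse(x)
}

# 1-based positions belonging to any CpG dinucleotide of `seq`
.cpg_positions <- function(seq) {
  x <- .chars(seq)
  i <- which(x[-length(x)] == "C" & x[-1L] == "G")
  unique(sort(c(i, i + 1L)))
}

# -------------------------------------------------------------------------
# SINE templates

#' Build a chimeric SINE template from a tRNA head and a CR1-derived tail
#'
#' CR1-mobilized SINEs are chimeras of a tRNA-derived head and the 3' end of
#' a CR1 LINE, terminating in the 8-bp microsatellite (DNA: ATTCTRTG,
#' R = A/G) required for target-primed reverse transcription.
#'
#' @param trna tRNA-derived head sequence (typically ~70-90 nt).
#' @param cr1_tail CR1-derived tail; must end with the terminal motif.
#' @param name family name.
#' @return an object of class `sine_template` with fields `name`, `head`,
#'   `tail`, `microsat`, `sequence`.
#' @export
make_sine_template <- function(trna, cr1_tail, name = "SINE") {
  trna <- .check_dna(trna, "trna")
  cr1_tail <- .check_dna(cr1_tail, "cr1_tail")
  motif <- substr(cr1_tail, nchar(cr1_tail) - 7L, nchar(cr1_tail))
  if (nchar(cr1_tail) < 8L || !grepl("^ATTCT[AG]TG$", motif)) {
    stop("cr1_tail must end with the CR1 terminal 8-bp microsatellite ",
         "ATTCTRTG (R = A or G); got '", motif, "'", call. = FALSE)
  }
  structure(list(name = name, head = trna, tail = cr1_tail, microsat = motif,
                 sequence = paste0(trna, cr1_tail)),
            class = "sine_template")
}

#' @export
print.sine_template <- function(x, ...) {
  cat("SINE template '", x$name, "': ", nchar(x$sequence), " nt (head ",
      nchar(x$head), " nt + CR1 tail ", nchar(x$tail),
      " nt, terminal microsatellite ", x$microsat, ")\n", sep = "")
  invisible(x)
}

# -------------------------------------------------------------------------
# Locus-set simulation

#' Simulation configuration
#'
#' @param n_loci_per_branch named integer vector, branch id -> number of
#'   marker loci whose insertion occurred on that branch.
#' @param flank_length nucleotides of flank on EACH side of the insertion
#'   point.
#' @param ts_tv_ratio transition/transversion rate ratio kappa.
#' @param tsd_length_range integer [min, max] target-site-duplication length,
#'   within [4, 20].
#' @param ils_probability per-locus probability that the marker sorts
#'   discordantly (incomplete lineage sorting) into one of the two
#'   alternative quartet resolutions of its insertion branch.
#' @param copy_divergence expected substitutions/site separating each
#'   inserted element copy from the family template.
#' @param decay_mode "stochastic" draws copy decay from the K80 chain;
#'   "planted" realizes `copy_divergence` exactly via [plant_divergence()].
#' @param orientation "forward" or "reverse": strand on which elements are
#'   inserted (reverse exists for negative tests of the orientation
#'   criterion).
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci_per_branch, flank_length = 500,
                       ts_tv_ratio = 2, tsd_length_range = c(6L, 12L),
                       ils_probability = 0, copy_divergence = 0.05,
                       decay_mode = c("stochastic", "planted"),
                       orientation = c("forward", "reverse"), seed = 1L) {
  decay_mode <- match.arg(decay_mode)
  orientation <- match.arg(orientation)
  stopifnot(length(n_loci_per_branch) >= 1L,
            !is.null(names(n_loci_per_branch)),
            all(n_loci_per_branch >= 0),
            flank_length > 0, ts_tv_ratio > 0,
            length(tsd_length_range) == 2L,
            tsd_length_range[1L] <= tsd_length_range[2L],
            tsd_length_range[1L] >= 4L, tsd_length_range[2L] <= 20L,
            ils_probability >= 0, ils_probability <= 1,
            copy_divergence >= 0)
  structure(list(n_loci_per_branch = n_loci_per_branch,
                 flank_length = as.integer(flank_length),
                 ts_tv_ratio = ts_tv_ratio,
                 tsd_length_range = as.integer(tsd_length_range),
                 ils_probability = ils_probability,
                 copy_divergence = copy_divergence,
                 decay_mode = decay_mode,
                 orientation = orientation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a set of presence/absence marker loci with truth records
#'
#' For each requested locus: an ancestral flank pair evolves down the tree
#' under the K80 process; on the insertion branch (or, with probability
#' `ils_probability`, into one of the two discordant quartet alternatives)
#' the element plus a target-site duplication is inserted at the flank
#' midpoint. The element copy is decayed once by `copy_divergence`; the
#' target site and its duplicate are held fixed below the insertion node so
#' the TSD criterion has a deterministic truth value. Insertions are modeled
#' as gap columns in absence taxa, so output alignments are column-true.
#'
#' @param tree rooted, labelled [ape::phylo] species tree with branch
#'   lengths in expected substitutions/site.
#' @param template a [make_sine_template()] object, or a single named DNA
#'   string for non-SINE elements (CR1, LTR).
#' @param cfg a [sim_config()].
#' @return list with `loci` (list of [locus_alignment()]) and `truth`
#'   (list of `sim_truth` records).
#' @export
simulate_locus_set <- function(tree, template, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- label_nodes(tree)
  if (ape::Ntip(tree) < 2L) stop("tree must have >= 2 tips", call. = FALSE)
  if (sum(cfg$n_loci_per_branch) == 0L) {
    stop("zero loci requested", call. = FALSE)
  }
  bids <- branch_ids(tree)
  unknown <- setdiff(names(cfg$n_loci_per_branch), bids)
  if (length(unknown)) {
    stop("branch(es) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  elem_seq <- if (inherits(template, "sine_template")) template$sequence
              else .check_dna(unname(template), "template")
  elem_name <- if (inherits(template, "sine_template")) template$name
               else if (!is.null(names(template))) names(template)[1L]
               else "element"

  set.seed(cfg$seed)
  loci <- list()
  truth <- list()
  counter <- 0L
  for (branch in names(cfg$n_loci_per_branch)) {
    for (i in seq_len(cfg$n_loci_per_branch[[branch]])) {
      counter <- counter + 1L
      locus_id <- sprintf("locus%04d", counter)
      sim <- .simulate_one_locus(tree, branch, elem_seq, elem_name, cfg,
                                 locus_id)
      loci[[locus_id]] <- sim$locus
      truth[[locus_id]] <- sim$truth
    }
  }
  list(loci = loci, truth = truth)
}

#' @noRd
.simulate_one_locus <- function(tree, branch, elem_seq, elem_name, cfg,
                                locus_id) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  F <- cfg$flank_length
  kappa <- cfg$ts_tv_ratio

  # evolve the 2F-nt flank from the root to every node (preorder)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- .random_dna(2L * F)
  ord <- ape::reorder.phylo(tree, "cladewise")
  node_seq_branch <- rep(NA_character_, ntip + tree$Nnode)
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    bl <- if (is.null(ord$edge.length)) 0 else ord$edge.length[e]
    seqs[[child]] <- evolve_sequence(seqs[[par]], bl, kappa)
  }

  # choose present-taxa set: concordant clade, or a quartet alternative
  concordant <- clade_tips(tree, branch)
  present <- concordant
  is_ils <- FALSE
  if (cfg$ils_probability > 0 && stats::runif(1) < cfg$ils_probability) {
    alt <- quartet_alternatives(tree, branch)
    if (!is.null(alt)) {
      present <- if (stats::runif(1) < 0.5) alt$alt1 else alt$alt2
      is_ils <- TRUE
    }
  }

  # insertion state created once at the insertion node
  ins_node <- .node_of_branch(tree, branch)
  tsd_len <- sample(seq(cfg$tsd_length_range[1L], cfg$tsd_length_range[2L]),
                    1L)
  tsd <- substr(seqs[[ins_node]], F - tsd_len + 1L, F)
  copy <- switch(cfg$decay_mode,
                 stochastic = evolve_sequence(elem_seq, cfg$copy_divergence,
                                              kappa),
                 planted = plant_divergence(elem_seq, cfg$copy_divergence,
                                            kappa))
  if (cfg$orientation == "reverse") copy <- revcomp(copy)
  E <- nchar(copy)

  rows <- character(ntip)
  names(rows) <- tree$tip.label
  for (t in seq_len(ntip)) {
    s <- seqs[[t]]
    left <- substr(s, 1L, F)
    right <- substr(s, F + 1L, 2L * F)
    taxon <- tree$tip.label[t]
    if (taxon %in% present) {
      # target site + duplicate frozen from the insertion node
      left <- paste0(substr(left, 1L, F - tsd_len), tsd)
      rows[taxon] <- paste0(left, copy, tsd, right)
    } else {
      rows[taxon] <- paste0(left, strrep("-", E + tsd_len), right)
    }
  }
  ref_taxon <- intersect(tree$tip.label, present)[1L]
  locus <- locus_alignment(locus_id, rows, element_span = c(F, F + E),
                           ref_taxon = ref_taxon)
  state <- stats::setNames(ifelse(tree$tip.label %in% present,
                                  "present", "absent"), tree$tip.label)
  truth <- structure(list(locus_id = locus_id, insertion_branch = branch,
                          tsd_sequence = tsd, per_taxon_state = state,
                          is_ils = is_ils, element = elem_name),
                     class = "sim_truth")
  list(locus = locus, truth = truth)
}

#' Simulate a retroposon family as decayed copies of a master sequence
#'
#' @param master family master/consensus DNA string.
#' @param n number of copies.
#' @param divergence expected substitutions/site per copy, recycled to n.
#' @param kappa ts/tv rate ratio.
#' @param decay_mode see [sim_config()].
#' @param seed optional seed.
#' @return named character vector of copies ("copy1"...).
#' @export
simulate_family <- function(master, n, divergence, kappa = 2,
                            decay_mode = c("stochastic", "planted"),
                            seed = NULL) {
  decay_mode <- match.arg(decay_mode)
  if (!is.null(seed)) set.seed(seed)
  divergence <- rep_len(divergence, n)
  out <- vapply(seq_len(n), function(i) {
    switch(decay_mode,
           stochastic = evolve_sequence(master, divergence[i], kappa),
           planted = plant_divergence(master, divergence[i], kappa))
  }, character(1))
  stats::setNames(out, paste0("copy", seq_len(n)))
}
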