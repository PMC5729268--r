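# A fully synthetic analogue of a deep-passerine retroposon marker study,
# used by the test suite and the acceptance script. Every sequence here is
# generated in code (none is a real tRNA, CR1 or SINE); the *design* — the
# taxon sampling, the number of markers per element class and per branch,
# the single discordant marker, the per-copy divergences of the young SINE
# family, and the total flank length — encodes the study conditions the
# pipeline is meant to handle.

# taxon sampling: two outgroups, the New Zealand wren lineage, three
# suboscines and six oscines
.SYNTH_TREE_NWK <- paste0(
  "(Gallus_gallus:0.030,(Nestor_notabilis:0.025,(Acanthisitta_chloris:0.022,",
  "((Pitta_sordida:0.020,(Sayornis_phoebe:0.015,Manacus_vitellinus:0.015)",
  "NWSuboscines:0.008)Suboscines:0.010,(Menura_novaehollandiae:0.015,",
  "(Climacteris_picumnus:0.013,(Malurus_cyaneus:0.012,",
  "(Pomatostomus_superciliosus:0.011,(Corvus_cornix:0.010,",
  "Taeniopygia_guttata:0.010)CorePasserida:0.004)Passerida:0.004)",
  "Meliphagoidea:0.004)CoreOscines:0.004)Oscines:0.010)Eupasseres:0.008)",
  "Passeriformes:0.010)Psittacopasserae:0.010);")

#' The synthetic study species tree
#'
#' A 12-taxon rooted tree with labelled internal nodes (Passeriformes,
#' Eupasseres, Suboscines, Oscines, ...) and branch lengths in expected
#' substitutions/site. All taxa are synthetic stand-ins for the lineages a
#' deep-passerine sampling would include.
#'
#' @return an [ape::phylo] tree.
#' @export
synthetic_tree <- function() {
  label_nodes(ape::read.tree(text = .SYNTH_TREE_NWK))
}

#' Synthetic reference sequences: tRNAs, CR1 3' end, SINE consensi
#'
#' Deterministic synthetic stand-ins (fixed internal seed, independent of
#' any analysis seed): two unrelated ~72-nt tRNA head sources, a 400-nt CR1
#' 3'-end consensus ending in the terminal microsatellite, two chimeric SINE
#' consensi sharing a CR1-derived tail that carries four planted diagnostic
#' substitutions relative to the CR1 (plus two private substitutions each),
#' and an unrelated LTR consensus.
#'
#' @return list: `trna_ile`, `trna_asp`, `cr1_3end`, `tgusine1`, `pittsine`,
#'   `ltr`, `tail_length`, `diagnostic_offsets` (0-based, within the tail),
#'   `library` (named vector used for subtype calling), `templates`
#'   (per-class element templates for the simulator).
#' @export
synthetic_references <- function() {
  set.seed(773001L)  # fixed: references are constants, not draws
  trna_ile <- .random_dna(72L)
  trna_asp <- .random_dna(72L)
  cr1_3end <- paste0(.random_dna(392L), "ATTCTGTG")
  tail_len <- 150L
  cr1_tail_src <- substr(cr1_3end, 401L - tail_len, 400L)
  # four diagnostic substitutions shared by both SINE tails, clear of the
  # terminal motif
  diag_off <- c(29L, 54L, 79L, 109L)  # 0-based within the tail
  plant <- function(seq, off, partner) {
    x <- .chars(seq)
    x[off + 1L] <- partner[x[off + 1L]]
    .collapse(x)
  }
  sine_tail <- plant(cr1_tail_src, diag_off, .TS_PARTNER)
  # family-private tail substitutions at disjoint positions
  tgu_tail <- plant(sine_tail, c(14L, 94L), .TV_PARTNER1)
  pitt_tail <- plant(sine_tail, c(39L, 124L), .TV_PARTNER2)
  tgusine1 <- make_sine_template(trna_ile, tgu_tail, name = "TguSINE1_syn")
  pittsine <- make_sine_template(trna_asp, pitt_tail, name = "PittSINE_syn")
  ltr <- .random_dna(350L)
  list(trna_ile = trna_ile, trna_asp = trna_asp, cr1_3end = cr1_3end,
       tgusine1 = tgusine1, pittsine = pittsine, ltr = ltr,
       tail_length = tail_len, diagnostic_offsets = diag_off,
       library = c(TguSINE1_syn = tgusine1$sequence,
                   PittSINE_syn = pittsine$sequence,
                   CR1_syn = cr1_3end, LTR_syn = ltr),
       templates = list(`SINE-TguSINE1` = tgusine1,
                        `SINE-PittSINE` = pittsine,
                        CR1 = c(CR1_syn = cr1_3end),
                        LTR = c(LTR_syn = ltr)))
}

# per-locus design of the synthetic study: 44 markers, 19 TguSINE1 /
# 6 PittSINE / 13 CR1 / 6 LTR, placed on the branches where such a study
# finds them; one TguSINE1 marker on the suboscine stem is discordant
# (incomplete lineage sorting). Per-side flank lengths vary by locus and
# sum so that the element-stripped supermatrix is 22,410 columns wide. The
# six young-SINE copies carry planted divergences spanning 0-11% with mean
# 6.3%.
.study_design <- function() {
  branches <- c(rep("Eupasseres", 6L), rep("Oscines", 9L),
                "Suboscines", "Suboscines",
                rep("Pitta_sordida", 2L),                    # TguSINE1 (19)
                rep("Pitta_sordida", 6L),                    # PittSINE (6)
                rep("Passeriformes", 5L), rep("Eupasseres", 4L),
                rep("Oscines", 2L), rep("Suboscines", 2L),   # CR1 (13)
                rep("Passeriformes", 2L), rep("Eupasseres", 2L),
                rep("Oscines", 2L))                          # LTR (6)
  classes <- c(rep("SINE-TguSINE1", 19L), rep("SINE-PittSINE", 6L),
               rep("CR1", 13L), rep("LTR", 6L))
  ids <- c(sprintf("synTgu%02d", 1:19), sprintf("synPitt%02d", 1:6),
           sprintf("synCR1_%02d", 1:13), sprintf("synLTR%02d", 1:6))
  ils <- ids == "synTgu10"  # the single discordant marker
  copy_div <- rep(0.05, 44L)
  decay <- rep("stochastic", 44L)
  pitt <- classes == "SINE-PittSINE"
  copy_div[pitt] <- c(0, 0.030, 0.058, 0.080, 0.100, 0.110)
  decay[pitt] <- "planted"
  flank <- floor(seq(150, 360, length.out = 44L))
  flank[44L] <- flank[44L] + (11205L - sum(flank))
  data.frame(locus_id = ids, re_class = classes, branch = branches,
             is_ils = ils, copy_divergence = copy_div, decay_mode = decay,
             flank_length = flank, stringsAsFactors = FALSE)
}

#' Generate and analyse the synthetic passerine retroposon study
#'
#' Simulates 44 marker loci under the study design (see
#' [synthetic_references()] and the package vignette), then runs the whole
#' pipeline: per-taxon calling and validation, presence/absence matrix,
#' Dollo mapping with conflict detection, branch support, the young-SINE
#' divergence landscape, and the element-stripped flank supermatrix.
#'
#' @param seed integer seed for the simulation.
#' @return list: `tree`, `refs`, `design`, `loci`, `truth`, `records`,
#'   `matrix`, `mapping`, `support`, `landscape`, `supermatrix`.
#' @export
synthetic_passerine_study <- function(seed = 1L) {
  tree <- synthetic_tree()
  refs <- synthetic_references()
  design <- .study_design()
  base <- (as.integer(seed) %% 100000L) * 1000L
  loci <- list()
  truth <- list()
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    template <- refs$templates[[d$re_class]]
    cfg <- sim_config(
      n_loci_per_branch = stats::setNames(1L, d$branch),
      flank_length = d$flank_length,
      ils_probability = as.numeric(d$is_ils),
      copy_divergence = d$copy_divergence,
      decay_mode = d$decay_mode,
      seed = base + i)
    sim <- simulate_locus_set(tree, template, cfg)
    locus <- sim$loci[[1L]]
    tr <- sim$truth[[1L]]
    locus$locus_id <- d$locus_id
    tr$locus_id <- d$locus_id
    loci[[d$locus_id]] <- locus
    truth[[d$locus_id]] <- tr
  }
  records <- lapply(loci, call_locus, library = refs$library)
  matrix <- build_matrix(records)
  mapping <- map_markers(matrix, tree)
  support <- branch_support_table(matrix, tree)
  # the six young-SINE copies, extracted back out of their loci
  pitt_ids <- design$locus_id[design$re_class == "SINE-PittSINE"]
  copies <- vapply(pitt_ids, function(id) {
    l <- loci[[id]]
    u <- .ungapped_span(l$rows[[l$ref_taxon]], l$element_span)
    substr(u$seq, u$start + 1L, u$end)
  }, character(1))
  landscape <- family_landscape(copies, refs$pittsine$sequence)
  supermatrix <- concatenate(lapply(loci, strip_elements, drop_tsd = TRUE))
  list(tree = tree, refs = refs, design = design, loci = loci, truth = truth,
       records = records, matrix = matrix, mapping = mapping,
       support = support, landscape = landscape, supermatrix = supermatrix)
}

#' Boundary-recovery benchmark on synthetic tRNA/CR1 chimeras
#'
#' Builds `n` chimeric elements (a random one of the two synthetic tRNA
#' heads plus the CR1-derived tail), decays each, and partitions it against
#' the tRNA and CR1 references; reports boundary error and head-source
#' identification.
#'
#' @param n number of chimeras.
#' @param divergence expected substitutions/site of decay per chimera.
#' @param seed integer seed.
#' @return data.frame: `head_source_true`, `head_source_called`,
#'   `boundary_true`, `boundary_called`, `boundary_error`, `head_correct`.
#' @export
chimera_partition_benchmark <- function(n = 50L, divergence = 0.05,
                                        seed = 1L) {
  refs <- synthetic_references()
  set.seed(seed)
  trna_lib <- c(tRNA_Ile_syn = refs$trna_ile, tRNA_Asp_syn = refs$trna_asp)
  cr1_lib <- c(CR1_syn = refs$cr1_3end)
  tail <- substr(refs$cr1_3end, 401L - refs$tail_length, 400L)
  out <- lapply(seq_len(n), function(i) {
    which_head <- if (i %% 2L == 0L) "tRNA_Ile_syn" else "tRNA_Asp_syn"
    head <- trna_lib[[which_head]]
    chimera <- evolve_sequence(paste0(head, tail), divergence)
    model <- partition_sine(chimera, trna_lib, cr1_lib)
    data.frame(head_source_true = which_head,
               head_source_called = model$head_source,
               boundary_true = nchar(head),
               boundary_called = model$head_span[2L],
               boundary_error = abs(model$head_span[2L] - nchar(head)),
               head_correct = model$head_source == which_head)
  })
  do.call(rbind, out)
}
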