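test_that("evolve_sequence is identity at zero distance and seed-deterministic", {
  expect_identical(evolve_sequence("ACGTACGT", 0, kappa = 2, seed = 1),
                   "ACGTACGT")
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  a <- evolve_sequence(s, 0.2, kappa = 3, seed = 11)
  b <- evolve_sequence(s, 0.2, kappa = 3, seed = 11)
  expect_identical(a, b)
  expect_identical(nchar(a), nchar(s))
  # a different seed gives a different realization
  expect_false(identical(a, evolve_sequence(s, 0.2, kappa = 3, seed = 12)))
})

test_that("evolve_sequence rejects bad input, naming the offending position", {
  expect_error(evolve_sequence("ACGX", 0.1), "position 4")
  expect_error(evolve_sequence("ACGT", -0.1))
  expect_error(evolve_sequence("ACGT", 0.1, kappa = 0))
})

test_that("realized divergence matches the nominal distance (LLN oracle)", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  d <- replicate(200, {
    k2p_distance(s, evolve_sequence(s, 0.10, kappa = 2))$distance
  })
  expect_lt(abs(mean(d) - 0.10), 0.01)
  # within 3 standard errors of the nominal distance
  expect_lt(abs(mean(d) - 0.10), 3 * sd(d) / sqrt(length(d)) + 0.003)
})

test_that("evolved sequences agree with an independent K80 estimator", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  mut <- evolve_sequence(s, 0.08, kappa = 2)
  dd <- ape::dist.dna(ape::as.DNAbin(rbind(a = strsplit(tolower(s), "")[[1]],
                                           b = strsplit(tolower(mut),
                                                        "")[[1]])),
                      model = "K80")
  expect_lt(abs(as.numeric(dd) - 0.08), 0.01)
})

test_that("plant_divergence realizes the requested K2P distance near-exactly", {
  refs <- synthetic_references()
  master <- refs$tgusine1$sequence
  for (d in c(0.03, 0.063, 0.11)) {
    copy <- plant_divergence(master, d, kappa = 2, seed = 5)
    est <- k2p_distance(copy, master, exclude_cpg_in = master)$distance
    expect_lt(abs(est - d), 0.004)
  }
  expect_identical(plant_divergence(master, 0), master)
})

test_that("make_sine_template enforces the terminal microsatellite", {
  trna <- strrep("ACGT", 18)  # 72 nt
  tail_g <- paste0(strrep("GATC", 35), "ATTCTGTG")
  tmpl <- make_sine_template(trna, tail_g, name = "toy")
  expect_s3_class(tmpl, "sine_template")
  expect_identical(nchar(tmpl$sequence), 72L + 148L)
  expect_identical(tmpl$microsat, "ATTCTGTG")
  # motif degeneracy: R = A also accepted
  expect_silent(make_sine_template(trna, paste0(strrep("GATC", 35),
                                                "ATTCTATG")))
  expect_error(make_sine_template(trna, paste0(strrep("GATC", 35),
                                               "AAAAAAAA")),
               "microsatellite")
})

test_that("concordant simulation places the element exactly on the clade", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 5L), flank_length = 120,
                    ils_probability = 0, copy_divergence = 0, seed = 3)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  expect_length(sim$loci, 5L)
  for (tr in sim$truth) {
    expect_false(tr$is_ils)
    expect_identical(unname(tr$per_taxon_state[c("A", "B")]),
                     c("present", "present"))
    expect_identical(unname(tr$per_taxon_state[c("C", "D")]),
                     c("absent", "absent"))
  }
  # zero decay: every inserted copy is the template verbatim
  tmpl <- fixture_template()$sequence
  for (l in sim$loci) {
    row <- l$rows[["A"]]
    span <- l$element_span
    expect_identical(substr(row, span[1] + 1, span[2]), tmpl)
  }
})

test_that("present-taxa sets are clades whenever ils_probability is zero", {
  tr8 <- tree8()
  internal <- setdiff(branch_ids(tr8), tr8$tip.label)
  for (seed in 1:5) {
    cfg <- sim_config(
      n_loci_per_branch = stats::setNames(rep(1L, length(internal)),
                                          internal),
      flank_length = 60, ils_probability = 0, seed = seed)
    sim <- simulate_locus_set(tr8, fixture_template(), cfg)
    clades <- lapply(branch_ids(tr8), clade_tips, tree = tr8)
    for (tr in sim$truth) {
      present <- names(tr$per_taxon_state)[tr$per_taxon_state == "present"]
      expect_true(any(vapply(clades, setequal, logical(1), present)))
    }
  }
})

test_that("forced ILS flags every locus and draws a quartet alternative", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 40L), flank_length = 60,
                    ils_probability = 1, seed = 9)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  alt <- quartet_alternatives(tree4(), "AB")
  for (tr in sim$truth) {
    expect_true(tr$is_ils)
    present <- names(tr$per_taxon_state)[tr$per_taxon_state == "present"]
    expect_true(setequal(present, alt$alt1) || setequal(present, alt$alt2))
  }
  # both alternatives occur over 40 draws
  sets <- vapply(sim$truth, function(tr) {
    paste(sort(names(tr$per_taxon_state)[tr$per_taxon_state == "present"]),
          collapse = ",")
  }, character(1))
  expect_identical(length(unique(sets)), 2L)
})

test_that("TSD copies are exact direct repeats and recorded in the truth", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 4L), flank_length = 100,
                    copy_divergence = 0.08, seed = 21)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  for (id in names(sim$loci)) {
    l <- sim$loci[[id]]
    tsd <- sim$truth[[id]]$tsd_sequence
    t_len <- nchar(tsd)
    row <- l$rows[["A"]]  # present, ungapped
    span <- l$element_span
    left <- substr(row, span[1] - t_len + 1, span[1])
    right <- substr(row, span[2] + 1, span[2] + t_len)
    expect_identical(left, tsd)
    expect_identical(right, tsd)
    expect_gte(t_len, 4L)
    expect_lte(t_len, 20L)
  }
})

test_that("identical config and seed give byte-identical FASTA output", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 3L, ABC = 2L),
                    flank_length = 80, seed = 14)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_locus_set(tree4(), fixture_template(), cfg)
  s2 <- simulate_locus_set(tree4(), fixture_template(), cfg)
  write_locus_set(s1$loci, d1, s1$truth)
  write_locus_set(s2$loci, d2, s2$truth)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("simulate_locus_set validates its inputs", {
  cfg <- sim_config(n_loci_per_branch = c(NOPE = 1L), flank_length = 50)
  expect_error(simulate_locus_set(tree4(), fixture_template(), cfg),
               "NOPE")
  cfg0 <- sim_config(n_loci_per_branch = c(AB = 0L), flank_length = 50)
  expect_error(simulate_locus_set(tree4(), fixture_template(), cfg0),
               "zero loci")
  expect_error(sim_config(n_loci_per_branch = c(AB = 1L),
                          tsd_length_range = c(2, 10)))
  expect_error(sim_config(n_loci_per_branch = c(AB = 1L),
                          ils_probability = 1.5))
})
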