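test_that("detect_tsd finds constructed duplications and prefers the longest", {
  elem <- strrep("N", 0)  # element content is irrelevant to detection
  row <- paste0("AAAACCGGTT", "CCGGTT", strrep("G", 40), "CCGGTT", "GGGG")
  # element occupies the 40 G's: starts after 16, ends before the repeat
  expect_identical(detect_tsd(row, 16L, 56L), "CCGGTT")
  # no repeated flanking string
  row2 <- paste0("ACACACACAC", strrep("G", 20), "TTTTTTTTTT")
  expect_null(detect_tsd(row2, 10L, 30L))
  # nested candidates: the 8-nt repeat wins over the 4-nt one inside it
  row3 <- paste0("TTTT", "ACGGACGG", strrep("C", 12), "ACGGACGG", "TTTT")
  expect_identical(detect_tsd(row3, 12L, 24L), "ACGGACGG")
  expect_identical(detect_tsd(row3, 12L, 24L, max_len = 4L), "ACGG")
})

test_that("detect_tsd warns and returns NULL at sequence boundaries", {
  expect_warning(out <- detect_tsd("ACGTACGT", 0L, 4L), "boundary")
  expect_null(out)
  expect_warning(out2 <- detect_tsd("ACGTACGT", 4L, 8L), "boundary")
  expect_null(out2)
})

test_that("detect_tsd agrees with exhaustive substring search on random loci", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    flank_l <- paste(sample(bases, sample(8:30, 1), replace = TRUE),
                     collapse = "")
    flank_r <- paste(sample(bases, sample(8:30, 1), replace = TRUE),
                     collapse = "")
    elem <- paste(sample(bases, sample(5:20, 1), replace = TRUE),
                  collapse = "")
    tsd <- if (runif(1) < 0.7) {
      paste(sample(bases, sample(4:20, 1), replace = TRUE), collapse = "")
    } else ""
    row <- paste0(flank_l, tsd, elem, tsd, flank_r)
    start <- nchar(flank_l) + nchar(tsd)
    end <- start + nchar(elem)
    got <- detect_tsd(row, start, end)
    want <- oracle_tsd(row, start, end)
    expect_identical(got, want)
  }
})

test_that("classification recovers simulated truth, with empty reasons", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 3L), flank_length = 150,
                    copy_divergence = 0.05, seed = 31)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  for (id in names(sim$loci)) {
    locus <- sim$loci[[id]]
    truth <- sim$truth[[id]]$per_taxon_state
    for (taxon in names(locus$rows)) {
      call <- classify_taxon(locus, taxon, fixture_library())
      expect_identical(call$state, unname(truth[taxon]))
      expect_length(call$reasons, 0L)
      if (call$state == "present") {
        expect_false(is.na(call$left_junction))
        expect_false(is.na(call$right_junction))
        expect_identical(call$subtype, "TguSINE1_syn")
      }
    }
  }
})

test_that("orientation is never silently ignored: a flipped copy is flagged", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 1L), flank_length = 150,
                    copy_divergence = 0.02, seed = 33)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  locus <- sim$loci[[1]]
  span <- locus$element_span
  # reverse-complement the element of the non-reference present taxon
  other <- setdiff(c("A", "B"), locus$ref_taxon)
  row <- locus$rows[[other]]
  elem <- substr(row, span[1] + 1, span[2])
  locus$rows[[other]] <- paste0(substr(row, 1, span[1]), revcomp(elem),
                                substr(row, span[2] + 1, nchar(row)))
  call <- classify_taxon(locus, other, fixture_library())
  expect_identical(call$state, "ambiguous")
  expect_true("orientation_flip" %in% call$reasons)
  rec <- call_locus(locus, fixture_library())
  expect_false(rec$valid)
  expect_true("orientation_flip" %in% rec$failure_reasons)
})

test_that("a subtype mismatch invalidates the marker", {
  refs <- synthetic_references()
  cfg <- sim_config(n_loci_per_branch = c(ABC = 1L), flank_length = 150,
                    copy_divergence = 0.02, seed = 35)
  sim <- simulate_locus_set(tree4(), refs$tgusine1, cfg)
  locus <- sim$loci[[1]]
  span <- locus$element_span
  other <- setdiff(c("A", "B", "C"), locus$ref_taxon)[1]
  row <- locus$rows[[other]]
  # replace this taxon's element by an equally long slice of the LTR
  fake <- substr(strrep(refs$ltr, 2), 1, span[2] - span[1])
  locus$rows[[other]] <- paste0(substr(row, 1, span[1]), fake,
                                substr(row, span[2] + 1, nchar(row)))
  rec <- call_locus(locus, refs$library)
  expect_false(rec$valid)
  expect_true("subtype_mismatch" %in% rec$failure_reasons)
})

test_that("missing taxa are ambiguous, never absent; validity is monotone", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 1L), flank_length = 150,
                    seed = 37)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  locus <- sim$loci[[1]]
  rec <- call_locus(locus, fixture_library())
  expect_true(rec$valid)
  # add a taxon with no sequence at all
  locus$rows[["E"]] <- strrep("?", nchar(locus$rows[[1]]))
  call <- classify_taxon(locus, "E", fixture_library())
  expect_identical(call$state, "ambiguous")
  expect_identical(call$reasons, "missing_sequence")
  rec2 <- call_locus(locus, fixture_library())
  expect_true(rec2$valid)  # an ambiguous taxon cannot invalidate a marker
})

test_that("validate_marker needs 3+ calls and flags uninformative loci", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 1L), flank_length = 150,
                    seed = 39)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  locus <- sim$loci[[1]]
  calls <- lapply(names(locus$rows), classify_taxon, locus = locus,
                  library = fixture_library())
  expect_error(validate_marker(locus, calls[1:2]), "3 taxa")
  # erase everything: all taxa ambiguous -> uninformative
  blank <- lapply(calls, function(cl) { cl$state <- "ambiguous"; cl })
  rec <- validate_marker(locus, blank)
  expect_false(rec$valid)
  expect_true("uninformative" %in% rec$failure_reasons)
})

test_that("classify_taxon errors on unknown taxa", {
  cfg <- sim_config(n_loci_per_branch = c(AB = 1L), flank_length = 100,
                    seed = 41)
  sim <- simulate_locus_set(tree4(), fixture_template(), cfg)
  expect_error(classify_taxon(sim$loci[[1]], "nope", fixture_library()),
               "nope")
})

test_that("discover_candidates recognizes a constructed empty site", {
  set.seed(51)
  bases <- c("A", "C", "G", "T")
  flank_l <- paste(sample(bases, 300, replace = TRUE), collapse = "")
  flank_r <- paste(sample(bases, 300, replace = TRUE), collapse = "")
  tsd <- "CATTAG"
  elem <- fixture_template()$sequence
  ingroup <- paste0(flank_l, tsd, elem, tsd, flank_r)
  outgroup <- paste0(flank_l, tsd, flank_r)  # pristine single target site
  ann <- data.frame(name = "m1", start = 306L, end = 306L + nchar(elem))
  res <- discover_candidates(ingroup, ann, outgroup, flank_len = 300)
  expect_true(res$candidate)
  expect_identical(res$reason, "empty_site")
  # the two flank hits overlap by about the single target-site copy
  expect_lte(abs(res$out_gap), 2L * nchar(tsd) + 4L)
  # outgroup missing the right flank: no candidate
  res2 <- discover_candidates(ingroup, ann, paste0(flank_l, tsd),
                              flank_len = 300)
  expect_false(res2$candidate)
  expect_identical(res2$reason, "flank_unmapped")
  # flanks on opposite strands are rejected
  res3 <- discover_candidates(ingroup, ann,
                              paste0(flank_l, tsd, revcomp(flank_r)),
                              flank_len = 300)
  expect_false(res3$candidate)
  # an outgroup that also carries the element is not an empty site
  res4 <- discover_candidates(ingroup, ann, ingroup, flank_len = 300)
  expect_false(res4$candidate)
  expect_identical(res4$reason, "site_occupied")
})

test_that("discover_candidates recovers simulated loci at 5% divergence", {
  tr2 <- label_nodes(ape::read.tree(text = "(In:0.025,Out:0.025)R;"))
  cfg <- sim_config(n_loci_per_branch = c(In = 20L), flank_length = 300,
                    copy_divergence = 0.02, seed = 53)
  sim <- simulate_locus_set(tr2, fixture_template(), cfg)
  hits <- 0L
  for (id in names(sim$loci)) {
    locus <- sim$loci[[id]]
    span <- locus$element_span
    ingroup <- locus$rows[["In"]]                    # ungapped, present
    outgroup <- gsub("-", "", locus$rows[["Out"]])   # empty site
    ann <- data.frame(name = id, start = span[1], end = span[2])
    res <- discover_candidates(ingroup, ann, outgroup, flank_len = 250)
    hits <- hits + res$candidate
  }
  expect_gte(hits, 19L)
})
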