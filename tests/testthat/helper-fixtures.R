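# Shared fixtures: tiny trees, a reusable SINE template, and independent
# oracles (brute-force TSD search, exhaustive polytomy-null enumeration,
# independent K2P closed-form evaluation).

tree4 <- function() {
  label_nodes(ape::read.tree(
    text = "(((A:0.02,B:0.02)AB:0.02,C:0.04)ABC:0.02,D:0.06)R;"))
}

tree4_flat <- function() {
  label_nodes(ape::read.tree(text = "(((A:0,B:0)AB:0,C:0)ABC:0,D:0)R;"))
}

# an 8-taxon balanced tree with short branches
tree8 <- function() {
  label_nodes(ape::read.tree(text = paste0(
    "(((t1:0.01,t2:0.01)n12:0.01,(t3:0.01,t4:0.01)n34:0.01)n14:0.01,",
    "((t5:0.01,t6:0.01)n56:0.01,(t7:0.01,t8:0.01)n78:0.01)n58:0.01)R;")))
}

fixture_template <- function() synthetic_references()$tgusine1

fixture_library <- function() synthetic_references()$library

# Brute-force TSD oracle: longest s with min_len <= |s| <= max_len such
# that s immediately precedes element_start and begins at element_end.
# Written as an exhaustive scan over all lengths, independent of detect_tsd.
oracle_tsd <- function(row, start, end, max_len = 20L, min_len = 4L) {
  best <- NULL
  n <- nchar(row)
  for (len in min_len:max_len) {
    if (len > start || end + len > n) next
    s1 <- substring(row, start - len + 1L, start)
    s2 <- substring(row, end + 1L, end + len)
    if (identical(s1, s2)) best <- s1
  }
  best
}

# Exhaustive polytomy-null oracle: enumerate all 3^n assignments of n
# markers to the three quartet resolutions and take the fraction with at
# least n1 falling on the first.
oracle_polytomy_p <- function(n1, n2, n3) {
  n <- n1 + n2 + n3
  if (n == 0L) return(1)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  mean(rowSums(grid == 1L) >= n1)
}

# Independent K2P evaluation: count transitions/transversions with a purine
# lookup, then the closed form, no shared code with k2p_distance().
oracle_k2p <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[ok]; vb <- vb[ok]
  purine <- function(x) x %in% c("A", "G")
  d <- va != vb
  ts <- d & (purine(va) == purine(vb))
  P <- sum(ts) / length(va)
  Q <- sum(d & !ts) / length(va)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# random mutated pair for oracle tests: seq plus iid random substitutions
random_pair <- function(n = 300L, rate = 0.1) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n, replace = TRUE)
  b <- a
  hit <- runif(n) < rate
  b[hit] <- vapply(b[hit], function(x) sample(setdiff(bases, x), 1L),
                   character(1))
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# fabricate a minimal marker_record for matrix-level tests
fake_record <- function(locus_id, states, valid = TRUE,
                        re_class = "CR1", reasons = character(0)) {
  calls <- lapply(names(states), function(t) {
    structure(list(taxon = t, state = states[[t]], reasons = character(0)),
              class = "insertion_call")
  })
  structure(list(locus_id = locus_id, calls = calls, valid = valid,
                 re_class = re_class, failure_reasons = reasons),
            class = "marker_record")
}

# presence/absence matrix straight from simulation truth records
truth_matrix <- function(truth) {
  taxa <- names(truth[[1]]$per_taxon_state)
  m <- vapply(truth, function(tr) {
    unname(c(present = "1", absent = "0")[tr$per_taxon_state[taxa]])
  }, character(length(taxa)))
  rownames(m) <- taxa
  colnames(m) <- vapply(truth, `[[`, character(1), "locus_id")
  m
}
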