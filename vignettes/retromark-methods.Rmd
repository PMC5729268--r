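---
title: "Retroposon presence/absence markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retroposon presence/absence markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromark)
```

# The problem

Retroposon insertions — SINEs, CR1-type LINEs, LTR elements — are rare
genomic changes: an element inserts once at an orthologous locus and is
essentially never excised precisely. The presence of the element in some
species and a pristine *empty site* (a single copy of the target sequence)
in others is therefore a nearly homoplasy-free phylogenetic character. In
birds these markers are precious because avian SINEs are scarce; in
passerines, two chimeric tRNA-head/CR1-tail SINE families were active only
during a narrow window of early diversification, which makes their
presence/absence patterns informative exactly for the deepest branches.

`retromark` implements the complete analysis around such markers:

1. **simulate** — synthetic marker loci with full truth tables;
2. **markers** — locus discovery and strict per-taxon state calling;
3. **phylo** — presence/absence matrix, Dollo mapping, conflict detection,
   polytomy-null branch support;
4. **anatomy** — SINE family consensus, head/tail partition, diagnostic
   sites, terminal microsatellite;
5. **landscape** — CpG-excluded Kimura 2-parameter divergence landscapes;
6. **concat** — element-stripped flank supermatrix for external tree
   inference.

# Marker validity: automating a by-eye protocol

A marker is accepted only when all presences share (i) the orthologous
insertion point, (ii) the element orientation, (iii) the element subtype,
(iv) identical target-site duplications (TSDs) where detected, and (v) at
least one taxon shows a clean empty site. The original protocol applies
these criteria by manual inspection of alignments; `retromark` replaces
eyes with explicit numeric surrogates, all configurable:

* *presence* needs at most 10% gap characters inside the annotated element
  span; *absence* needs at least 90%, plus contiguous flanks (at least
  half the 30 columns on each side of the span must be sequence);
* junctions (first/last occupied columns of the span) must agree with the
  reference taxon within ±2 columns;
* subtype and orientation come from the best local-alignment hit against a
  reference element library (match +1, mismatch −1, gap open −5, gap
  extend −1; ties broken by library order);
* TSDs are compared by exact string equality, and the criterion is skipped
  when either taxon's TSD is undetected ("if present");
* taxa with no sequence are *ambiguous*, never absent — so a missing
  genome can weaken but not fabricate evidence. Criterion violations
  (junction shift, subtype mismatch, orientation flip, TSD mismatch)
  invalidate the marker; soft ambiguity does not. This makes validity
  monotone: adding an ambiguous taxon cannot invalidate a marker.

TSD detection returns the longest exact direct repeat (4–20 nt) that ends
at the element start and restarts at the element end. Because a candidate
of shorter-than-true length compares a shifted window of the duplication
against itself, partial repeats only match for periodic TSDs; in practice
the detector finds either the full duplication or nothing, which is why
the "identical TSD" criterion is skipped rather than failed when decay has
erased one copy. A TSD overlapping the terminal microsatellite can be
genuinely ambiguous; the detector reports what it finds and leaves the
interpretation to the caller.

# Dollo mapping and the polytomy test

Under Dollo parsimony a marker gained once and never regained must have
its presence taxa form a clade. `map_markers()` checks every branch: a
marker maps to branch *b* when its 1-taxa equal the clade of *b*
restricted to scored taxa and no 0-taxon falls inside the clade. "?"
entries can leave several nested branches compatible; all are reported and
the most recent is chosen, mirroring the practice of substituting a
related taxon for a missing one. A marker compatible with no branch is a
*conflict* — hemiplasy (incomplete lineage sorting) or, rarely, true
homoplasy — and is only flagged, never resolved automatically.

Branch support uses a hard-polytomy null: if a branch were a polytomy,
each marker would fall on one of the three quartet resolutions with
probability 1/3. With `n1` markers on the branch and `n2`, `n3` on the
alternatives, the p-value is the exact binomial tail
P(X ≥ n1), X ~ Binomial(n1+n2+n3, 1/3), computed as an exact sum. This is
a deliberately simple, enumeration-checkable surrogate for the
likelihood-based insertion-marker tests in the literature; the
`branch_support_test(n1, n2, n3)` interface accepts a drop-in replacement.

# Divergence with CpG exclusion

Element copies decay neutrally after insertion, so the Kimura 2-parameter
distance of each copy to the family consensus is a clock-like proxy for
insertion age, and the histogram of copy distances (the *landscape*) reads
as an activity profile through time. With transition fraction P and
transversion fraction Q over compared sites,

$$d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Rates are uniform across sites. Columns where either sequence has a gap or
ambiguity are excluded pairwise. CpG dinucleotides are methylation
hotspots whose elevated transition rate would inflate distances, so both
positions of every CpG *in the consensus* are excluded before counting —
full exclusion, rather than down-weighting, because it is exactly
reproducible. When the log argument is non-positive the estimator is
undefined and the package raises an explicit "saturated" error (a dropped,
warned-about copy in `family_landscape()`), never a silent `NaN`.

# The simulator

`simulate_locus_set()` is the generative conjugate of the estimators
above. Flanks evolve along a rooted tree under the Kimura two-parameter
substitution process (equal base frequencies; transition/transversion
rate ratio κ, default 2), so the K2P estimator is consistent for the
branch lengths used. Design choices, each made to keep the simulated
truth exactly knowable:

* **No indels in flanks.** Alignments are column-true by construction;
  alignment inference is out of scope, so simulated "alignments" must not
  need aligning.
* **Insertion at the flank midpoint**, as gap columns in absence taxa.
* **TSD model.** At the insertion node, the duplication copies the last
  4–20 nt (drawn uniformly from the configured range, default 6–12 nt) of
  the left flank. The target site and its duplicate are then held fixed
  below the insertion node; element decay is governed solely by
  `copy_divergence`. This makes the TSD criterion's truth value
  deterministic — left and right copies are exact repeats, and all
  present taxa share the same TSD — at the cost of ignoring second-order
  post-insertion drift in those ≤20 columns.
* **ILS model.** With probability `ils_probability` a marker's presence
  set is drawn from the two discordant resolutions of the insertion
  branch's local quartet (children clades X, Y; sister S; alternatives
  X∪S and Y∪S). This reproduces the one conflict type observed in deep
  passerine marker sets. Terminal branches have no local quartet, so an
  ILS draw there is ignored.
* **Planted decay.** Besides stochastic K80 decay, `plant_divergence()`
  realizes a requested K2P distance exactly (up to count rounding) by
  solving the closed form for (P, Q) at the chain's transition/
  transversion ratio and planting those counts at non-CpG sites. Small
  families (six copies of a ~220-nt element) have sampling noise larger
  than the precision one wants from a designed benchmark; planting
  removes that noise without touching the estimator.

What the simulator does **not** emulate: insertion-site preference,
flank indels and alignment error, precise excision, sequencing/assembly
artifacts, and rate variation among sites or lineages. Tests passing on
synthetic data therefore validate the *logic* of calling, mapping and
distance estimation — not robustness to alignment error, which the manual
inspection step of a real study addresses.

# The synthetic study benchmark

`synthetic_passerine_study()` packages the pipeline's end-to-end exercise
at realistic study conditions: 12 taxa (two outgroups, the New Zealand
wren lineage, three suboscines, six oscines); 44 markers — 19 of the
older tRNA-Ile-headed SINE family, 6 of the younger tRNA-Asp-headed
family confined to the Old World suboscine tip, 13 CR1 and 6 LTR — placed
on the stem branches such a study resolves; exactly one marker on the
suboscine stem drawn discordantly (the incomplete-lineage-sorting case);
per-side flank lengths varying 150–360 nt and summing so the
element-stripped supermatrix is 22,410 columns; and six young-SINE copies
with planted divergences {0, 3.0, 5.8, 8.0, 10.0, 11.0}% — range 0–11%,
mean 6.3%. Every sequence is synthetic (fixed-seed random tRNA heads, CR1
3′ end with the terminal ATTCTRTG microsatellite, four planted diagnostic
tail sites shared by the two SINE families plus two private substitutions
each); the *numbers* are the study design the pipeline must reproduce
from raw simulated alignments.

```{r study, eval = FALSE}
study <- synthetic_passerine_study(seed = 1)
sum(vapply(study$records, `[[`, logical(1), "valid"))  # 44
subset(study$mapping, conflict)                        # synTgu10 only
study$landscape                                        # mean ~6.3%, 0-11%
supermatrix_width(study$supermatrix)                   # 22410
```

# Numerical and interface conventions

* Coordinates are 0-based half-open alignment columns everywhere inside
  the package; the RAxML partition writer converts to 1-based inclusive.
* Consensus ties use IUPAC ambiguity codes; a column is emitted only when
  more than half the copies are non-gap.
* Head/tail partition: the boundary is the midpoint of the gap between
  the best tRNA and best CR1 hit spans (or of their overlap); a hit below
  score 20 (about the score a ~70-nt random match cannot reach) makes the
  consensus "unpartitionable" rather than silently mis-partitioned.
* Missing taxa are padded with `?` in the supermatrix to distinguish
  missing data from indels; TSD-duplicate columns are kept by default
  when stripping (`drop_tsd = TRUE` removes them).
* Empty-site discovery tolerates up to 25 nt of overlap between the two
  mapped flanks, because at a true empty site both flanks share the
  single copy of the target sequence.
* All randomness flows through explicit integer seeds; identical
  configuration and seed give byte-identical FASTA output.

# Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations for a
single CPU: 100 mixed loci (plus 20 zero-divergence loci) for calling
recovery, 200 replicates of a 5,000-nt sequence for divergence
consistency, 1,000 random pairs for the closed-form oracle, exhaustive
enumeration to n = 8 for the polytomy test, a 20-seed sweep for Dollo
soundness, the 44-marker synthetic study, and 50 chimeras for boundary
recovery. These sizes were chosen so each law-of-large-numbers tolerance
sits several standard errors away from its threshold.

# Known limitations

* The validity thresholds are surrogates for expert inspection; on real,
  indel-rich alignments they are a starting point, not a replacement for
  curation.
* The polytomy-null branch test ignores marker non-independence and
  ascertainment; it is a screening statistic.
* CpG exclusion uses consensus CpGs only; hypermutable sites arising in
  copies are not excluded.
* Subtype assignment trusts the supplied library; paralogous or chimeric
  library entries will confuse the best-hit rule.
* The simulator's frozen target site slightly understates TSD mismatch
  rates at very deep divergences.
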