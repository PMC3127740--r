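---
title: "Methods: strand asymmetry, 5'-nucleotide composition, and duplex covariation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand asymmetry, 5'-nucleotide composition, and duplex covariation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirasym)
```

# The problem

Animal miRNAs are excised from hairpin precursors (pre-miRNAs) as a
miRNA/miRNA\* duplex; only one strand of each duplex — the miRNA, or guide —
is stably loaded into the RNA-induced silencing complex, while the passenger
(miRNA\*) is discarded. Mature miRNAs have one conspicuous sequence bias: a
uridine at their first (5') position. `mirasym` implements the informatics
needed to ask, from small-RNA sequencing tag counts alone, whether that 5'-U
is a signal read *after* processing — i.e. whether it tracks how asymmetric
the loading of the two strands is — and which sequence or structural features
of the duplex covary with the identity of the first miRNA nucleotide.

The package runs entirely from three plain-text inputs: precursor sequences
(FASTA), mature-arm coordinates (miRBase-dialect GFF3 or TSV), and tag-count
libraries (sequence + read count). A synthetic-cohort generator with a
ground-truth ledger stands in for external data so that every stage is
testable offline.

# Quantification model

**Isoform profiling.** A tag is assigned to an arm of a hairpin iff it is an
exact substring of the hairpin whose 5' end lies within `arm_window`
(default 5 nt) of the annotated arm start. Matching is exact and
sense-strand-only: small-RNA libraries are directional, isomiR 5' ends
wander only a few nucleotides, and mismatched or trimmed tags are rare
enough to log rather than model. Multi-mapping tags count fully toward every
matching hairpin, because each hairpin is analyzed independently; fractional
assignment would introduce an uncited model.

**Strand designation.** The miRNA is the arm with the larger pooled read
count (tie: 5p). Annotation-supplied guide labels can override abundance via
`designate_strands(..., mirna_arms =)` when a fixed external nomenclature is
preferred; both modes are exposed because reference-based and
abundance-based labels can disagree for near-symmetric duplexes.

**Depth filter.** Duplexes whose pooled hairpin total is below `min_reads`
(default 100) are dropped. The threshold is applied per hairpin by default;
`per_strand = TRUE` applies it to each strand, the stricter reading.

**Asymmetry bins.** With `ratio = miRNA count / miRNA* count`, bins are
`highly_asymmetric` (ratio >= 10), `moderately_asymmetric` (ratio in
[2, 10)) and `quasisymmetric` (ratio in [1, 2)). The half-open [2, 10) is
used so that the three bins partition [1, Inf]; with the alternative open
interval (2, 10), a duplex at exactly ratio 2 would belong to no bin.

# The composition statistic and its null

The statistic is a two-level weighting: within a hairpin, the nt-1
distribution of a strand's isoforms is weighted by isoform read counts and
normalized; across hairpins, every hairpin-strand counts equally. Abundant
hairpins therefore do not dominate the cross-hairpin signal, while abundant
isoforms rightly dominate within a hairpin.

The null asks: is the 5' nucleotide distribution just the strand's overall
composition? `resample_background()` builds `n_sets` (default 100) random
frequency vectors; in each set, every hairpin-strand contributes exactly one
nucleotide, drawn by sampling an isoform with probability proportional to
its count and then a position uniformly from the window (default nt 1-18,
truncated for shorter isoforms with a message). Each random set thus has
exactly the size and the weighting of the observed set of 5' nucleotides.
One draw per hairpin-strand per set (rather than one per read) is chosen
because the observed statistic also gives each hairpin-strand a single unit
of weight.

Two p values are always reported, per nucleotide and one-sided in the
direction of the observed deviation (a `two.sided` option doubles the tail):

* `p_empirical = (1 + #{sets at least as extreme}) / (n_sets + 1)`. The +1
  pseudocount means finite resampling can never report p = 0; the smallest
  attainable value is 1/(n_sets + 1).
* `p_gaussian`: the normal tail at `z = (obs - mean) / sd` of the resampled
  values. 100 resamples cannot resolve p values many orders of magnitude
  below 1/101, but the resample mean and spread are well estimated, so a
  Gaussian tail reproduces the magnitude of extremely small p values while
  staying tied to the same null. Both variants are labeled in all output;
  when the observed value equals the resample mean both report 0.5, and a
  zero resample spread with a deviating observation reports p_gaussian = 0
  with a warning.

**Flanking-U profile.** For hairpins passing the depth filter, the U
frequency is measured at each offset in -10..+10 on the precursor, with
offset 0 anchored at the most abundant miRNA isoform's first nucleotide
(the same "top isoform" rule the structural analysis uses). The background
is the U frequency in 100 random draws of one in-bounds position per hairpin
from its 21-nt segment; the interval is the empirical 2.5/97.5 percentile of
the set means. Offsets falling outside a hairpin are skipped for that
hairpin.

# The duplex structure engine

The covariation analysis needs one bit per nucleotide: paired or unpaired at
pairing probability > 0.5 (strictly; a position at exactly 0.5 is unpaired).
The builtin engine computes exact pair probabilities by an inside-outside
dynamic program over all non-crossing, intermolecular-only pairings of the
two strands — at duplex-forming conditions a ~21-nt strand has little room
for intramolecular structure — with Watson-Crick and G:U pairs and a simple
additive score:

* pair scores: G:C +3, A:U +2, G:U +1 (score units; roughly 1 unit per
  kcal/mol of stack stability);
* internal unpaired regions: -0.5 per unpaired nucleotide, plus a bulge
  surcharge of -3 when the region is one-sided;
* terminal unpaired runs free; Boltzmann weight `exp(score / scale)`,
  `scale = 1`.

The bulge surcharge deserves a note, because a flat per-run or
per-nucleotide penalty is *structurally unable* to assign the correct end
register of a natural duplex. For the miR-2a/miR-2a-1\* worked example the
correct register leaves the miRNA* 3' dinucleotide overhanging (nt 1 facing
miRNA* position 19); a competing register pairs nt 1 to the terminal G of
the overhang via a G:U wobble and bridges back with a 2-nt bulge. The
wobble register gains one pair and spends one loop region, so any scoring
that prices a 2-nt bulge like a 1x1 internal loop prefers it — but
nearest-neighbor thermodynamics prices bulges at roughly twice a symmetric
loop (~2.8-3.8 kcal/mol), and the full co-folding ensemble gives the wobble
register no weight. With the bulge surcharge at the thermodynamic magnitude
the engine reproduces the published register call. All parameters sit in
`duplex_scores()` and are echoed in the run manifest.

The engine is validated against exhaustive enumeration of every non-crossing
pairing for strand lengths up to 6 (tolerance 1e-9), satisfies per-position
probability conservation, and is transpose-symmetric in its arguments. Full
nearest-neighbor co-folding (e.g. RNAcofold) can be substituted through the
external-engine adapter, which ingests a `pos_a`/`pos_b`/`prob` table and
enforces the same conservation contract. Note that under full Turner rules
the terminal base pair of a duplex breathes (its equilibrium pairing
probability can fall below 0.5 even when the register is unambiguous); the
simplified intermolecular-only ensemble is what makes the threshold call at
nt 1 stable, which is precisely its role here.

# The covariation scan

Each duplex (top isoform of each strand) is encoded as 144 categorical
features: for each strand (miRNA, miRNA\*), each anchor (counting from the
5' or the 3' end) and positions 1..18 — nucleotide identity (72 features)
and base-pairing status (72 features). Positions beyond a strand's length
are missing, not absent: the vector always has length 144, and duplexes
with a missing value at a feature are dropped pairwise for that feature
only. The miRNA 5'-anchor identity at position 1 is the nt-1
self-correlation and is reported like every other feature, as the published
presentation does.

Each feature is tested against miRNA nt-1 identity with Fisher's exact
test, two-sided by the minimum-likelihood convention (the p value sums the
probabilities of all margin-compatible tables no more probable than the
observed one — the convention of standard r x c exact implementations;
conventions differ, so it is stated). Dispatch:

* 2 x c tables with a small composition space: direct enumeration
  (`exact_2xc`);
* other tables whose margin-constrained space is below `max_tables`
  (default 1e6, assessed by the cheap per-column bound
  `prod(choose(c_j + r - 1, r - 1))`; an exact table count would cost more
  than the test): the exact network algorithm (`exact_network`);
* otherwise margin-preserving Monte-Carlo (Patefield's algorithm,
  `monte_carlo`), `p = (1 + #as-or-more-extreme) / (1 + n_mc)`, reproducible
  given a seed. The smallest attainable Monte-Carlo p is 1/(n_mc + 1);
  self-correlations sit at that floor.

Full 4-level nt-1 tables are the default; `collapse_nt1 = TRUE` tests U
vs non-U. Raw p values are reported (144 curves are read jointly, as in the
published figure); a Bonferroni column is emitted alongside for users who
want a corrected threshold.

# The synthetic cohort: a stated world

`synthetic_params()` fixes the world the tests run in:

* 64-nt hairpins carrying two 22-nt arms around a loop. The loop length is
  derived as `hairpin_len - 2 * mature_len` (20 by default) so that the
  stated hairpin length holds exactly; it is configurable through
  `hairpin_len`.
* strand bodies uniform over A/C/G/U; miRNA nt-1 distribution defaulting to
  65% U (fly-like), miRNA\* nt-1 U-depleted (20%);
* miRNA:miRNA\* ratio log-normal with median 20 and sdlog 1.8, reflected at
  1 (draws below 1 flip strand designation rather than produce ratios < 1).
  This yields roughly 65/27/8% highly/moderately/quasisymmetric duplexes —
  the same shape as the published 79/33/10 split — and
  `expected_bin_props()` gives the implied proportions in closed form for
  recovery tests;
* per-hairpin depth log-normal with median 1000 and sdlog 1.5, so ~6% of
  hairpins fall below the 100-read filter (the filter boundary is
  exercised, not avoided);
* isoform 5' jitter 0.2 (shifts of +-1 nt at 0.35 x jitter each, +-2 at
  0.15 x jitter);
* miRNA\* built complementary to the miRNA position-by-position with
  probability 0.9, mismatches drawn from the non-pairing nucleotides, so
  duplexes are realistically mostly-paired with occasional internal
  mismatches;
* an optional injected dependency between miRNA nt 1 and a chosen miRNA
  5'-anchor feature (identity at a position, or pairing status via the
  facing miRNA\* nucleotide), for generator-truth recovery tests.

Everything sampled is recorded in a truth ledger, and the whole cohort is
bit-reproducible from one seed. The generator deliberately does **not**
model sequencing error, adapter artifacts, cross-mapping between hairpins,
2-nt Dicer overhangs, or central-mismatch biology: a green test establishes
that the statistics recover what the generative model put in, not that the
biology of any particular organism is reproduced.

Two calibration-specific choices:

* *Parameter recovery runs with jitter off.* Under 5' jitter, shifted
  isoforms genuinely start with different nucleotides, so the read-weighted
  nt-1 frequency estimates a mixture, not the designed nt-1 probability.
  The recovery test asks whether the estimator recovers the parameter, so
  the scenario makes the parameter the estimand.
* *The independence null for the covariation scan redraws nt-1 labels.* In
  any physically sensible generator the miRNA\* nucleotide facing nt 1 is
  complementary to it most of the time — features are mechanically coupled
  to nt 1 through base pairing. "All features independent of nt 1" is
  therefore realized by permuting the nt-1 labels across duplexes, which
  preserves every feature marginal while breaking all dependence; this is
  the canonical permutation null for a scan.

# Numerical choices and edge cases

* Frequencies sum to 1 within 1e-9; probability conservation of the duplex
  engine is exact by construction and tested at 1e-9.
* Top-isoform ties break toward the isoform starting closest to the
  annotated arm start, then 5'-most; strand-designation ties break to 5p.
  Both rules are deterministic so reruns are byte-identical.
* The pairing call is strict (`> 0.5`), so a probability of exactly 0.5 is
  unpaired.
* Degenerate contingency tables (one non-empty row or column) report p = 1
  with a warning rather than failing a scan.
* Monte-Carlo tie handling compares log-probabilities with a 1e-7 slack so
  that tables identical to the observed one count as "as extreme".
* All randomness flows through explicit seeds (`withr::with_seed`); no
  function touches the global RNG state.

# Limitations

* The builtin energy model is deliberately minimal; absolute pair
  probabilities are not thermodynamic quantities, only the thresholded
  calls are consumed, and the external adapter exists for users who need
  tool-faithful ensembles.
* Exact substring matching ignores non-templated additions and sequencing
  errors; heavily edited libraries will inflate the unmatched tally (which
  is logged per run).
* Fisher p values on discrete tables are conservative; uniformity of null
  scan p values holds approximately, which is why the calibration tests use
  tolerance bands rather than exact uniformity.
* The headline percentages of the motivating analyses derive from ~90
  pooled public libraries and a specific annotation release; reproducing
  those exact numbers requires those inputs, which the package accepts but
  does not fetch.
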