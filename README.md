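# mirasym

Strand-loading asymmetry and 5'-nucleotide composition analysis for
miRNA/miRNA\* duplexes, from small-RNA sequencing tag counts.

Animal miRNAs are excised from hairpin precursors as a miRNA/miRNA\* duplex;
only the guide strand is retained in the silencing complex, and mature
miRNAs tend to begin with a 5' uridine. `mirasym` asks, from tag counts
alone, whether the 5'-U bias is read after processing — does it track
loading asymmetry rather than the arm of origin? — and which duplex
sequence/structure features covary with the first miRNA nucleotide. It is
aimed at small-RNA informaticians who have hairpin annotations and
tag-count libraries and want these analyses reproducible and testable
offline.

## What it computes

* **Quantification** — exact-substring isoform profiles per hairpin arm,
  abundance-based miRNA/miRNA\* designation, the `>= 100` pooled-read
  filter, and asymmetry bins on the ratio r = miRNA/miRNA\*:
  highly asymmetric (r >= 10), moderately asymmetric (2 <= r < 10),
  quasisymmetric (r < 2).
* **Composition statistic** — abundance-weighted 5'-nucleotide frequencies
  f = (f_A, f_C, f_G, f_U) with per-hairpin equal weighting, a resampling
  null of 100 random sets drawn from nt 1-18 (each set the same size and
  weighting as the observed set of 5' nucleotides), and per-nucleotide
  one-sided p values: empirical, p = (1 + #extreme)/(n_sets + 1), and a
  Gaussian tail at z = (obs − mean)/sd of the resamples.
* **Duplex structure** — exact intermolecular base-pair probabilities from
  an inside-outside partition function over non-crossing pairings
  (Watson-Crick + G:U, additive scores, bulge-aware loop penalties);
  paired/unpaired calls at probability > 0.5.
* **Covariation scan** — 144 features per duplex (identity and pairing
  status at positions 1-18 from each end of each strand) tested against
  miRNA nt-1 identity with Fisher's exact test (exact enumeration, network
  algorithm, or seeded Patefield Monte-Carlo, chosen automatically).
* **Flanking profile** — precursor U frequency at offsets −10..+10 around
  the miRNA 5' end, with a resampled background and 95% interval.
* **Synthetic cohorts** — a generator with controllable asymmetry, depth,
  5'-nt composition, isoform jitter and an injectable nt1→feature
  dependency, plus a ground-truth ledger; every pipeline stage runs with no
  external data.

## Worked example

A classic duplex: miR-2a and miR-2a-1\* (the guide begins with U; its first
nucleotide faces position 19 of the star strand, leaving the usual 2-nt 3'
overhang).

```r
library(mirasym)

mir2a  <- "UAUCACAGCCAGCUUUGAUGAGC"   # guide, 23 nt
star   <- "UCUCAAAGUGGUUGUGAAAUG"     # passenger, 21 nt
m <- pair_probabilities(mir2a, star)
s <- pairing_status(m, threshold = 0.5)
s$paired_a[1]
#> [1] TRUE
s$partner_a[1]
#> [1] 19
```

The engine calls nt 1 paired, to star position 19 — the annotated register.
An end-to-end run on a synthetic cohort:

```r
dir <- tempfile(); out <- file.path(dir, "reports")
cohort <- generate_cohort(synthetic_params(n_hairpins = 50, seed = 1))
paths <- write_cohort(cohort, dir)
res <- run_pipeline(pipeline_config(
  hairpin_fasta = paths[["hairpin_fasta"]],
  mature_coords = paths[["mature_coords"]],
  tag_counts    = paths[["tag_counts"]],
  out_dir = out, seed = 1))

subset(res$composition, stratum == "all" & strand_class == "miRNA" & nt == "U",
       c(observed, resample_mean, p_empirical, p_gaussian))
#>    observed resample_mean p_empirical   p_gaussian
#> 4 0.5862197     0.2294737  0.00990099 3.740699e-10
```

The miRNA strands' observed 5'-U frequency (0.59 here; the generator's
default is 65% U) far exceeds the nt 1-18 background (~0.23): the empirical
p sits at its floor 1/101 and the Gaussian tail shows the magnitude. The
report directory contains `duplexes.tsv`, `composition.tsv`,
`structure.tsv`, `covariation.tsv` (144 rows, ordered for plotting the
identity and pairing curves), `flanking.tsv`, `manifest.json` and
`log.txt`; reruns with the same config and seed are byte-identical.

A command-line entry point with the same stages is installed as
`exec/mirasym` (subcommands `simulate`, `quantify`, `composition`,
`structure`, `covariation`, `all`, sharing one flat key=value config).

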