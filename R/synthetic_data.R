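# Synthetic cohort generator: hairpins, mature arms, read libraries and a
# ground-truth ledger, emulating the statistical structure the pipeline
# analyzes (read-depth spread straddling the 100-read filter, isoform 5'
# jitter, controllable strand asymmetry and 5'-nt composition, and an
# injectable dependency between miRNA nt 1 and a chosen duplex feature).
# Sequencing error, adapters and cross-mapping are deliberately not modeled.

#' Parameters for the synthetic cohort generator
#'
#' Defaults sketch a fly-like cohort: most mature strands start with U, miRNA*
#' strands are U-depleted at their 5' end, the asymmetry ratio is log-normal
#' with median 20 (about 65% of duplexes highly asymmetric, ~8% quasi-
#' symmetric) and per-hairpin depth is log-normal with median 1000, straddling
#' the 100-read filter.
#'
#' @param n_hairpins number of hairpins to generate.
#' @param hairpin_len precursor length; the loop length is
#'   `hairpin_len - 2 * mature_len` and must be >= 1.
#' @param mature_len mature strand length.
#' @param body_nt_probs nucleotide distribution of strand bodies (A,C,G,U).
#' @param mirna_nt1_probs,star_nt1_probs nt-1 distributions per strand class.
#' @param asymmetry_meanlog,asymmetry_sdlog log-normal law of the miRNA:miRNA*
#'   ratio; draws below 1 are reflected (1/x) so the designated ratio is >= 1.
#' @param depth_meanlog,depth_sdlog log-normal law of per-hairpin read totals.
#' @param isoform_jitter probability that a read comes from a 5'-shifted
#'   isoform (+-1 nt at 0.35 x jitter each, +-2 nt at 0.15 x jitter each).
#' @param complementarity per-position probability that the star strand is
#'   Watson-Crick complementary to the miRNA; mismatches are random
#'   non-complementary nucleotides.
#' @param arm5p_prob probability that the miRNA occupies the 5p arm.
#' @param covariation_injection optional list
#'   `list(position =, block = "identity"|"pairing", cond =)` injecting a
#'   dependency between miRNA nt 1 and the miRNA 5'-anchor feature at
#'   `position`: for `identity`, `cond` is a named list nt1 -> 4-vector over
#'   (A,C,G,U); for `pairing`, nt1 -> probability that the position is paired.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a validated `synthetic_params` list.
#' @export
synthetic_params <- function(n_hairpins,
                             hairpin_len = 64L, mature_len = 22L,
                             body_nt_probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                             mirna_nt1_probs = c(A = 0.15, C = 0.10, G = 0.10, U = 0.65),
                             star_nt1_probs = c(A = 0.30, C = 0.25, G = 0.25, U = 0.20),
                             asymmetry_meanlog = log(20), asymmetry_sdlog = 1.8,
                             depth_meanlog = log(1000), depth_sdlog = 1.5,
                             isoform_jitter = 0.2,
                             complementarity = 0.9,
                             arm5p_prob = 0.4,
                             covariation_injection = NULL,
                             seed = 1L) {
  if (n_hairpins < 1) stop("synthetic_params: n_hairpins must be >= 1")
  loop_len <- hairpin_len - 2L * mature_len
  if (loop_len < 1L) {
    stop("synthetic_params: mature_len must be < hairpin_len / 2 (no room for a loop)")
  }
  chkp <- function(p, lab) {
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("synthetic_params: %s must be a 4-vector of probabilities summing to 1", lab))
    }
    stats::setNames(as.numeric(p), RNA_NT)
  }
  stopifnot(isoform_jitter >= 0, isoform_jitter <= 1,
            complementarity >= 0, complementarity <= 1,
            arm5p_prob >= 0, arm5p_prob <= 1, asymmetry_sdlog >= 0,
            depth_sdlog >= 0)
  if (!is.null(covariation_injection)) {
    ci <- covariation_injection
    stopifnot(is.list(ci), !is.null(ci$position), !is.null(ci$block),
              ci$block %in% c("identity", "pairing"),
              ci$position >= 1, ci$position <= mature_len, !is.null(ci$cond))
    if (ci$block == "identity" && ci$position == 1) {
      stop("synthetic_params: cannot inject at position 1 (that IS nt 1)")
    }
  }
  structure(list(n_hairpins = as.integer(n_hairpins),
                 hairpin_len = as.integer(hairpin_len),
                 mature_len = as.integer(mature_len), loop_len = loop_len,
                 body_nt_probs = chkp(body_nt_probs, "body_nt_probs"),
                 mirna_nt1_probs = chkp(mirna_nt1_probs, "mirna_nt1_probs"),
                 star_nt1_probs = chkp(star_nt1_probs, "star_nt1_probs"),
                 asymmetry_meanlog = asymmetry_meanlog,
                 asymmetry_sdlog = asymmetry_sdlog,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 isoform_jitter = isoform_jitter,
                 complementarity = complementarity,
                 arm5p_prob = arm5p_prob,
                 covariation_injection = covariation_injection,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Asymmetry-bin proportions implied by the generator's ratio law
#'
#' Closed form under the reflected log-normal: the designated ratio is
#' `max(X, 1/X)` with `X` log-normal, so
#' `P(r >= t) = P(X >= t) + P(X <= 1/t)`.
#'
#' @param params a `synthetic_params` object.
#' @return named 3-vector of expected proportions per bin.
#' @export
expected_bin_props <- function(params) {
  p_ge <- function(t) {
    stats::plnorm(t, params$asymmetry_meanlog, params$asymmetry_sdlog,
                  lower.tail = FALSE) +
      stats::plnorm(1 / t, params$asymmetry_meanlog, params$asymmetry_sdlog)
  }
  high <- p_ge(10); mod <- p_ge(2) - high
  c(highly_asymmetric = high, moderately_asymmetric = mod,
    quasisymmetric = 1 - high - mod)
}

sample_nt <- function(n, probs) sample(RNA_NT, n, replace = TRUE, prob = probs)

# nucleotides that cannot pair (neither Watson-Crick nor wobble) with `nt`
non_pairing_nt <- function(nt) {
  switch(nt, A = c("A", "C", "G"), C = c("A", "C", "U"),
         G = c("A", "G"), U = c("C", "U"))
}

# split `total` reads over 5'-shifted isoforms of one strand
jitter_isoforms <- function(hairpin, start, len, total, jitter) {
  shifts <- -2:2
  probs <- c(0.15, 0.35, 0, 0.35, 0.15) * jitter
  probs[shifts == 0] <- 1 - jitter
  ok <- start + shifts >= 1 & start + shifts + len - 1 <= nchar(hairpin)
  shifts <- shifts[ok]; probs <- probs[ok] / sum(probs[ok])
  counts <- as.vector(stats::rmultinom(1, total, probs))
  keep <- counts > 0
  data.frame(sequence = substring(hairpin, start + shifts[keep],
                                  start + shifts[keep] + len - 1L),
             start = start + shifts[keep], count = counts[keep],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds hairpins containing both mature arms verbatim around a loop, a
#' pooled read library realizing the asymmetry and depth laws with isoform
#' jitter, and a truth ledger recording every sampled quantity. Bit-
#' reproducible from `params$seed`.
#'
#' @param params a [synthetic_params] object.
#' @return object of class `synthetic_cohort`: list with `records` (list of
#'   [premirna_record]), `library` (a [read_library]), `truth` (data frame)
#'   and `params`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  L <- params$mature_len
  withr::with_seed(params$seed, {
    records <- vector("list", params$n_hairpins)
    truth <- vector("list", params$n_hairpins)
    tag_seq <- character(0); tag_cnt <- numeric(0)
    for (h in seq_len(params$n_hairpins)) {
      id <- sprintf("syn-mir-%04d", h)
      mirna <- sample_nt(L, params$body_nt_probs)
      mirna[1] <- sample_nt(1, params$mirna_nt1_probs)
      inj <- params$covariation_injection
      injected_value <- NA_character_
      if (!is.null(inj) && inj$block == "identity") {
        mirna[inj$position] <- sample_nt(1, inj$cond[[mirna[1]]])
        injected_value <- mirna[inj$position]
      }
      # star strand: 5' nt drawn, remainder complementary-with-mismatches;
      # star position k faces miRNA position L + 1 - k in the stem
      star <- character(L)
      star[1] <- sample_nt(1, params$star_nt1_probs)
      for (k in 2:L) {
        facing <- mirna[L + 1L - k]
        star[k] <- if (stats::runif(1) < params$complementarity) {
          rna_complement(facing)
        } else {
          sample(non_pairing_nt(facing), 1L)
        }
      }
      if (!is.null(inj) && inj$block == "pairing") {
        facing <- mirna[inj$position]
        k <- L + 1L - inj$position
        paired <- stats::runif(1) < inj$cond[[mirna[1]]]
        star[k] <- if (paired) rna_complement(facing) else
          sample(non_pairing_nt(facing), 1L)
        injected_value <- if (paired) "paired" else "unpaired"
      }
      mirna_arm <- if (stats::runif(1) < params$arm5p_prob) "5p" else "3p"
      loop <- sample_nt(params$loop_len, params$body_nt_probs)
      arms <- if (mirna_arm == "5p") list(mirna, star) else list(star, mirna)
      hairpin <- paste(c(arms[[1]], loop, arms[[2]]), collapse = "")
      a5 <- c(1L, L); a3 <- c(L + params$loop_len + 1L, 2L * L + params$loop_len)
      records[[h]] <- premirna_record(id, hairpin, arm5p = a5, arm3p = a3,
                                      species = "synthetic")

      x <- stats::rlnorm(1, params$asymmetry_meanlog, params$asymmetry_sdlog)
      ratio <- max(x, 1 / x)
      depth <- max(2, round(stats::rlnorm(1, params$depth_meanlog, params$depth_sdlog)))
      mirna_total <- round(depth * ratio / (1 + ratio))
      star_total <- depth - mirna_total
      starts <- if (mirna_arm == "5p") c(a5[1], a3[1]) else c(a3[1], a5[1])
      for (strand in 1:2) {
        tot <- if (strand == 1) mirna_total else star_total
        if (tot == 0) next
        iso <- jitter_isoforms(hairpin, starts[strand], L, tot, params$isoform_jitter)
        tag_seq <- c(tag_seq, iso$sequence); tag_cnt <- c(tag_cnt, iso$count)
      }
      truth[[h]] <- data.frame(
        hairpin_id = id, mirna_arm = mirna_arm,
        mirna_nt1 = mirna[1], star_nt1 = star[1],
        true_ratio = ratio, depth = depth,
        mirna_total = mirna_total, star_total = star_total,
        injected_value = injected_value, stringsAsFactors = FALSE)
    }
    agg <- tapply(tag_cnt, tag_seq, sum)
    lib <- read_library(stats::setNames(as.numeric(agg), names(agg)),
                        source_ids = sprintf("synthetic-seed%d", params$seed))
    structure(list(records = records, library = lib,
                   truth = do.call(rbind, truth), params = params),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d hairpins, %d tags, %s reads (seed %d)\n",
              length(x$records), length(x$library$counts),
              format(sum(x$library$counts), big.mark = ","), x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats [read_annotations()] and [read_tag_counts()]
#' read, plus the truth ledger.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param coord_format `"tsv"` or `"gff3"`.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, coord_format = c("tsv", "gff3")) {
  coord_format <- match.arg(coord_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (coord_format == "tsv") "tsv" else "gff3"
  paths <- c(hairpin_fasta = file.path(dir, "hairpins.fa"),
             mature_coords = file.path(dir, paste0("mature.", ext)),
             tag_counts = file.path(dir, "tags.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_annotations(cohort$records, paths["hairpin_fasta"],
                    paths["mature_coords"], format = coord_format)
  write_tag_counts(cohort$library, paths["tag_counts"], dialect = "tsv")
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
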