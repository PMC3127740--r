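# Duplex reconstruction and per-nucleotide base-pair probabilities.
#
# The builtin engine computes exact pair probabilities over the space of all
# non-crossing, intermolecular-only pairings of the two strands (no hairpins
# within a ~21-nt strand under duplex-forming conditions), Boltzmann-weighted
# by a simple additive score. The downstream analysis consumes only binary
# paired/unpaired calls at probability 0.5, which are robust to the scoring
# details for near-complementary duplexes; full co-folding output from an
# external tool can be supplied through the adapter instead.

#' Scoring parameters for the builtin duplex engine
#'
#' Additive per-pair scores (score units), a per-nucleotide penalty for
#' internal unpaired regions, and a surcharge for bulges (regions leaving
#' nucleotides unpaired on only one strand), which nearest-neighbor
#' thermodynamics penalizes well beyond a symmetric internal loop of the same
#' size. The bulge term is what lets the engine discriminate the correct
#' duplex-end register from a wobble-shifted alternative. Terminal unpaired
#' ends are free. Boltzmann weights are `exp(score / scale)`.
#'
#' @param gc,au,gu per-pair scores for G:C, A:U and G:U pairs.
#' @param loop_per_nt penalty (negative) per internal unpaired nucleotide.
#' @param bulge_open additional penalty when an internal region is one-sided.
#' @param scale temperature-like scale factor.
#' @return a named list of parameters.
#' @export
duplex_scores <- function(gc = 3, au = 2, gu = 1, loop_per_nt = -0.5,
                          bulge_open = -3, scale = 1) {
  stopifnot(scale > 0)
  list(gc = gc, au = au, gu = gu, loop_per_nt = loop_per_nt,
       bulge_open = bulge_open, scale = scale)
}

pair_score <- function(a, b, scores) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) scores$gc
  else if (key %in% c("AU", "UA")) scores$au
  else if (key %in% c("GU", "UG")) scores$gu
  else NA_real_
}

# Per-pair Boltzmann weight matrix in "chain space": rows follow seq_a 5'->3',
# columns follow seq_b 3'->5' (reversed), zero where no WC/GU pair is possible.
duplex_weight_matrix <- function(seq_a, seq_b, scores) {
  a <- seq_chars(seq_a); c_ <- rev(seq_chars(seq_b))
  n <- length(a); m <- length(c_)
  w <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      s <- pair_score(a[i], c_[k], scores)
      if (!is.na(s)) w[i, k] <- exp(s / scores$scale)
    }
  }
  w
}

#' Extract the miRNA/miRNA* duplex sequences for one hairpin
#'
#' Returns the most abundant isoform of each arm (guide first), the pair of
#' sequences the structural analysis operates on. Count ties are broken toward
#' the isoform starting closest to the annotated arm start, then 5'-most.
#'
#' @param record a [premirna_record].
#' @param profiles an `isoform_profiles` data frame.
#' @param mirna_arm which arm carries the miRNA; default designates by
#'   pooled abundance as in [designate_strands()].
#' @return list with elements `seq_a` (miRNA) and `seq_b` (miRNA*).
#' @export
extract_duplex <- function(record, profiles, mirna_arm = NULL) {
  counts <- vapply(c("5p", "3p"), function(a) {
    sum(profiles$count[profiles$hairpin_id == record$id & profiles$arm == a])
  }, numeric(1))
  if (any(counts == 0)) {
    stop(sprintf("extract_duplex: hairpin '%s' has an arm with no isoforms", record$id))
  }
  if (is.null(mirna_arm)) {
    mirna_arm <- if (counts["3p"] > counts["5p"]) "3p" else "5p"
  }
  star_arm <- setdiff(c("5p", "3p"), mirna_arm)
  list(seq_a = top_isoform(profiles, record$id, mirna_arm, record)$sequence,
       seq_b = top_isoform(profiles, record$id, star_arm, record)$sequence)
}

#' Intermolecular base-pair probabilities for a duplex
#'
#' Computes, for every position of each strand, the probability that it pairs
#' each position of the other strand, over the Boltzmann ensemble of
#' non-crossing intermolecular pairings (builtin engine), or parses an
#' external co-folding tool's pair-probability table into the same contract.
#'
#' @param seq_a,seq_b the two strands, 5'->3' (miRNA, miRNA*); length <= 50.
#' @param engine `"builtin"` or `"external"`.
#' @param scores scoring parameters from [duplex_scores()] (builtin engine).
#' @param external_file for the external engine: a TSV with columns
#'   `pos_a`, `pos_b`, `prob` (1-based from each 5' end). If unavailable the
#'   builtin engine is used with a warning.
#' @return an object of class `pairprob_matrix`: list with `seq_a`, `seq_b`,
#'   `p` (matrix, `p[i, j]` = probability that a-position i pairs b-position
#'   j, both 1-based from the 5' end), `unpaired_a`, `unpaired_b`.
#' @export
pair_probabilities <- function(seq_a, seq_b, engine = c("builtin", "external"),
                               scores = duplex_scores(), external_file = NULL) {
  engine <- match.arg(engine)
  seq_a <- normalize_rna(seq_a, "seq_a"); seq_b <- normalize_rna(seq_b, "seq_b")
  n <- nchar(seq_a); m <- nchar(seq_b)
  if (n < 1 || m < 1 || n > 50 || m > 50) {
    stop("pair_probabilities: strand lengths must be in 1..50")
  }
  if (engine == "external") {
    if (is.null(external_file) || !file.exists(external_file)) {
      warning("external engine output unavailable; falling back to builtin engine")
    } else {
      return(read_pairprob_table(seq_a, seq_b, external_file))
    }
  }
  w <- duplex_weight_matrix(seq_a, seq_b, scores)
  res <- duplex_dp_cpp(w, exp(scores$loop_per_nt / scores$scale),
                       exp(scores$bulge_open / scores$scale))
  p_chain <- res$p                      # columns in reversed-b order
  p <- p_chain[, rev(seq_len(m)), drop = FALSE]
  dimnames(p) <- list(seq_chars(seq_a), seq_chars(seq_b))
  structure(list(seq_a = seq_a, seq_b = seq_b, p = p,
                 unpaired_a = 1 - rowSums(p), unpaired_b = 1 - colSums(p),
                 engine = "builtin", Z = res$Z),
            class = "pairprob_matrix")
}

read_pairprob_table <- function(seq_a, seq_b, path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          col.names = c("pos_a", "pos_b", "prob"))
  n <- nchar(seq_a); m <- nchar(seq_b)
  if (any(df$pos_a < 1 | df$pos_a > n | df$pos_b < 1 | df$pos_b > m) ||
      any(df$prob < 0 | df$prob > 1)) {
    stop("external pair-probability table: positions out of range or probabilities outside [0,1]")
  }
  p <- matrix(0, n, m, dimnames = list(seq_chars(seq_a), seq_chars(seq_b)))
  p[cbind(df$pos_a, df$pos_b)] <- df$prob
  if (any(rowSums(p) > 1 + 1e-9) || any(colSums(p) > 1 + 1e-9)) {
    stop("external pair-probability table violates probability conservation")
  }
  structure(list(seq_a = seq_a, seq_b = seq_b, p = p,
                 unpaired_a = 1 - rowSums(p), unpaired_b = 1 - colSums(p),
                 engine = "external", Z = NA_real_),
            class = "pairprob_matrix")
}

#' @export
print.pairprob_matrix <- function(x, ...) {
  cat(sprintf("<pairprob_matrix> %d x %d nt duplex (%s engine)\n",
              nchar(x$seq_a), nchar(x$seq_b), x$engine))
  invisible(x)
}

#' Call paired/unpaired status from a pair-probability matrix
#'
#' A position is called paired when its total pairing probability is strictly
#' greater than `threshold`; its partner is the maximal-probability position
#' on the other strand.
#'
#' @param matrix a `pairprob_matrix`.
#' @param threshold pairing-probability cutoff (default 0.5, strict).
#' @return an object of class `pairing_status`: logical vectors `paired_a`,
#'   `paired_b` and integer vectors `partner_a`, `partner_b` (`NA` where
#'   unpaired).
#' @export
pairing_status <- function(matrix, threshold = 0.5) {
  p <- matrix$p
  paired_a <- (1 - matrix$unpaired_a) > threshold
  paired_b <- (1 - matrix$unpaired_b) > threshold
  partner_a <- ifelse(paired_a & ncol(p) > 0, apply(p, 1, which.max), NA_integer_)
  partner_b <- ifelse(paired_b & nrow(p) > 0, apply(p, 2, which.max), NA_integer_)
  structure(list(paired_a = unname(paired_a), paired_b = unname(paired_b),
                 partner_a = as.integer(partner_a), partner_b = as.integer(partner_b),
                 threshold = threshold),
            class = "pairing_status")
}

#' @export
print.pairing_status <- function(x, ...) {
  cat(sprintf("<pairing_status> a: %d/%d paired; b: %d/%d paired (threshold %g)\n",
              sum(x$paired_a), length(x$paired_a),
              sum(x$paired_b), length(x$paired_b), x$threshold))
  invisible(x)
}
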