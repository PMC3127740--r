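# Shared low-level helpers: RNA alphabet handling and seed scoping.

RNA_NT <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U (DNA-alphabet input is accepted everywhere),
#' and validates that only A/C/G/U remain.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector over \{A,C,G,U\}.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("tu", "TU", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGU symbols: %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")))
  }
  x
}

# Watson-Crick complement (RNA).
rna_complement <- function(nt) chartr("ACGU", "UGCA", nt)

# TRUE if nt_a:nt_b can form a Watson-Crick or G:U wobble pair.
can_pair_nt <- function(a, b) {
  key <- paste0(a, b)
  key %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Evaluate `expr` under a fixed RNG seed when `seed` is non-NULL, leaving the
# global RNG state untouched; otherwise evaluate as-is.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Tabulate nucleotides into a named frequency 4-vector over (A,C,G,U).
nt_freq_vector <- function(nts, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(nts))
  v <- vapply(RNA_NT, function(n) sum(weights[nts == n]), numeric(1))
  tot <- sum(v)
  if (tot > 0) v <- v / tot
  v
}
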