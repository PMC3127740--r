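# The 144-feature duplex representation and the Fisher-exact covariation scan
# against miRNA nt-1 identity.

#' Canonical descriptors of the 144 duplex features
#'
#' For each strand (miRNA, miRNA*), each anchor (counting from the 5' end or
#' from the 3' end) and positions 1..18, two blocks are defined: nucleotide
#' identity (A/C/G/U; 72 features) and base-pairing status (paired/unpaired;
#' 72 features). The row order here fixes the feature order everywhere.
#'
#' @return a 144-row data frame with columns `strand`, `anchor`, `position`,
#'   `block` and `feature` (a unique label).
#' @export
feature_descriptors <- function() {
  d <- expand.grid(position = 1:18, anchor = c("5p", "3p"),
                   strand = c("mirna", "star"), block = c("identity", "pairing"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("strand", "anchor", "position", "block")]
  d$feature <- sprintf("%s|%s|%02d|%s", d$strand, d$anchor, d$position, d$block)
  rownames(d) <- NULL
  d
}

#' Build the 144-feature vector of one miRNA/miRNA* duplex
#'
#' Positions beyond a strand's length yield `NA` (missing, not absent): the
#' vector always has length 144. The miRNA 5'-anchor identity feature at
#' position 1 equals `nt1` itself by construction (the self-correlation the
#' scan exposes at position 1).
#'
#' @param seq_a,seq_b miRNA and miRNA* sequences, 5'->3'.
#' @param status a `pairing_status` computed on the same pair.
#' @param duplex_id identifier carried along.
#' @return object of class `feature_vector`: list with `duplex_id`, `nt1`
#'   and `features` (named character vector, length 144).
#' @export
build_feature_vector <- function(seq_a, seq_b, status, duplex_id = NA_character_) {
  seq_a <- normalize_rna(seq_a, "seq_a"); seq_b <- normalize_rna(seq_b, "seq_b")
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  stopifnot(length(status$paired_a) == length(a),
            length(status$paired_b) == length(b))
  desc <- feature_descriptors()
  vals <- character(nrow(desc))
  for (r in seq_len(nrow(desc))) {
    chars <- if (desc$strand[r] == "mirna") a else b
    paired <- if (desc$strand[r] == "mirna") status$paired_a else status$paired_b
    k <- desc$position[r]
    idx <- if (desc$anchor[r] == "5p") k else length(chars) - k + 1L
    if (idx < 1L || idx > length(chars)) { vals[r] <- NA_character_; next }
    vals[r] <- if (desc$block[r] == "identity") chars[idx] else
      if (paired[idx]) "paired" else "unpaired"
  }
  structure(list(duplex_id = as.character(duplex_id), nt1 = a[1],
                 features = stats::setNames(vals, desc$feature)),
            class = "feature_vector")
}

#' Compute feature vectors for every duplex in a duplex table
#'
#' Runs the pair-probability engine and pairing calls on each duplex's top
#' isoforms and builds the 144-feature vector.
#'
#' @param duplexes a `duplex_table`.
#' @param threshold pairing-probability call threshold (default 0.5).
#' @param engine,scores,external_file passed to [pair_probabilities()].
#' @return list of `feature_vector` objects.
#' @export
duplex_features <- function(duplexes, threshold = 0.5,
                            engine = "builtin", scores = duplex_scores(),
                            external_file = NULL) {
  lapply(seq_len(nrow(duplexes)), function(i) {
    m <- pair_probabilities(duplexes$mirna_seq[i], duplexes$star_seq[i],
                            engine = engine, scores = scores,
                            external_file = external_file)
    build_feature_vector(duplexes$mirna_seq[i], duplexes$star_seq[i],
                         pairing_status(m, threshold),
                         duplex_id = duplexes$hairpin_id[i])
  })
}

table_logprob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# Upper bound on the number of contingency tables with the given margins:
# each column filled independently (stars and bars), ignoring row constraints.
table_space_bound <- function(rs, cs) {
  prod(choose(cs + length(rs) - 1, length(rs) - 1))
}

# Exact two-sided p for a 2 x c table by enumerating all first rows compatible
# with the margins. Two-sided by the minimum-likelihood rule: sum the
# probabilities of all tables no more probable than the observed one.
fisher_2xc_enumerate <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  lp_obs <- table_logprob(tab)
  c_ <- length(cs)
  lp_all <- numeric(0)
  rec <- function(j, remaining, row1) {
    if (j > c_) {
      if (remaining == 0) {
        t2 <- rbind(row1, cs - row1)
        lp_all[[length(lp_all) + 1L]] <<- table_logprob(t2)
      }
      return(invisible(NULL))
    }
    lo <- max(0L, remaining - sum(cs[j:c_]) + cs[j])
    hi <- min(cs[j], remaining)
    if (lo > hi) return(invisible(NULL))
    for (x in lo:hi) rec(j + 1L, remaining - x, c(row1, x))
  }
  rec(1L, rs[1], integer(0))
  pr <- exp(lp_all - max(lp_all))
  sum(pr[lp_all <= lp_obs + 1e-7]) / sum(pr)
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided throughout, by the minimum-likelihood convention (the p value
#' sums the probabilities of all margin-compatible tables no more probable
#' than the observed one). 2 x c tables are handled by direct enumeration;
#' larger tables use the exact network algorithm when the margin-constrained
#' table space is below `max_tables` (assessed by a cheap per-column upper
#' bound), and otherwise margin-preserving Monte-Carlo sampling (Patefield's
#' algorithm) with `p = (1 + #as-or-more-extreme) / (1 + n_mc)`.
#'
#' @param tab matrix of non-negative integer counts.
#' @param method `"auto"`, `"exact"` or `"monte_carlo"`.
#' @param max_tables cap on the table-space bound for the exact branch.
#' @param n_mc Monte-Carlo sample size.
#' @param seed optional seed making the Monte-Carlo branch reproducible.
#' @return list with `p` and `method_used` (`"exact_2xc"`, `"exact_network"`,
#'   `"monte_carlo"` or `"degenerate"`).
#' @export
fisher_exact <- function(tab, method = c("auto", "exact", "monte_carlo"),
                         max_tables = 1e6, n_mc = 10000L, seed = NULL) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("fisher_exact: counts must be non-negative integers")
  }
  storage.mode(tab) <- "integer"
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("fisher_exact: degenerate table (fewer than 2 non-empty rows or columns); p = 1")
    return(list(p = 1, method_used = "degenerate"))
  }
  if (nrow(tab) > ncol(tab)) tab <- t(tab)   # enumerate over the shorter margin
  rs <- rowSums(tab); cs <- colSums(tab)
  bound <- table_space_bound(rs, cs)

  use_exact <- switch(method,
    exact = TRUE,
    monte_carlo = FALSE,
    auto = is.finite(bound) && bound <= max_tables)

  if (use_exact) {
    # direct enumeration for small 2 x c tables; the network algorithm is
    # exact too and much faster once the composition space grows
    if (nrow(tab) == 2 && is.finite(bound) && bound <= 5e3) {
      return(list(p = fisher_2xc_enumerate(tab), method_used = "exact_2xc"))
    }
    res <- tryCatch(
      list(p = stats::fisher.test(tab, workspace = 2e7)$p.value,
           method_used = "exact_network"),
      error = function(e) NULL)
    if (!is.null(res)) return(res)
    warning("exact test failed; falling back to Monte-Carlo")
  }
  lp_obs <- table_logprob(tab)
  hits <- with_seed_opt(seed, {
    sims <- stats::r2dtable(n_mc, rs, cs)
    # margins are fixed across simulated tables: only the cell term varies
    lp_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1)
    lp_sims <- lp_const - colSums(lgamma(matrix(unlist(sims), nrow = length(tab)) + 1))
    sum(lp_sims <= lp_obs + 1e-7)
  })
  list(p = (1 + hits) / (1 + n_mc), method_used = "monte_carlo")
}

#' Scan the 144 duplex features for covariation with miRNA nt-1 identity
#'
#' Runs one Fisher's exact test per feature on the contingency table of nt-1
#' identity against feature value, dropping duplexes with a missing value at
#' that feature pairwise. Raw p values are reported (the position-1 miRNA
#' identity feature is the nt1 self-correlation); a Bonferroni column over the
#' 144 tests is emitted alongside.
#'
#' @param feature_vectors list of `feature_vector` objects.
#' @param collapse_nt1 test U vs non-U instead of the full 4-level nt1 factor.
#' @param method,max_tables,n_mc passed to [fisher_exact()].
#' @param seed optional; per-feature seeds are derived from it.
#' @return a data frame (class `covariation_result`) with one row per feature:
#'   descriptor columns, `n_used`, `levels`, `p`, `method_used`,
#'   `neg_log10_p`, `p_bonferroni`, ordered for plotting the identity and
#'   pairing curves per strand and anchor.
#' @export
covariation_scan <- function(feature_vectors, collapse_nt1 = FALSE,
                             method = "auto", max_tables = 1e6,
                             n_mc = 10000L, seed = NULL) {
  stopifnot(length(feature_vectors) >= 2)
  nt1 <- vapply(feature_vectors, `[[`, "", "nt1")
  if (collapse_nt1) nt1 <- ifelse(nt1 == "U", "U", "nonU")
  if (length(unique(nt1)) < 2) {
    stop("covariation_scan: miRNA nt 1 is constant across duplexes; nothing to covary")
  }
  fmat <- vapply(feature_vectors, `[[`, character(144), "features")
  desc <- feature_descriptors()
  out <- desc
  out$n_used <- NA_integer_; out$levels <- NA_integer_
  out$p <- NA_real_; out$method_used <- NA_character_
  for (r in seq_len(nrow(desc))) {
    vals <- fmat[r, ]
    ok <- !is.na(vals)
    out$n_used[r] <- sum(ok)
    tab <- table(nt1[ok], vals[ok])
    out$levels[r] <- sum(colSums(tab) > 0)
    ft <- withCallingHandlers(
      fisher_exact(tab, method = method, max_tables = max_tables, n_mc = n_mc,
                   seed = if (is.null(seed)) NULL else as.integer(seed) + r),
      warning = function(w) invokeRestart("muffleWarning"))
    out$p[r] <- ft$p
    out$method_used[r] <- ft$method_used
  }
  out$neg_log10_p <- -log10(out$p)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  class(out) <- c("covariation_result", "data.frame")
  out
}

#' Write a covariation scan result to TSV
#' @param result a `covariation_result`.
#' @param path output path.
#' @export
write_covariation <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
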