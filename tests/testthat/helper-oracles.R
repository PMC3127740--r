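# Independent oracles. These deliberately reimplement the quantities the
# package computes, by brute force, and share no code with the package
# beyond the published score/parameter definitions.

# --- duplex partition function by exhaustive chain enumeration ---------------

# All non-crossing intermolecular pairings of seq_a with seq_b, enumerated
# recursively; returns the pair-probability matrix in the same orientation as
# pair_probabilities() (columns = b positions from b's 5' end).
bf_pair_probabilities <- function(seq_a, seq_b, scores = duplex_scores()) {
  a <- strsplit(seq_a, "")[[1]]
  cc <- rev(strsplit(seq_b, "")[[1]])
  n <- length(a); m <- length(cc)
  sc1 <- function(x, y) {
    k <- paste0(x, y)
    if (k %in% c("GC", "CG")) scores$gc
    else if (k %in% c("AU", "UA")) scores$au
    else if (k %in% c("GU", "UG")) scores$gu
    else NA_real_
  }
  cand <- list()
  for (i in seq_len(n)) for (k in seq_len(m)) {
    s <- sc1(a[i], cc[k])
    if (!is.na(s)) cand[[length(cand) + 1L]] <- c(i, k, exp(s / scores$scale))
  }
  Z <- 0
  acc <- matrix(0, n, m)
  gl <- exp(scores$loop_per_nt / scores$scale)
  gb <- exp(scores$bulge_open / scores$scale)
  rec <- function(prev_i, prev_k, w, chain) {
    Z <<- Z + w
    for (r in chain) acc[r[1], r[2]] <<- acc[r[1], r[2]] + w
    for (p in cand) {
      if (p[1] > prev_i && p[2] > prev_k) {
        f <- p[3]
        if (prev_i > 0) {
          da <- p[1] - prev_i - 1L; dk <- p[2] - prev_k - 1L
          f <- f * gl^(da + dk)
          if ((da == 0) != (dk == 0)) f <- f * gb
        }
        rec(p[1], p[2], w * f, c(chain, list(p)))
      }
    }
  }
  rec(0L, 0L, 1, list())
  p_chain <- acc / Z
  structure(list(p = p_chain[, rev(seq_len(m)), drop = FALSE], Z = Z),
            class = "bf_pairprob")
}

# --- Fisher's exact test by full table enumeration ---------------------------

# Every non-negative integer table with the observed margins, generated row by
# row; two-sided p by the minimum-likelihood rule.
bf_fisher_p <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  lp <- function(t) {
    sum(lgamma(rowSums(t) + 1)) + sum(lgamma(colSums(t) + 1)) -
      lgamma(sum(t) + 1) - sum(lgamma(t + 1))
  }
  lp_obs <- lp(tab)
  lps <- numeric(0)
  fill_row <- function(remaining_rows, cap, built) {
    if (length(remaining_rows) == 1L) {
      if (all(cap >= 0)) {
        t_full <- rbind(built, cap)
        if (sum(cap) == remaining_rows[1]) lps[[length(lps) + 1L]] <<- lp(t_full)
      }
      return(invisible(NULL))
    }
    target <- remaining_rows[1]
    comps <- compositions(target, cap)
    for (ci in seq_len(nrow(comps))) {
      fill_row(remaining_rows[-1], cap - comps[ci, ],
               rbind(built, comps[ci, ]))
    }
  }
  # all vectors x >= 0, sum(x) == s, x <= cap
  compositions <- function(s, cap) {
    if (length(cap) == 1L) {
      if (s <= cap) return(matrix(s, 1, 1)) else return(matrix(0, 0, 1))
    }
    out <- list()
    for (x in 0:min(s, cap[1])) {
      rest <- compositions(s - x, cap[-1])
      if (nrow(rest) > 0) out[[length(out) + 1L]] <- cbind(x, rest)
    }
    if (length(out) == 0) return(matrix(0, 0, length(cap)))
    do.call(rbind, out)
  }
  fill_row(rs, cs, NULL)
  pr <- exp(lps - max(lps))
  sum(pr[lps <= lp_obs + 1e-7]) / sum(pr)
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}
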