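# Abundance-weighted 5'-nucleotide composition, the nt 1-18 resampling null,
# p values, and the flanking-uridine profile.
#
# Weighting follows a two-level scheme: within a hairpin, isoforms of a strand
# are weighted by their read counts; across hairpins, every hairpin-strand
# contributes equally. The resampling null draws, per hairpin-strand and per
# set, one isoform (abundance-proportionally) and one position uniformly from
# the nt 1-18 window, so each random set has exactly the size and weighting of
# the observed set of 5' nucleotides.

strand_profile_rows <- function(duplexes, profiles, strand_class) {
  arm <- if (strand_class == "miRNA") duplexes$mirna_arm else
    ifelse(duplexes$mirna_arm == "5p", "3p", "5p")
  lapply(seq_len(nrow(duplexes)), function(i) {
    profiles[profiles$hairpin_id == duplexes$hairpin_id[i] &
               profiles$arm == arm[i], , drop = FALSE]
  })
}

apply_stratum <- function(duplexes, stratum) {
  if (is.null(stratum)) return(duplexes)
  keep <- rep(TRUE, nrow(duplexes))
  if (!is.null(stratum$arm)) keep <- keep & duplexes$mirna_arm == stratum$arm
  if (!is.null(stratum$bin)) keep <- keep & duplexes$bin == stratum$bin
  out <- duplexes[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop(sprintf("empty stratum: %s",
                 paste(names(stratum), unlist(stratum), sep = "=", collapse = ", ")))
  }
  out
}

#' Abundance-weighted 5'-nucleotide frequencies
#'
#' For each hairpin, the nt-1 distribution of the chosen strand's isoforms is
#' weighted by isoform read counts and normalized; the reported frequency
#' vector is the unweighted mean of these per-hairpin distributions.
#'
#' @param duplexes a `duplex_table` (typically after [filter_expressed()]).
#' @param profiles the `isoform_profiles` the duplex table was built from.
#' @param strand_class `"miRNA"` or `"miRNA*"`.
#' @param stratum optional list with `arm` (`"5p"`/`"3p"`, the miRNA arm) and/or
#'   `bin` (asymmetry bin label) restricting the duplex set.
#' @return named numeric 4-vector of frequencies over (A, C, G, U), summing
#'   to 1.
#' @export
weighted_nt1_frequencies <- function(duplexes, profiles,
                                     strand_class = c("miRNA", "miRNA*"),
                                     stratum = NULL) {
  strand_class <- match.arg(strand_class)
  duplexes <- apply_stratum(duplexes, stratum)
  rows <- strand_profile_rows(duplexes, profiles, strand_class)
  per_hairpin <- vapply(rows, function(pr) {
    nt_freq_vector(substr(pr$sequence, 1, 1), pr$count)
  }, numeric(4))
  rowMeans(per_hairpin)
}

#' Resample the nt 1-18 composition null
#'
#' Generates `n_sets` random frequency 4-vectors under the null that the 5'
#' nucleotide is a random draw from the strand body: per set and per
#' hairpin-strand, one isoform is sampled with probability proportional to its
#' count and one position uniformly from `window` (truncated to the isoform
#' length when shorter, with a message); the nucleotide at that position is
#' recorded. Set frequencies use the same per-hairpin equal weighting as the
#' observed statistic.
#'
#' @inheritParams weighted_nt1_frequencies
#' @param n_sets number of random sets (default 100).
#' @param window positions eligible for resampling (default 1:18).
#' @param seed RNG seed; same seed, same matrix.
#' @return `n_sets` x 4 matrix of frequency vectors (columns A, C, G, U).
#' @export
resample_background <- function(duplexes, profiles,
                                strand_class = c("miRNA", "miRNA*"),
                                stratum = NULL, n_sets = 100L, window = 1:18,
                                seed = NULL) {
  strand_class <- match.arg(strand_class)
  stopifnot(n_sets >= 1)
  duplexes <- apply_stratum(duplexes, stratum)
  rows <- strand_profile_rows(duplexes, profiles, strand_class)
  n_h <- length(rows)
  truncated <- FALSE
  with_seed_opt(seed, {
    draws <- matrix(NA_character_, nrow = n_sets, ncol = n_h)
    for (h in seq_len(n_h)) {
      pr <- rows[[h]]
      iso_idx <- sample.int(nrow(pr), n_sets, replace = TRUE, prob = pr$count)
      lens <- nchar(pr$sequence[iso_idx])
      if (any(lens < max(window))) truncated <- TRUE
      pos <- vapply(lens, function(L) {
        w <- window[window <= L]
        w[sample.int(length(w), 1L)]
      }, numeric(1))
      draws[, h] <- substr(pr$sequence[iso_idx], pos, pos)
    }
    if (truncated) message("resample_background: window truncated for isoforms shorter than max(window)")
    t(apply(draws, 1, nt_freq_vector))
  })
}

#' Empirical and Gaussian p values for a composition deviation
#'
#' One-sided in the direction of the observed deviation (two-sided available).
#' The empirical p uses a +1 pseudocount so finite resampling never yields
#' p = 0; the Gaussian p is the normal tail at
#' `z = (observed - resample mean) / resample sd`, reproducing the magnitude
#' of very small p values that `n_sets` empirical resamples cannot resolve.
#'
#' @param observed named frequency 4-vector from [weighted_nt1_frequencies()].
#' @param resamples matrix from [resample_background()].
#' @param alternative `"one.sided"` (direction of the deviation) or
#'   `"two.sided"`.
#' @return data frame with one row per nucleotide: `nt`, `observed`,
#'   `resample_mean`, `resample_sd`, `direction`, `p_empirical`, `p_gaussian`.
#' @export
composition_pvalue <- function(observed, resamples,
                               alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(nrow(resamples) >= 2, length(observed) == 4)
  n_sets <- nrow(resamples)
  out <- lapply(seq_along(RNA_NT), function(j) {
    obs <- observed[[j]]; rs <- resamples[, j]
    mu <- mean(rs); sdev <- stats::sd(rs)
    if (obs == mu) {
      dir <- "none"; p_emp <- 0.5; p_gau <- 0.5
    } else {
      dir <- if (obs > mu) "enriched" else "depleted"
      extreme <- if (obs > mu) sum(rs >= obs) else sum(rs <= obs)
      p_emp <- (1 + extreme) / (n_sets + 1)
      if (sdev == 0) {
        warning(sprintf("composition_pvalue: zero resample sd for %s with observed != mean; p_gaussian = 0",
                        RNA_NT[j]))
        p_gau <- 0
      } else {
        z <- (obs - mu) / sdev
        p_gau <- stats::pnorm(abs(z), lower.tail = FALSE)
      }
      if (alternative == "two.sided") {
        p_emp <- min(1, 2 * p_emp); p_gau <- min(1, 2 * p_gau)
      }
    }
    data.frame(nt = RNA_NT[j], observed = obs, resample_mean = mu,
               resample_sd = sdev, direction = dir,
               p_empirical = p_emp, p_gaussian = p_gau,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Composition analysis across strata
#'
#' Convenience wrapper running observed frequencies, the resampling null and
#' p values for both strand classes across a set of strata (overall, by miRNA
#' arm, by asymmetry bin). Strata empty in this duplex set are skipped with a
#' message.
#'
#' @inheritParams resample_background
#' @param strata named list of stratum filters; the default mirrors the
#'   arm-stratified and bin-stratified analyses.
#' @param alternative passed to [composition_pvalue()].
#' @return data frame with columns `stratum`, `strand_class`, `n_duplexes`
#'   and the [composition_pvalue()] columns.
#' @export
analyze_composition <- function(duplexes, profiles,
                                strata = default_strata(),
                                n_sets = 100L, window = 1:18, seed = NULL,
                                alternative = "one.sided") {
  out <- list()
  for (sname in names(strata)) {
    for (sc in c("miRNA", "miRNA*")) {
      res <- tryCatch({
        d <- apply_stratum(duplexes, strata[[sname]])
        obs <- weighted_nt1_frequencies(d, profiles, sc)
        rs <- resample_background(d, profiles, sc, n_sets = n_sets,
                                  window = window,
                                  seed = if (is.null(seed)) NULL
                                         else as.integer(seed) + length(out))
        pv <- composition_pvalue(obs, rs, alternative = alternative)
        cbind(data.frame(stratum = sname, strand_class = sc,
                         n_duplexes = nrow(d), stringsAsFactors = FALSE), pv)
      }, error = function(e) {
        message(sprintf("stratum '%s' (%s) skipped: %s", sname, sc, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Default composition strata
#' @return named list of stratum filters: overall, each miRNA arm, each
#'   asymmetry bin.
#' @export
default_strata <- function() {
  list(all = NULL,
       arm_5p = list(arm = "5p"), arm_3p = list(arm = "3p"),
       highly_asymmetric = list(bin = "highly_asymmetric"),
       moderately_asymmetric = list(bin = "moderately_asymmetric"),
       quasisymmetric = list(bin = "quasisymmetric"))
}

#' Uridine profile around the miRNA 5' end on the precursor
#'
#' Measures, per offset in `-halfwidth..halfwidth` relative to the most
#' abundant miRNA isoform's first nucleotide (offset 0), the per-hairpin
#' equal-weighted frequency of U on the precursor, across hairpins passing the
#' read filter. The background is the U frequency in `n_sets` random draws of
#' one in-bounds position per hairpin from its 21-nt segment, with an
#' empirical confidence interval over set means.
#'
#' @param records list of [premirna_record].
#' @param duplexes a filtered `duplex_table` (depth filter already applied).
#' @param halfwidth extent of the window on each side of nt 1 (default 10).
#' @param n_sets number of background sets (default 100).
#' @param ci confidence level for the background interval (default 0.95).
#' @param seed RNG seed.
#' @return object of class `flanking_profile`: list with `profile` (data
#'   frame: `offset`, `u_freq`, `n_hairpins`), `background_mean`, `ci_low`,
#'   `ci_high`.
#' @export
flanking_u_profile <- function(records, duplexes, halfwidth = 10L,
                               n_sets = 100L, ci = 0.95, seed = NULL) {
  if (halfwidth < 0) stop("flanking_u_profile: halfwidth must be >= 0")
  stopifnot(nrow(duplexes) >= 1)
  recs <- stats::setNames(records, vapply(records, `[[`, "", "id"))
  offsets <- -halfwidth:halfwidth
  # nucleotide at each offset, NA when outside the hairpin
  ntmat <- vapply(seq_len(nrow(duplexes)), function(i) {
    rec <- recs[[duplexes$hairpin_id[i]]]
    pos <- duplexes$mirna_start[i] + offsets
    ok <- pos >= 1 & pos <= nchar(rec$hairpin_seq)
    out <- rep(NA_character_, length(offsets))
    out[ok] <- substring(rec$hairpin_seq, pos[ok], pos[ok])
    out
  }, character(length(offsets)))
  u_freq <- apply(ntmat, 1, function(v) mean(v == "U", na.rm = TRUE))
  n_hair <- apply(ntmat, 1, function(v) sum(!is.na(v)))

  set_means <- with_seed_opt(seed, {
    vapply(seq_len(n_sets), function(s) {
      draws <- vapply(seq_len(ncol(ntmat)), function(i) {
        v <- ntmat[, i]; v <- v[!is.na(v)]
        v[sample.int(length(v), 1L)]
      }, character(1))
      mean(draws == "U")
    }, numeric(1))
  })
  alpha <- (1 - ci) / 2
  qs <- stats::quantile(set_means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(profile = data.frame(offset = offsets, u_freq = u_freq,
                                      n_hairpins = n_hair),
                 background_mean = mean(set_means),
                 ci_low = qs[1], ci_high = qs[2],
                 n_sets = n_sets, ci = ci),
            class = "flanking_profile")
}

#' @export
print.flanking_profile <- function(x, ...) {
  cat(sprintf("<flanking_profile> offsets %d..%d; background U freq %.3f [%.3f, %.3f]\n",
              min(x$profile$offset), max(x$profile$offset),
              x$background_mean, x$ci_low, x$ci_high))
  invisible(x)
}

#' Write a flanking profile to TSV
#' @param profile a `flanking_profile`.
#' @param path output path.
#' @export
write_flanking_profile <- function(profile, path) {
  df <- profile$profile
  df$background_mean <- profile$background_mean
  df$ci_low <- profile$ci_low
  df$ci_high <- profile$ci_high
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
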