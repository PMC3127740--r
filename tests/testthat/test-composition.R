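# Handcrafted profile/duplex tables used to drive the composition statistics
# directly (no file IO, no read mapping).
manual_cohort <- function(seqs, counts_list, bin = "highly_asymmetric") {
  profiles <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    data.frame(hairpin_id = sprintf("h%d", i), arm = "5p",
               sequence = seqs[[i]], start = 1L, count = counts_list[[i]],
               stringsAsFactors = FALSE)
  }))
  duplexes <- data.frame(hairpin_id = sprintf("h%d", seq_along(seqs)),
                         mirna_arm = "5p", bin = bin,
                         stringsAsFactors = FALSE)
  list(profiles = profiles, duplexes = duplexes)
}

test_that("weighted nt-1 frequencies: per-hairpin equal weighting", {
  co <- toy_cohort()
  prof <- profile_isoforms(co$library, co$records)
  dup <- designate_strands(prof, co$records)
  obs <- weighted_nt1_frequencies(dup, prof, "miRNA")
  # hairpin A all-U; hairpin B 75 U-start + 25 A-start reads
  expect_equal(unname(obs["U"]), (1 + 0.75) / 2)
  expect_equal(unname(obs["A"]), 0.125)
  expect_equal(sum(obs), 1)

  # all strands start with U -> freq(U) = 1
  mc <- manual_cohort(list(c("UAAA", "UCCC"), "UGGG"),
                      list(c(5, 5), 10))
  expect_equal(unname(weighted_nt1_frequencies(mc$duplexes, mc$profiles,
                                               "miRNA")["U"]), 1)

  # empty stratum names the filter
  expect_error(
    weighted_nt1_frequencies(dup, prof, "miRNA", stratum = list(bin = "quasisymmetric")),
    "empty stratum.*quasisymmetric")
})

test_that("resampling null: homopolymers, set sizes, reproducibility", {
  mc <- manual_cohort(list(strrep("U", 20), strrep("U", 20)), list(7, 3))
  rs <- resample_background(mc$duplexes, mc$profiles, "miRNA",
                            n_sets = 20, seed = 1)
  expect_equal(dim(rs), c(20L, 4L))
  expect_true(all(rs[, "U"] == 1))

  # each set draws one nucleotide per hairpin-strand: frequencies are
  # multiples of 1/n_hairpins and rows sum to 1
  mc3 <- manual_cohort(list("ACGUACGUACGUACGUAC", "GGGGCCCCAAAAUUUUGG",
                            "AUAUAUAUAUAUAUAUAU"),
                       list(5, 2, 9))
  rs3 <- suppressMessages(
    resample_background(mc3$duplexes, mc3$profiles, "miRNA",
                        n_sets = 50, seed = 2))
  expect_true(all(abs(rowSums(rs3) - 1) < 1e-9))
  expect_true(all(abs(rs3 * 3 - round(rs3 * 3)) < 1e-9))

  a <- resample_background(mc3$duplexes, mc3$profiles, "miRNA", n_sets = 30, seed = 5)
  b <- resample_background(mc3$duplexes, mc3$profiles, "miRNA", n_sets = 30, seed = 5)
  d <- resample_background(mc3$duplexes, mc3$profiles, "miRNA", n_sets = 30, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, d))

  # isoforms shorter than the window truncate it (message, not error)
  short <- manual_cohort(list("ACGU"), list(5))
  expect_message(
    resample_background(short$duplexes, short$profiles, "miRNA",
                        n_sets = 5, seed = 1),
    "truncated")
})

test_that("composition p values: symmetry, closed-form tail, guards", {
  rs <- matrix(0.25, nrow = 10, ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "U")))
  rs[, "U"] <- c(0.20, 0.30, 0.20, 0.30, 0.20, 0.30, 0.20, 0.30, 0.20, 0.30)
  rs[, "A"] <- 0.5 - rs[, "U"]
  mu <- mean(rs[, "U"]); sdev <- sd(rs[, "U"])

  # observed equal to resample mean -> p = 0.5
  obs <- c(A = 0.5 - mu, C = 0.25, G = 0.25, U = mu)
  pv <- composition_pvalue(obs, rs)
  expect_equal(pv$p_gaussian[pv$nt == "U"], 0.5)
  expect_equal(pv$p_empirical[pv$nt == "U"], 0.5)

  # observed = mean + 2 sd -> one-sided Gaussian tail = pnorm(-2)
  obs2 <- c(A = 0.5 - mu - 2 * sdev, C = 0.25, G = 0.25, U = mu + 2 * sdev)
  pv2 <- composition_pvalue(obs2, rs)
  expect_equal(pv2$p_gaussian[pv2$nt == "U"], 0.02275013, tolerance = 1e-6)
  expect_equal(pv2$direction[pv2$nt == "U"], "enriched")
  # empirical p never reaches zero
  expect_gte(min(pv2$p_empirical), 1 / (nrow(rs) + 1))

  # zero resample sd with a deviating observation -> warning, p_gaussian 0
  rs0 <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), each = 5), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "U")))
  obs3 <- c(A = 0.15, C = 0.25, G = 0.25, U = 0.35)
  # both A and U deviate from a zero-spread null: one warning each
  expect_warning(expect_warning(pv3 <- composition_pvalue(obs3, rs0),
                                "zero resample sd"), "zero resample sd")
  expect_equal(pv3$p_gaussian[pv3$nt == "U"], 0)

  # two-sided doubles the one-sided tail
  pv4 <- composition_pvalue(obs2, rs, alternative = "two.sided")
  expect_equal(pv4$p_gaussian[pv4$nt == "U"], 2 * 0.02275013, tolerance = 1e-6)
})

test_that("flanking-U profile: homopolymer and constructed-contrast cohorts", {
  # homopolymer U: profile all 1, CI width 0
  recs <- list(premirna_record("u1", strrep("U", 60), arm5p = c(1, 22),
                               arm3p = c(38, 59)))
  dup <- data.frame(hairpin_id = "u1", mirna_arm = "5p", mirna_start = 22L,
                    stringsAsFactors = FALSE)
  fp <- flanking_u_profile(recs, dup, n_sets = 20, seed = 1)
  expect_true(all(fp$profile$u_freq == 1))
  expect_equal(fp$background_mean, 1)
  expect_equal(fp$ci_high - fp$ci_low, 0)

  # U forced at offset 0, U-free elsewhere: offset 0 above the CI,
  # offsets +-1 below it
  n <- 100
  seqs <- rep(paste0(strrep("A", 20), "U", strrep("A", 20)), n)
  recs2 <- lapply(seq_len(n), function(i) {
    premirna_record(sprintf("c%03d", i), seqs[i], arm5p = c(21, 41))
  })
  dup2 <- data.frame(hairpin_id = sprintf("c%03d", seq_len(n)),
                     mirna_arm = "5p", mirna_start = 21L,
                     stringsAsFactors = FALSE)
  fp2 <- flanking_u_profile(recs2, dup2, n_sets = 100, seed = 3)
  prof <- fp2$profile
  expect_gt(prof$u_freq[prof$offset == 0], fp2$ci_high)
  expect_lt(prof$u_freq[prof$offset == 1], fp2$ci_low)
  expect_lt(prof$u_freq[prof$offset == -1], fp2$ci_low)
  expect_true(fp2$ci_low <= fp2$background_mean &&
                fp2$background_mean <= fp2$ci_high)

  # out-of-bounds offsets are skipped per hairpin
  recs3 <- list(premirna_record("s1", strrep("A", 30), arm5p = c(3, 24)))
  dup3 <- data.frame(hairpin_id = "s1", mirna_arm = "5p", mirna_start = 3L,
                     stringsAsFactors = FALSE)
  fp3 <- flanking_u_profile(recs3, dup3, n_sets = 5, seed = 1)
  expect_equal(fp3$profile$n_hairpins[fp3$profile$offset == -10], 0L)
  expect_equal(fp3$profile$n_hairpins[fp3$profile$offset == 0], 1L)

  expect_error(flanking_u_profile(recs, dup, halfwidth = -1), "halfwidth")
})
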