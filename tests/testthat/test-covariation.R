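test_that("feature vectors: length 144, self-feature, manual transcription", {
  desc <- feature_descriptors()
  expect_equal(nrow(desc), 144L)
  expect_equal(sum(desc$block == "identity"), 72L)

  # perfect-complement 21/21 duplex: identities read off the strands, all
  # positions paired; transcription checked by hand for both anchors
  a <- "GCGCGCGCGCGCGCGCGCGCG"
  b <- chartr("GC", "CG", paste(rev(strsplit(a, "")[[1]]), collapse = ""))
  st <- pairing_status(pair_probabilities(a, b))
  fv <- build_feature_vector(a, b, st, duplex_id = "toy")
  expect_length(fv$features, 144L)
  expect_equal(fv$nt1, "G")
  expect_equal(unname(fv$features["mirna|5p|01|identity"]), fv$nt1)
  expect_equal(unname(fv$features["mirna|5p|03|identity"]), substr(a, 3, 3))
  expect_equal(unname(fv$features["mirna|3p|02|identity"]), substr(a, 20, 20))
  expect_equal(unname(fv$features["star|5p|04|identity"]), substr(b, 4, 4))
  expect_equal(unname(fv$features["star|3p|01|identity"]), substr(b, 21, 21))
  expect_true(all(fv$features[desc$feature[desc$block == "pairing"]] == "paired"))

  # 17-nt strand: position 18 is missing on both anchors, vector still 144
  a17 <- substr(a, 1, 17)
  st17 <- pairing_status(pair_probabilities(a17, b))
  fv17 <- build_feature_vector(a17, b, st17)
  expect_length(fv17$features, 144L)
  expect_true(is.na(fv17$features["mirna|5p|18|identity"]))
  expect_true(is.na(fv17$features["mirna|3p|18|pairing"]))
  expect_false(anyNA(fv17$features[grepl("^star", names(fv17$features))]))
})

test_that("fisher_exact: exact values, oracle agreement, invariances", {
  expect_warning(r0 <- fisher_exact(matrix(c(5, 0, 5, 0), 2)), "degenerate")
  expect_equal(r0$p, 1)

  expect_equal(fisher_exact(matrix(5, 2, 2))$p, 1)

  t1 <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  r1 <- fisher_exact(t1, method = "exact")
  expect_equal(r1$method_used, "exact_2xc")
  expect_equal(r1$p, bf_fisher_p(t1), tolerance = 1e-10)
  expect_equal(r1$p, 0.005477495, tolerance = 1e-7)  # frozen enumeration value

  # random small tables: package exact == full-enumeration oracle ==
  # stats::fisher.test, and row/column permutation invariance
  withr::with_seed(11, {
    for (rep in seq_len(20)) {
      r <- sample(2:3, 1); cc <- sample(2:4, 1)
      tab <- matrix(rpois(r * cc, 3), r, cc)
      tab[1, 1] <- tab[1, 1] + 2
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p_pkg <- fisher_exact(tab, method = "exact")$p
      expect_equal(p_pkg, bf_fisher_p(tab), tolerance = 1e-7)
      expect_equal(p_pkg, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
      perm <- tab[sample(r), sample(cc), drop = FALSE]
      expect_equal(fisher_exact(perm, method = "exact")$p, p_pkg,
                   tolerance = 1e-7)
    }
  })
})

test_that("Monte-Carlo branch agrees with exact within 3 SE and is seeded", {
  withr::with_seed(13, {
    tabs <- list(matrix(c(9, 3, 2, 7, 5, 4, 1, 6), 4, 2),      # 4x2, n ~ 37
                 matrix(c(8, 2, 1, 9), 2, byrow = TRUE),
                 matrix(rpois(9, 4) + 1, 3, 3))
    for (tab in tabs) {
      p_ex <- fisher_exact(tab, method = "exact")$p
      mc <- fisher_exact(tab, method = "monte_carlo", n_mc = 4000, seed = 99)
      expect_equal(mc$method_used, "monte_carlo")
      se <- sqrt(p_ex * (1 - p_ex) / 4000)
      expect_lt(abs(mc$p - p_ex), 3 * se + 2 / 4000)
      mc2 <- fisher_exact(tab, method = "monte_carlo", n_mc = 4000, seed = 99)
      expect_identical(mc$p, mc2$p)
    }
  })
})

# fabricated feature vectors: nt1 balanced over ACGU; one feature depends on
# nt1, the rest are iid noise
fabricate_fvecs <- function(n, target = "mirna|5p|02|identity", p_dep = 0.9) {
  desc <- feature_descriptors()
  lapply(seq_len(n), function(i) {
    nt1 <- c("A", "C", "G", "U")[1 + (i %% 4)]
    vals <- sample(c("A", "C", "G", "U"), 144, replace = TRUE)
    vals[desc$block == "pairing"] <-
      sample(c("paired", "unpaired"), 72, replace = TRUE)
    names(vals) <- desc$feature
    vals["mirna|5p|01|identity"] <- nt1
    if (nt1 == "U" && runif(1) < p_dep) vals[target] <- "U"
    structure(list(duplex_id = sprintf("d%d", i), nt1 = nt1,
                   features = vals), class = "feature_vector")
  })
}

test_that("covariation scan recovers a planted dependency and orders output", {
  withr::with_seed(21, fv <- fabricate_fvecs(120))
  scan <- covariation_scan(fv, seed = 1)
  expect_s3_class(scan, "covariation_result")
  expect_equal(nrow(scan), 144L)
  expect_equal(scan$feature, feature_descriptors()$feature)
  expect_true(all(scan$p > 0 & scan$p <= 1))
  expect_true(all(scan$n_used == 120L))
  # self-correlation at miRNA 5' position 1 sits at the Monte-Carlo floor
  expect_lte(scan$p[scan$feature == "mirna|5p|01|identity"],
             1 / (1 + 10000) + 1e-12)
  # planted dependency is the most significant non-position-1 feature
  non1 <- scan[scan$position != 1L, ]
  expect_equal(non1$feature[which.min(non1$p)], "mirna|5p|02|identity")
  expect_equal(scan$p_bonferroni, pmin(1, scan$p * 144))

  expect_error(covariation_scan(fv[c(4, 8)]), "constant")
})
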