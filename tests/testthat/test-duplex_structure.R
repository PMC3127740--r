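test_that("perfect complement duplex pairs every position with its mirror", {
  # homopolymer: every register is complementary, so terminal pairs fray
  # slightly across shifted registers (~0.90); interior positions saturate
  m <- pair_probabilities("GGGGGGGGGG", "CCCCCCCCCC")
  expect_true(all(1 - m$unpaired_a > 0.85))
  expect_true(all((1 - m$unpaired_a)[2:9] > 0.9))
  s <- pairing_status(m)
  expect_equal(s$partner_a, 11L - seq_len(10L))

  # heteropolymer perfect complement: unique register, all positions > 0.9
  a <- "GCGAUCGGAC"
  b <- chartr("ACGU", "UGCA", paste(rev(strsplit(a, "")[[1]]), collapse = ""))
  m2 <- pair_probabilities(a, b)
  expect_true(all(1 - m2$unpaired_a > 0.9))
  expect_equal(pairing_status(m2)$partner_a, 11L - seq_len(10L))
})

test_that("builtin engine equals exhaustive enumeration (fixed toy + random pairs)", {
  # 4-nt toy duplex, checked against full enumeration
  toy <- pair_probabilities("GCAU", "AUGC")
  bf <- bf_pair_probabilities("GCAU", "AUGC")
  expect_equal(toy$p, bf$p, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(toy$Z, bf$Z, tolerance = 1e-9)

  # property: 100 random pairs with lengths <= 6
  withr::with_seed(42, {
    for (rep in seq_len(100)) {
      la <- sample(1:6, 1); lb <- sample(1:6, 1)
      sa <- random_rna(1, la); sb <- random_rna(1, lb)
      got <- pair_probabilities(sa, sb)
      want <- bf_pair_probabilities(sa, sb)
      expect_equal(got$p, want$p, tolerance = 1e-9, ignore_attr = TRUE)
      # conservation
      expect_true(all(abs(rowSums(got$p) + got$unpaired_a - 1) < 1e-9))
      expect_true(all(abs(colSums(got$p) + got$unpaired_b - 1) < 1e-9))
    }
  })
})

test_that("pair_probabilities(a, b) and (b, a) are transposes", {
  withr::with_seed(7, {
    for (rep in seq_len(20)) {
      sa <- random_rna(1, sample(3:10, 1)); sb <- random_rna(1, sample(3:10, 1))
      expect_equal(pair_probabilities(sa, sb)$p,
                   t(pair_probabilities(sb, sa)$p),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  })
})

test_that("miR-2a nt 1 is called paired with miR-2a-1* position 19", {
  m <- pair_probabilities(MIR2A, MIR2A1S)
  s <- pairing_status(m)
  expect_true(s$paired_a[1])
  expect_equal(s$partner_a[1], 19L)
})

test_that("pairing call is strict at the threshold", {
  # hand-built matrix: a1 exactly 0.5, a2 just above
  fake <- structure(list(
    seq_a = "AU", seq_b = "AU",
    p = matrix(c(0, 0.5, 0.51, 0), 2, 2, byrow = TRUE),
    unpaired_a = c(0.5, 0.49), unpaired_b = c(0.49, 0.5)),
    class = "pairprob_matrix")
  s <- pairing_status(fake)
  expect_false(s$paired_a[1])   # exactly 0.5 -> unpaired
  expect_true(s$paired_a[2])
  expect_equal(s$partner_a, c(NA_integer_, 1L))

  zero <- structure(list(seq_a = "AU", seq_b = "AU",
                         p = matrix(0, 2, 2),
                         unpaired_a = c(1, 1), unpaired_b = c(1, 1)),
                    class = "pairprob_matrix")
  expect_false(any(pairing_status(zero)$paired_a))
})

test_that("extract_duplex returns abundance-top isoforms with tie rules", {
  rec <- mir2a_record()
  # two 3p isoforms, counts 10 vs 11: the 11-count isoform wins
  iso2 <- substr(PRE_MIR2A1, 43, 64)
  lib <- read_library(stats::setNames(c(10, 11, 50),
                                      c(MIR2A, iso2, MIR2A1S)))
  prof <- profile_isoforms(lib, list(rec))
  d <- extract_duplex(rec, prof)
  expect_equal(d$seq_a, MIR2A1S)    # 5p arm is the more abundant strand here
  expect_equal(d$seq_b, iso2)

  # single-isoform arms pass through; Table 1 strands as sole isoforms
  lib <- read_library(stats::setNames(c(500, 40), c(MIR2A, MIR2A1S)))
  prof <- profile_isoforms(lib, list(rec))
  d <- extract_duplex(rec, prof)
  expect_equal(d$seq_a, MIR2A)
  expect_equal(d$seq_b, MIR2A1S)

  lib <- read_library(stats::setNames(500, MIR2A))
  expect_error(extract_duplex(rec, profile_isoforms(lib, list(rec))),
               "no isoforms")
})

test_that("external engine adapter honors the matrix contract and falls back", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "probs.tsv")
  writeLines(c("pos_a\tpos_b\tprob", "1\t4\t0.9", "2\t3\t0.8"), f)
  m <- pair_probabilities("GCAU", "AUGC", engine = "external", external_file = f)
  expect_equal(m$p[1, 4], 0.9)
  expect_equal(m$unpaired_a[[1]], 0.1)
  expect_equal(m$engine, "external")

  expect_warning(
    m2 <- pair_probabilities("GCAU", "AUGC", engine = "external",
                             external_file = file.path(dir, "nope.tsv")),
    "falling back")
  expect_equal(m2$engine, "builtin")

  writeLines(c("pos_a\tpos_b\tprob", "1\t4\t0.9", "1\t3\t0.8"), f)
  expect_error(pair_probabilities("GCAU", "AUGC", engine = "external",
                                  external_file = f), "conservation")
})

test_that("invalid sequences are rejected", {
  expect_error(pair_probabilities("ACGX", "ACGU"), "non-ACGU")
  expect_error(pair_probabilities("", "ACGU"))
  expect_error(pair_probabilities(strrep("A", 51), "ACGU"), "1..50")
})
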