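# Shared fixtures, built in code.

# The miR-2a-1 worked example: precursor, guide and star strands.
MIR2A   <- "UAUCACAGCCAGCUUUGAUGAGC"                # 3p arm, 23 nt, starts U
MIR2A1S <- "UCUCAAAGUGGUUGUGAAAUG"                  # 5p arm, 21 nt
PRE_MIR2A1 <- "UCUCAAAGUGGUUGUGAAAUGCAUUUCCGCUUUGCGCGGCAUAUCACAGCCAGCUUUGAUGAGC"

mir2a_record <- function() {
  premirna_record("pre-miR-2a-1", PRE_MIR2A1, arm5p = c(1, 21),
                  arm3p = c(42, 64), species = "dme")
}

# Write a cohort of records + tag counts to tempdir files; returns paths.
write_fixture_files <- function(records, counts, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "hairpins.fa")
  tsv <- file.path(dir, "mature.tsv")
  tags <- file.path(dir, "tags.tsv")
  write_annotations(records, fa, tsv, format = "tsv")
  write_tag_counts(read_library(counts), tags)
  list(fa = fa, tsv = tsv, tags = tags, dir = dir)
}

# Two-hairpin toy cohort with hand-controlled isoform structure:
# hairpin A: both strands single-isoform; hairpin B: miRNA arm has a U-start
# isoform (75 reads) and an A-start isoform (25 reads).
toy_cohort <- function() {
  # arms are designed substrings; loops keep arms unique
  hpA <- paste0("UGGCAUAGCUCAGGCAAGGCAU", "CCCCCCCCCCCCCCC",
                "AUGCCAACGCUGAGCAAUGCCA")
  hpB <- paste0("UAGCGUAAGCUCAGGGCAAGAC", "GGGGGGGGGGGGGGG",
                "AUCUUGCACUGAGCAUACGCUA")
  recA <- premirna_record("hpA", hpA, arm5p = c(1, 22), arm3p = c(38, 59))
  recB <- premirna_record("hpB", hpB, arm5p = c(1, 22), arm3p = c(38, 59))
  counts <- c(
    stats::setNames(400, substr(hpA, 1, 22)),    # A miRNA (5p), starts U
    stats::setNames(40,  substr(hpA, 38, 59)),   # A star (3p)
    stats::setNames(75,  substr(hpB, 1, 22)),    # B miRNA isoform 1, starts U
    stats::setNames(25,  substr(hpB, 2, 23)),    # B miRNA isoform 2, starts A
    stats::setNames(10,  substr(hpB, 38, 59)))   # B star (3p)
  list(records = list(recA, recB), library = read_library(counts))
}
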