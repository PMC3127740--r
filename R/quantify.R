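# Tag-to-hairpin assignment, isoform profiles, strand designation,
# expression filtering and asymmetry binning.

#' Profile mature-strand isoforms from a tag-count library
#'
#' A tag is assigned to an arm of a hairpin iff it matches the hairpin exactly
#' (substring, sense strand only) with its 5' end within `arm_window`
#' nucleotides of the annotated arm start. Matching is exact: no mismatches, no
#' trimming of untemplated additions. A tag matching several hairpins (or both
#' arms) contributes its full count to each match. Tags assigned nowhere are
#' tallied, not dropped silently.
#'
#' @param library a [read_library] (typically pooled).
#' @param records list of [premirna_record].
#' @param arm_window maximum distance (nt) between the tag 5' end and the
#'   annotated arm start (default 5).
#' @return a data frame of class `isoform_profiles` with columns `hairpin_id`,
#'   `arm`, `sequence`, `start` (1-based on the hairpin) and `count`, plus
#'   attributes `unmatched_tags` (count of distinct tags) and
#'   `unmatched_reads`.
#' @export
profile_isoforms <- function(library, records, arm_window = 5L) {
  stopifnot(arm_window >= 0)
  tags <- names(library$counts)
  tag_lens <- sort(unique(nchar(tags)))

  # Dictionary of candidate substrings around each annotated arm start:
  # substring -> all (hairpin, arm, start) locations producing it.
  keys <- character(0); locs <- list()
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    hlen <- nchar(rec$hairpin_seq)
    for (arm in c("5p", "3p")) {
      co <- arm_coords(rec, arm)
      if (is.null(co)) next
      starts <- max(1L, co[1] - arm_window):min(hlen, co[1] + arm_window)
      for (s in starts) {
        for (L in tag_lens) {
          if (s + L - 1L > hlen) next
          key <- substr(rec$hairpin_seq, s, s + L - 1L)
          keys[length(keys) + 1L] <- key
          locs[[length(locs) + 1L]] <- list(hairpin_id = rec$id, arm = arm, start = s)
        }
      }
    }
  }
  dict <- split(locs, keys)

  rows <- list(); unmatched_tags <- 0L; unmatched_reads <- 0
  for (tag in tags) {
    hits <- dict[[tag]]
    if (is.null(hits)) {
      unmatched_tags <- unmatched_tags + 1L
      unmatched_reads <- unmatched_reads + library$counts[[tag]]
      next
    }
    for (h in hits) {
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_id = h$hairpin_id, arm = h$arm, sequence = tag,
        start = h$start, count = as.numeric(library$counts[[tag]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hairpin_id = character(0), arm = character(0),
               sequence = character(0), start = integer(0), count = numeric(0))
  out <- out[order(out$hairpin_id, out$arm, out$start, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched_tags") <- unmatched_tags
  attr(out, "unmatched_reads") <- unmatched_reads
  class(out) <- c("isoform_profiles", "data.frame")
  out
}

# Most abundant isoform of one arm; ties broken toward the isoform starting
# closest to the annotated arm start, then 5'-most.
top_isoform <- function(profiles, hairpin_id, arm, record) {
  sub <- profiles[profiles$hairpin_id == hairpin_id & profiles$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  co <- arm_coords(record, arm)
  sub <- sub[order(-sub$count, abs(sub$start - co[1]), sub$start), , drop = FALSE]
  sub[1L, , drop = FALSE]
}

#' Designate miRNA and miRNA* strands and build the duplex table
#'
#' For each hairpin with at least one isoform on each arm, the arm with the
#' larger pooled read count is designated the miRNA (guide); ties go to the 5p
#' arm. Annotation-derived labels can override abundance via `mirna_arms`.
#' Hairpins with a silent arm are excluded and tallied.
#'
#' @param profiles an `isoform_profiles` data frame from [profile_isoforms()].
#' @param records list of [premirna_record] (for top-isoform tie-breaking).
#' @param mirna_arms optional named character vector `hairpin_id -> "5p"/"3p"`
#'   overriding abundance-based designation.
#' @return a data frame of class `duplex_table` with columns `hairpin_id`,
#'   `mirna_arm`, `mirna_seq`, `star_seq`, `mirna_start`, `star_start`,
#'   `mirna_count`, `star_count`, `total`, `ratio`, `bin`; attribute
#'   `excluded` lists single-arm hairpins.
#' @export
designate_strands <- function(profiles, records, mirna_arms = NULL) {
  recs <- stats::setNames(records, vapply(records, `[[`, "", "id"))
  ids <- unique(profiles$hairpin_id)
  rows <- list(); excluded <- character(0)
  for (id in ids) {
    rec <- recs[[id]]
    counts <- vapply(c("5p", "3p"), function(a) {
      sum(profiles$count[profiles$hairpin_id == id & profiles$arm == a])
    }, numeric(1))
    if (any(counts == 0)) { excluded <- c(excluded, id); next }
    guide <- if (!is.null(mirna_arms) && !is.na(mirna_arms[id])) {
      unname(mirna_arms[id])
    } else if (counts["3p"] > counts["5p"]) "3p" else "5p"
    star <- setdiff(c("5p", "3p"), guide)
    top_g <- top_isoform(profiles, id, guide, rec)
    top_s <- top_isoform(profiles, id, star, rec)
    ratio <- counts[guide] / counts[star]
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin_id = id, mirna_arm = guide,
      mirna_seq = top_g$sequence, star_seq = top_s$sequence,
      mirna_start = top_g$start, star_start = top_s$start,
      mirna_count = counts[[guide]], star_count = counts[[star]],
      total = sum(counts), ratio = unname(ratio),
      bin = if (ratio >= 1) bin_asymmetry(ratio) else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hairpin_id = character(0), mirna_arm = character(0),
               mirna_seq = character(0), star_seq = character(0),
               mirna_start = integer(0), star_start = integer(0),
               mirna_count = numeric(0), star_count = numeric(0),
               total = numeric(0), ratio = numeric(0), bin = character(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("duplex_table", "data.frame")
  out
}

#' Keep duplexes passing the read-depth filter
#'
#' By default a duplex is kept when the pooled hairpin total (both strands,
#' all isoforms) is at least `min_reads`; with `per_strand = TRUE` both
#' strands must individually reach `min_reads`.
#'
#' @param duplexes a `duplex_table`.
#' @param min_reads minimum pooled read count (default 100).
#' @param per_strand apply the threshold to each strand separately.
#' @return the filtered `duplex_table`.
#' @export
filter_expressed <- function(duplexes, min_reads = 100L, per_strand = FALSE) {
  stopifnot(min_reads >= 0)
  keep <- if (per_strand) {
    duplexes$mirna_count >= min_reads & duplexes$star_count >= min_reads
  } else {
    duplexes$total >= min_reads
  }
  out <- duplexes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- attr(duplexes, "excluded")
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("duplex_table", "data.frame")
  out
}

#' Bin a miRNA/miRNA* asymmetry ratio
#'
#' Ratios at least 10 are `highly_asymmetric`, ratios in \[2, 10) are
#' `moderately_asymmetric` and ratios in \[1, 2) are `quasisymmetric`; the
#' three bins partition \[1, Inf\]. Vectorized.
#'
#' @param ratio numeric vector of miRNA/miRNA* count ratios (>= 1, `Inf`
#'   allowed for a silent miRNA* strand).
#' @param high,moderate bin thresholds; must satisfy `high > moderate > 1`.
#' @return character vector of bin labels.
#' @export
bin_asymmetry <- function(ratio, high = 10, moderate = 2) {
  stopifnot(high > moderate, moderate > 1)
  if (any(is.na(ratio)) || any(ratio < 1)) {
    stop("bin_asymmetry: ratio must be >= 1 (miRNA is the more abundant strand)")
  }
  ifelse(ratio >= high, "highly_asymmetric",
         ifelse(ratio >= moderate, "moderately_asymmetric", "quasisymmetric"))
}

#' Write the duplex table to TSV
#' @param duplexes a `duplex_table`.
#' @param path output path.
#' @export
write_duplex_table <- function(duplexes, path) {
  utils::write.table(as.data.frame(duplexes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
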