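# Reading and writing hairpin annotations and small-RNA tag-count libraries.

#' Construct a pre-miRNA hairpin record
#'
#' A hairpin record holds the precursor sequence (RNA alphabet, 5'->3') and
#' 1-based inclusive coordinates of the mature arms on that sequence. Either
#' arm may be absent (`NULL`).
#'
#' @param id hairpin identifier.
#' @param hairpin_seq precursor sequence; T is normalized to U.
#' @param arm5p,arm3p integer `c(start, end)` or `NULL`.
#' @param species free-text species label.
#' @return an object of class `premirna_record`.
#' @export
premirna_record <- function(id, hairpin_seq, arm5p = NULL, arm3p = NULL,
                            species = NA_character_) {
  hairpin_seq <- normalize_rna(hairpin_seq, sprintf("hairpin '%s'", id))
  len <- nchar(hairpin_seq)
  chk <- function(arm, lab) {
    if (is.null(arm)) return(NULL)
    arm <- as.integer(arm)
    if (length(arm) != 2L || anyNA(arm)) {
      stop(sprintf("hairpin '%s': %s arm must be c(start, end)", id, lab))
    }
    if (arm[1] < 1L || arm[2] > len || arm[1] > arm[2]) {
      stop(sprintf("hairpin '%s': %s arm coordinates %d-%d out of bounds (length %d)",
                   id, lab, arm[1], arm[2], len))
    }
    arm
  }
  arm5p <- chk(arm5p, "5p")
  arm3p <- chk(arm3p, "3p")
  if (!is.null(arm5p) && !is.null(arm3p) && arm5p[2] >= arm3p[1]) {
    stop(sprintf("hairpin '%s': 5p arm must end before 3p arm starts", id))
  }
  structure(list(id = as.character(id), species = as.character(species),
                 hairpin_seq = hairpin_seq, arm5p = arm5p, arm3p = arm3p),
            class = "premirna_record")
}

#' @export
print.premirna_record <- function(x, ...) {
  fmt <- function(a) if (is.null(a)) "absent" else sprintf("%d-%d", a[1], a[2])
  cat(sprintf("<premirna_record> %s (%d nt; 5p arm %s; 3p arm %s)\n",
              x$id, nchar(x$hairpin_seq), fmt(x$arm5p), fmt(x$arm3p)))
  invisible(x)
}

#' Extract a mature-arm sequence from a hairpin record
#'
#' @param record a `premirna_record`.
#' @param arm `"5p"` or `"3p"`.
#' @return the arm sequence, or `NA` if the arm is absent.
#' @export
arm_seq <- function(record, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  coords <- if (arm == "5p") record$arm5p else record$arm3p
  if (is.null(coords)) return(NA_character_)
  substr(record$hairpin_seq, coords[1], coords[2])
}

arm_coords <- function(record, arm) {
  if (arm == "5p") record$arm5p else record$arm3p
}

#' Read hairpin annotations
#'
#' Reads precursor sequences from a FASTA file and mature-arm coordinates from
#' either a miRBase-dialect GFF3 (feature type `miRNA`, coordinates relative to
#' the hairpin, attributes `ID` and `Derives_from`) or a 6-column TSV
#' (`hairpin_id`, `arm` in \{5p, 3p\}, `start`, `end`, `name`, `species`).
#' Coordinates are 1-based inclusive. Input order of the FASTA is preserved.
#'
#' @param hairpin_fasta path to the precursor FASTA.
#' @param mature_coords path to the coordinate file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return a list of [premirna_record] objects.
#' @export
read_annotations <- function(hairpin_fasta, mature_coords,
                             format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", mature_coords, ignore.case = TRUE)) "gff3" else "tsv"
  }
  seqs <- Biostrings::readBStringSet(hairpin_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  seqs <- stats::setNames(normalize_rna(as.character(seqs), "hairpin FASTA"), ids)

  coords <- switch(format,
    tsv = read_coords_tsv(mature_coords),
    gff3 = read_coords_gff3(mature_coords))

  missing <- setdiff(unique(coords$hairpin_id), ids)
  if (length(missing) > 0) {
    stop(sprintf("coordinate file references hairpin id(s) absent from FASTA: %s",
                 paste(missing, collapse = ", ")))
  }

  lapply(ids, function(id) {
    rows <- coords[coords$hairpin_id == id, , drop = FALSE]
    get_arm <- function(a) {
      r <- rows[rows$arm == a, , drop = FALSE]
      if (nrow(r) == 0) return(NULL)
      if (nrow(r) > 1) stop(sprintf("hairpin '%s': multiple %s arm entries", id, a))
      c(r$start, r$end)
    }
    sp <- if (nrow(rows) > 0 && !all(is.na(rows$species))) rows$species[1] else NA_character_
    premirna_record(id, seqs[[id]], arm5p = get_arm("5p"), arm3p = get_arm("3p"),
                    species = sp)
  })
}

read_coords_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("hairpin_id", "arm", "start", "end",
                                        "name", "species"),
                          colClasses = c("character", "character", "integer",
                                         "integer", "character", "character"),
                          comment.char = "#", blank.lines.skip = TRUE,
                          fill = FALSE)
  if (nrow(df) > 0 && !all(df$arm %in% c("5p", "3p"))) {
    stop("coordinate TSV: arm column must be '5p' or '3p'")
  }
  df
}

read_coords_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "miRNA"]
  hairpin <- if (!is.null(gr$Derives_from)) {
    as.character(gr$Derives_from)
  } else {
    as.character(GenomicRanges::seqnames(gr))
  }
  hairpin[is.na(hairpin)] <- as.character(GenomicRanges::seqnames(gr))[is.na(hairpin)]
  name <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  df <- data.frame(hairpin_id = hairpin,
                   arm = NA_character_,
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   name = name,
                   species = NA_character_,
                   stringsAsFactors = FALSE)
  # Arm from a -5p/-3p name suffix when present, otherwise by position order
  # within the hairpin (the earlier feature is the 5p arm).
  suf <- ifelse(grepl("-5p$", df$name), "5p",
                ifelse(grepl("-3p$", df$name), "3p", NA))
  df$arm <- suf
  for (h in unique(df$hairpin_id)) {
    idx <- which(df$hairpin_id == h)
    if (anyNA(df$arm[idx])) {
      ord <- idx[order(df$start[idx])]
      df$arm[ord] <- if (length(ord) == 1L) "5p" else c("5p", "3p")[seq_along(ord)]
    }
  }
  df
}

#' Write hairpin annotations
#'
#' Writes the FASTA and coordinate files that [read_annotations()] reads.
#'
#' @param records list of [premirna_record].
#' @param hairpin_fasta,mature_coords output paths.
#' @param format coordinate dialect, `"tsv"` or `"gff3"`.
#' @export
write_annotations <- function(records, hairpin_fasta, mature_coords,
                              format = c("tsv", "gff3")) {
  format <- match.arg(format)
  fa <- Biostrings::BStringSet(vapply(records, `[[`, "", "hairpin_seq"))
  names(fa) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(fa, hairpin_fasta)

  rows <- list()
  for (rec in records) {
    for (arm in c("5p", "3p")) {
      co <- arm_coords(rec, arm)
      if (is.null(co)) next
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_id = rec$id, arm = arm, start = co[1], end = co[2],
        name = paste0(rec$id, "-", arm),
        species = ifelse(is.na(rec$species), ".", rec$species),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (format == "tsv") {
    utils::write.table(df, mature_coords, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    lines <- c("##gff-version 3",
               sprintf("%s\tmirasym\tmiRNA\t%d\t%d\t.\t+\t.\tID=%s;Name=%s;Derives_from=%s",
                       df$hairpin_id, df$start, df$end, df$name, df$name, df$hairpin_id))
    writeLines(lines, mature_coords)
  }
  invisible(NULL)
}

#' Construct a read library
#'
#' @param counts named numeric vector: tag sequence -> read count.
#' @param source_ids character vector of source labels (e.g. GEO accessions).
#' @return an object of class `read_library`.
#' @export
read_library <- function(counts, source_ids = character()) {
  if (length(counts) > 0) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("read_library: counts must be named by tag sequence")
    }
    names(counts) <- normalize_rna(names(counts), "tag")
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("read_library: counts must be non-negative integers")
    }
    # merge duplicates that may arise from T->U normalization
    counts <- tapply(as.numeric(counts), names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    counts <- stats::setNames(numeric(0), character(0))
  }
  structure(list(source_ids = as.character(source_ids), counts = counts),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> %d tags, %s reads (sources: %s)\n",
              length(x$counts), format(sum(x$counts), big.mark = ","),
              if (length(x$source_ids)) paste(x$source_ids, collapse = ",") else "unnamed"))
  invisible(x)
}

#' Read a small-RNA tag-count library
#'
#' Two dialects are supported: a 2-column TSV (`sequence`, `count`) and a
#' FASTA whose headers carry the count as an `_xN` suffix (e.g. `>tag1_x9`).
#' Duplicate tags within one file have their counts summed.
#'
#' @param path input path.
#' @param dialect `"auto"`, `"tsv"` or `"fasta_count_header"`.
#' @param source_id label recorded in the library (defaults to the file name).
#' @return a [read_library].
#' @export
read_tag_counts <- function(path, dialect = c("auto", "tsv", "fasta_count_header"),
                            source_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(source_id)) source_id <- basename(path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (length(first) > 0 && startsWith(first, ">")) "fasta_count_header" else "tsv"
  }
  if (dialect == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) == 0) return(read_library(numeric(0), source_id))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    tags <- character(length(parts)); cnts <- numeric(length(parts))
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) < 2L) stop(sprintf("%s line %d: expected 2 tab-separated fields", path, i))
      n <- suppressWarnings(as.numeric(p[2]))
      if (is.na(n) || n < 0 || n != round(n)) {
        stop(sprintf("%s line %d: count '%s' is not a non-negative integer", path, i, p[2]))
      }
      tags[i] <- p[1]; cnts[i] <- n
    }
  } else {
    fa <- Biostrings::readBStringSet(path)
    if (length(fa) == 0) return(read_library(numeric(0), source_id))
    hdr <- sub("\\s.*$", "", names(fa))
    m <- regmatches(hdr, regexpr("_x([0-9]+)$", hdr))
    if (length(m) != length(hdr) || any(!nzchar(m))) {
      bad <- which(!grepl("_x[0-9]+$", hdr))[1]
      stop(sprintf("%s record %d: header '%s' lacks an _xN count suffix",
                   path, bad, hdr[bad]))
    }
    cnts <- as.numeric(sub("^_x", "", m))
    tags <- as.character(fa)
  }
  tags <- normalize_rna(tags, sprintf("tag in %s", path))
  agg <- tapply(cnts, tags, sum)
  read_library(stats::setNames(as.numeric(agg), names(agg)), source_id)
}

#' Write a tag-count library
#'
#' @param library a [read_library].
#' @param path output path.
#' @param dialect `"tsv"` or `"fasta_count_header"`.
#' @export
write_tag_counts <- function(library, path, dialect = c("tsv", "fasta_count_header")) {
  dialect <- match.arg(dialect)
  tags <- sort(names(library$counts))
  cnts <- library$counts[tags]
  if (dialect == "tsv") {
    writeLines(sprintf("%s\t%d", tags, as.integer(cnts)), path)
  } else {
    writeLines(as.vector(rbind(sprintf(">tag%d_x%d", seq_along(tags), as.integer(cnts)),
                               tags)), path)
  }
  invisible(NULL)
}

#' Pool several read libraries
#'
#' Counts are summed tag-wise; source ids are concatenated.
#'
#' @param libraries a list of [read_library] objects.
#' @return a single pooled [read_library].
#' @export
pool_libraries <- function(libraries) {
  if (!is.list(libraries) || length(libraries) == 0 ||
      inherits(libraries, "read_library")) {
    if (inherits(libraries, "read_library")) libraries <- list(libraries)
    else stop("pool_libraries: need a non-empty list of read_library objects")
  }
  all_tags <- unlist(lapply(libraries, function(l) names(l$counts)))
  all_cnts <- unlist(lapply(libraries, function(l) unname(l$counts)))
  if (length(all_tags) == 0) {
    return(read_library(numeric(0),
                        unlist(lapply(libraries, `[[`, "source_ids"))))
  }
  agg <- tapply(all_cnts, all_tags, sum)
  read_library(stats::setNames(as.numeric(agg), names(agg)),
               unlist(lapply(libraries, `[[`, "source_ids")))
}
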