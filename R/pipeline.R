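# End-to-end orchestration: config handling, staged execution, reports,
# manifest and accounting log.

#' Build a pipeline configuration
#'
#' Houses the analysis constants: the 100-read expression filter, the
#' asymmetry bin thresholds (10 and 2), the 100-set resampling null over
#' nt 1-18, and the 0.5 pairing-probability call threshold. Every stochastic
#' stage derives its stream from `seed`.
#'
#' @param hairpin_fasta,mature_coords,tag_counts input paths (`tag_counts`
#'   may list several libraries, pooled before analysis).
#' @param out_dir report directory.
#' @param min_reads,per_strand expression filter (see [filter_expressed()]).
#' @param arm_window isoform admission window (see [profile_isoforms()]).
#' @param bin_high,bin_moderate asymmetry bin thresholds.
#' @param n_sets,window resampling null (see [resample_background()]).
#' @param pairing_threshold paired/unpaired call cutoff.
#' @param engine,external_file pair-probability engine selection.
#' @param fisher_method,max_tables,n_mc Fisher's exact test settings.
#' @param strata `"all"`, `"by_arm"`, `"by_bin"` or a combination; selects the
#'   composition strata analyzed.
#' @param alternative sidedness of composition p values.
#' @param flank_halfwidth half-width of the flanking-U window.
#' @param collapse_nt1 collapse nt1 to U vs non-U in the covariation scan.
#' @param seed master seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(hairpin_fasta, mature_coords, tag_counts, out_dir,
                            min_reads = 100L, per_strand = FALSE,
                            arm_window = 5L, bin_high = 10, bin_moderate = 2,
                            n_sets = 100L, window = 1:18,
                            pairing_threshold = 0.5,
                            engine = "builtin", external_file = NULL,
                            fisher_method = "auto", max_tables = 1e6,
                            n_mc = 10000L,
                            strata = c("all", "by_arm", "by_bin"),
                            alternative = "one.sided",
                            flank_halfwidth = 10L, collapse_nt1 = FALSE,
                            seed = 1L) {
  stopifnot(min_reads >= 0, arm_window >= 0, bin_high > bin_moderate,
            bin_moderate > 1, n_sets >= 1, pairing_threshold > 0,
            flank_halfwidth >= 0, n_mc >= 1)
  structure(list(hairpin_fasta = hairpin_fasta, mature_coords = mature_coords,
                 tag_counts = tag_counts, out_dir = out_dir,
                 min_reads = as.integer(min_reads), per_strand = per_strand,
                 arm_window = as.integer(arm_window),
                 bin_high = bin_high, bin_moderate = bin_moderate,
                 n_sets = as.integer(n_sets), window = window,
                 pairing_threshold = pairing_threshold,
                 engine = engine, external_file = external_file,
                 fisher_method = fisher_method, max_tables = max_tables,
                 n_mc = as.integer(n_mc), strata = strata,
                 alternative = alternative,
                 flank_halfwidth = as.integer(flank_halfwidth),
                 collapse_nt1 = collapse_nt1, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; `tag_counts` and `strata`
#' accept comma-separated lists; `window` accepts `lo-hi`. Keys absent from
#' the file keep [pipeline_config()] defaults; `overrides` (named list) wins
#' over file values.
#'
#' @param path config file path.
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- list()
  for (ln in lines) {
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  for (k in names(overrides)) kv[[k]] <- overrides[[k]]
  num_keys <- c("min_reads", "arm_window", "bin_high", "bin_moderate",
                "n_sets", "pairing_threshold", "max_tables", "n_mc",
                "flank_halfwidth", "seed")
  lgl_keys <- c("per_strand", "collapse_nt1")
  args <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    args[[k]] <- if (k %in% num_keys) as.numeric(v)
      else if (k %in% lgl_keys) as.logical(v)
      else if (k %in% c("tag_counts", "strata")) strsplit(as.character(v), ",\\s*")[[1]]
      else if (k == "window") {
        rng <- as.integer(strsplit(as.character(v), "-", fixed = TRUE)[[1]])
        rng[1]:rng[2]
      } else v
  }
  do.call(pipeline_config, args)
}

config_echo <- function(config) {
  lapply(config, function(v) {
    if (is.null(v)) NULL
    else if (length(v) > 1 && is.numeric(v)) paste0(min(v), "-", max(v))
    else v
  })
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs and pool libraries; profile isoforms and designate
#' strands; apply the expression filter; composition analysis per stratum
#' (arm split and asymmetry-bin split); duplex structure calls; the
#' 144-feature covariation scan; the flanking-U profile. Writes six report
#' files (`duplexes.tsv`, `composition.tsv`, `structure.tsv`,
#' `covariation.tsv`, `flanking.tsv`, `manifest.json`) plus `log.txt` under
#' `config$out_dir`. A hard error in any stage aborts with the stage name.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  note <- function(...) log_lines[[length(log_lines) + 1L]] <<- sprintf(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("annotation_io", {
    if (!file.exists(config$hairpin_fasta)) {
      stop(sprintf("hairpin FASTA not found: %s", config$hairpin_fasta))
    }
    records <- read_annotations(config$hairpin_fasta, config$mature_coords)
    libs <- lapply(config$tag_counts, read_tag_counts)
    list(records = records, library = pool_libraries(libs))
  })
  note("hairpins: %d; pooled tags: %d; pooled reads: %.0f",
       length(inputs$records), length(inputs$library$counts),
       sum(inputs$library$counts))

  quant <- stage("quantify", {
    profiles <- profile_isoforms(inputs$library, inputs$records,
                                 arm_window = config$arm_window)
    duplexes <- designate_strands(profiles, inputs$records)
    duplexes$bin <- bin_asymmetry(duplexes$ratio, config$bin_high,
                                  config$bin_moderate)
    filtered <- filter_expressed(duplexes, config$min_reads,
                                 per_strand = config$per_strand)
    list(profiles = profiles, duplexes = duplexes, filtered = filtered)
  })
  note("unmatched tags: %d (%.0f reads)", attr(quant$profiles, "unmatched_tags"),
       attr(quant$profiles, "unmatched_reads"))
  note("single-arm hairpins excluded: %d", length(attr(quant$duplexes, "excluded")))
  note("duplexes below %d reads dropped: %d; retained: %d",
       config$min_reads, attr(quant$filtered, "n_dropped"), nrow(quant$filtered))
  for (b in c("highly_asymmetric", "moderately_asymmetric", "quasisymmetric")) {
    note("bin %s: %d duplexes", b, sum(quant$filtered$bin == b))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  write_duplex_table(quant$filtered, out("duplexes.tsv"))

  strata <- default_strata()
  wanted <- c("all"[("all" %in% config$strata)],
              c("arm_5p", "arm_3p")[rep("by_arm" %in% config$strata, 2)],
              c("highly_asymmetric", "moderately_asymmetric",
                "quasisymmetric")[rep("by_bin" %in% config$strata, 3)])
  composition <- stage("composition", {
    suppressMessages(
      analyze_composition(quant$filtered, quant$profiles,
                          strata = strata[wanted], n_sets = config$n_sets,
                          window = config$window, seed = config$seed,
                          alternative = config$alternative))
  })
  utils::write.table(composition, out("composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  structure_res <- stage("duplex_structure", {
    mats <- lapply(seq_len(nrow(quant$filtered)), function(i) {
      pair_probabilities(quant$filtered$mirna_seq[i], quant$filtered$star_seq[i],
                         engine = config$engine,
                         external_file = config$external_file)
    })
    calls <- lapply(mats, pairing_status, threshold = config$pairing_threshold)
    rows <- lapply(seq_along(mats), function(i) {
      m <- mats[[i]]; s <- calls[[i]]
      rbind(
        data.frame(hairpin_id = quant$filtered$hairpin_id[i], strand = "miRNA",
                   position = seq_len(nchar(m$seq_a)),
                   nucleotide = seq_chars(m$seq_a),
                   p_paired = 1 - m$unpaired_a, paired_call = s$paired_a,
                   partner = s$partner_a, stringsAsFactors = FALSE),
        data.frame(hairpin_id = quant$filtered$hairpin_id[i], strand = "miRNA*",
                   position = seq_len(nchar(m$seq_b)),
                   nucleotide = seq_chars(m$seq_b),
                   p_paired = 1 - m$unpaired_b, paired_call = s$paired_b,
                   partner = s$partner_b, stringsAsFactors = FALSE))
    })
    list(matrices = mats, calls = calls, table = do.call(rbind, rows))
  })
  utils::write.table(structure_res$table, out("structure.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  covariation <- stage("covariation", {
    fvecs <- lapply(seq_len(nrow(quant$filtered)), function(i) {
      build_feature_vector(quant$filtered$mirna_seq[i],
                           quant$filtered$star_seq[i],
                           structure_res$calls[[i]],
                           duplex_id = quant$filtered$hairpin_id[i])
    })
    scan <- covariation_scan(fvecs, collapse_nt1 = config$collapse_nt1,
                             method = config$fisher_method,
                             max_tables = config$max_tables,
                             n_mc = config$n_mc, seed = config$seed)
    list(feature_vectors = fvecs, scan = scan)
  })
  write_covariation(covariation$scan, out("covariation.tsv"))

  flanking <- stage("flanking_profile", {
    flanking_u_profile(inputs$records, quant$filtered,
                       halfwidth = config$flank_halfwidth,
                       n_sets = config$n_sets, seed = config$seed + 1L)
  })
  write_flanking_profile(flanking, out("flanking.tsv"))

  manifest <- list(
    package = "mirasym",
    version = as.character(utils::packageVersion("mirasym")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config_echo(config),
    tallies = list(
      hairpins = length(inputs$records),
      pooled_tags = length(inputs$library$counts),
      pooled_reads = sum(inputs$library$counts),
      unmatched_tags = attr(quant$profiles, "unmatched_tags"),
      unmatched_reads = attr(quant$profiles, "unmatched_reads"),
      single_arm_excluded = length(attr(quant$duplexes, "excluded")),
      below_threshold_dropped = attr(quant$filtered, "n_dropped"),
      duplexes_retained = nrow(quant$filtered),
      bins = as.list(table(factor(quant$filtered$bin,
                                  levels = c("highly_asymmetric",
                                             "moderately_asymmetric",
                                             "quasisymmetric"))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, out("log.txt"))

  invisible(list(records = inputs$records, library = inputs$library,
                 profiles = quant$profiles, duplexes = quant$duplexes,
                 filtered = quant$filtered, composition = composition,
                 structure = structure_res, covariation = covariation,
                 flanking = flanking, manifest = manifest))
}
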