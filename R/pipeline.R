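#' Run the full SSR survey over one or more databases
#'
#' For every database: sequence statistics, class I SSR mining, the survey
#' summary row, canonical motif frequency tables for all motif lengths and
#' the amino-acid profile of translatable motifs. A cross-database
#' aggregate row holds the unweighted means of the comparable columns.
#'
#' @param databases named list; each element a FASTA path, a
#'   `DNAStringSet`, or a named character vector of sequences.
#' @param config a [mining_config()].
#' @param frame translation frame for the amino-acid profile.
#' @param out_dir optional directory; when given, `summary.tsv`,
#'   `loci.tsv`, `motif_frequencies.tsv` and `amino_acid_profiles.tsv` are
#'   written there (re-running with identical inputs reproduces them
#'   byte-identically).
#' @return (invisibly) list with `summary`, `aggregate`, `minings`,
#'   `motif_tables`, `aa_profiles`.
#' @export
run_survey <- function(databases, config = mining_config(), frame = 0L,
                       out_dir = NULL) {
  if (length(databases) == 0L || is.null(names(databases)) ||
      any(!nzchar(names(databases)))) {
    usage_error("run_survey needs a non-empty named list of databases")
  }
  minings <- list(); summaries <- list()
  motif_tabs <- list(); aa_profiles <- list(); loci_out <- list()
  for (db in names(databases)) {
    records <- load_database(databases[[db]], db)
    stats <- database_stats(records, database = db)
    mining <- mine_database(records, config, database = db)
    minings[[db]] <- mining
    smry <- summarize_mining(mining)
    summaries[[db]] <- cbind(stats[c("database", "n_sequences", "total_bp",
                                     "avg_bp_per_est", "gc_percent")],
                             smry[setdiff(names(smry),
                                          c("database", "n_sequences"))])
    motif_tabs[[db]] <- do.call(rbind, lapply(1:10, function(p) {
      tab <- motif_frequency_table(mining$loci, p)
      if (nrow(tab) == 0L) return(NULL)
      cbind(data.frame(database = db, motif_length = p), tab)
    }))
    aa <- amino_acid_profile(mining$loci, frame = frame)
    aa_profiles[[db]] <- if (nrow(aa)) {
      cbind(data.frame(database = db), aa)
    } else NULL
    loci_out[[db]] <- if (nrow(mining$loci)) {
      cbind(data.frame(database = db),
            mining$loci[setdiff(names(mining$loci), "gap_before")])
    } else NULL
    message(sprintf("[ssrmine] %s: %d sequences, %d class I loci (%d single, %d compound members)",
                    db, mining$n_sequences, nrow(mining$loci),
                    sum(mining$loci$locus_type == "single"),
                    sum(mining$loci$locus_type == "compound-member")))
  }
  summary <- `rownames<-`(do.call(rbind, summaries), NULL)
  aggregate <- data.frame(
    n_databases = nrow(summary),
    mean_gc_percent = cross_database_mean(summary$gc_percent),
    mean_avg_bp_per_est = cross_database_mean(summary$avg_bp_per_est),
    mean_ssr_per_est_pct = cross_database_mean(summary$ssr_per_est_pct),
    mean_avg_motif_length_bp =
      cross_database_mean(summary$avg_motif_length_bp[
        !is.na(summary$avg_motif_length_bp)])
  )
  motif_tables <- do.call(rbind, Filter(Negate(is.null), motif_tabs))
  aa_all <- do.call(rbind, Filter(Negate(is.null), aa_profiles))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_versioned(summary, file.path(out_dir, "summary.tsv"),
                        "survey_summary")
    if (!is.null(motif_tables)) {
      write_tsv_versioned(motif_tables,
                          file.path(out_dir, "motif_frequencies.tsv"),
                          "motif_frequencies")
    }
    if (!is.null(aa_all)) {
      write_tsv_versioned(aa_all,
                          file.path(out_dir, "amino_acid_profiles.tsv"),
                          "aa_profiles")
    }
    loci_all <- do.call(rbind, Filter(Negate(is.null), loci_out))
    if (!is.null(loci_all)) {
      write_tsv_versioned(loci_all, file.path(out_dir, "loci.tsv"), "loci")
    }
    write_tsv_versioned(aggregate, file.path(out_dir, "aggregate.tsv"),
                        "aggregate")
  }
  invisible(list(summary = summary, aggregate = aggregate,
                 minings = minings, motif_tables = motif_tables,
                 aa_profiles = aa_all))
}

#' Run the in-silico transferability assay
#'
#' Designs flanking primers from every class I locus of the source
#' database, scans all other databases (and optionally the source itself)
#' for virtual amplicons, flags on-target products, and reports the
#' transfer-rate matrix plus virtual gel lanes.
#'
#' @param databases named list of databases (see [run_survey()]).
#' @param source name of the source database within `databases`.
#' @param config a [mining_config()].
#' @param params an [epcr_params()].
#' @param include_self also scan the source database against itself.
#' @param out_dir optional output directory (`transfer_matrix.tsv`,
#'   `amplicons.tsv`, `primers.tsv`, `gel.txt`).
#' @return (invisibly) list with `primers`, `rates`, `pair_counts`,
#'   `amplicons`, `gel`.
#' @export
run_transfer <- function(databases, source, config = mining_config(),
                         params = epcr_params(), include_self = FALSE,
                         out_dir = NULL) {
  if (!source %in% names(databases)) {
    usage_error("source database '", source, "' not among databases")
  }
  recs <- lapply(names(databases), function(db)
    load_database(databases[[db]], db))
  names(recs) <- names(databases)
  minings <- lapply(names(recs), function(db)
    mine_database(recs[[db]], config, database = db))
  names(minings) <- names(recs)
  pairs <- design_primers(minings[[source]], recs[[source]], params)
  if (nrow(pairs) == 0L) {
    warning("source database '", source,
            "' yielded no usable primer pairs; empty matrix")
  }
  target_names <- if (include_self) {
    names(recs)
  } else {
    setdiff(names(recs), source)
  }
  if (length(target_names) == 0L) {
    warning("no target databases; empty matrix")
    return(invisible(list(primers = pairs, rates = NULL,
                          pair_counts = NULL, amplicons = NULL,
                          gel = virtual_gel(
                            data.frame(pair_id = character(),
                                       target_db = character(),
                                       product_length = integer())))))
  }
  res <- transferability_matrix(pairs, recs[target_names], params,
                                target_minings = minings[target_names])
  gel <- virtual_gel(res$amplicons)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_versioned(pairs, file.path(out_dir, "primers.tsv"), "primers")
    write_tsv_versioned(res$rates,
                        file.path(out_dir, "transfer_matrix.tsv"),
                        "transfer_matrix")
    write_tsv_versioned(res$amplicons, file.path(out_dir, "amplicons.tsv"),
                        "amplicons")
    writeLines(render_gel(gel), file.path(out_dir, "gel.txt"))
  }
  invisible(list(primers = pairs, rates = res$rates,
                 pair_counts = res$pair_counts,
                 amplicons = res$amplicons, gel = gel))
}

load_database <- function(x, label) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    return(read_fasta(x))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  parse_error("database '", label,
              "' is neither an existing FASTA path nor a sequence set")
}
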