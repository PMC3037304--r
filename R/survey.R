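#' SSR incidence per EST database, percent
#'
#' `100 * n_loci / n_sequences`, truncated (not rounded) to 2 decimals.
#' Truncation matches the reporting convention of published EST-SSR survey
#' tables, whose per-species SSR/EST percentages are cut at the second
#' decimal.
#'
#' @param n_loci number of class I loci found.
#' @param n_sequences number of sequences in the database.
#' @return percent, 2 decimals.
#' @examples
#' ssr_incidence_pct(980, 40525)
#' @export
ssr_incidence_pct <- function(n_loci, n_sequences) {
  if (any(n_sequences == 0)) stop("n_sequences must be positive")
  trunc_decimals(100 * n_loci / n_sequences, 2)
}

#' Per-database survey summary
#'
#' The comparative row reported for each database: locus counts, SSR/EST
#' incidence, mean tract length of single loci (compound members excluded),
#' and how many sequences carry one or more loci. The percentage of
#' multi-SSR sequences is reported relative to the sequences that carry at
#' least one SSR (this package's own convention; published tables leave the
#' denominator of that column undocumented).
#'
#' @param mining an `ssr_mining` object from [mine_database()].
#' @param n_sequences database size; defaults to the size recorded at
#'   mining time.
#' @return one-row `data.frame` of summary statistics.
#' @export
summarize_mining <- function(mining, n_sequences = mining$n_sequences) {
  stopifnot(inherits(mining, "ssr_mining"))
  if (n_sequences == 0) stop("n_sequences must be positive")
  loci <- mining$loci
  n_loci <- nrow(loci)
  singles <- loci[loci$locus_type == "single", , drop = FALSE]
  per_seq <- table(loci$seq_id)
  n_with <- length(per_seq)
  n_multi <- sum(per_seq >= 2L)
  data.frame(
    database = mining$database,
    n_sequences = n_sequences,
    n_loci = n_loci,
    ssr_per_est_pct = ssr_incidence_pct(n_loci, n_sequences),
    avg_motif_length_bp = if (nrow(singles)) {
      round_half_up(mean(singles$tract_length), 2)
    } else NA_real_,
    n_seq_with_ssr = n_with,
    seq_with_ssr_pct = round_half_up(100 * n_with / n_sequences, 2),
    n_seq_multi_ssr = n_multi,
    multi_ssr_pct_of_ssr_seq = if (n_with) {
      round_half_up(100 * n_multi / n_with, 2)
    } else 0,
    n_single = sum(loci$locus_type == "single"),
    n_compound_loci = sum(loci$locus_type == "compound-member"),
    stringsAsFactors = FALSE
  )
}

#' Canonical motif-pair frequency table for one motif length
#'
#' Counts loci of the given motif length by canonical pair. `percent` is
#' the within-length-class share to 2 decimals; `percent_int` is the
#' integer-rounded convenience share used in prose (e.g. 246 of 578 dimer
#' occurrences is 43%). `motif` is the most frequent observed motif of the
#' class (ties alphabetical), used downstream for codon comparisons.
#'
#' @param loci loci `data.frame` (typically `mining$loci`).
#' @param motif_length motif length class, 1-10.
#' @return `data.frame` with `canonical_pair`, `motif`, `count`, `percent`,
#'   `percent_int`, sorted by count (desc) then label; the class total is
#'   in `attr(x, "total")`.
#' @export
motif_frequency_table <- function(loci, motif_length) {
  stopifnot(motif_length %in% 1:10)
  sub <- loci[loci$motif_length == motif_length, , drop = FALSE]
  if (nrow(sub) == 0L) {
    out <- data.frame(canonical_pair = character(), motif = character(),
                      count = integer(), percent = numeric(),
                      percent_int = integer(), stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  counts <- table(sub$canonical_pair)
  total <- sum(counts)
  rep_motif <- vapply(names(counts), function(cp) {
    obs <- sort(table(sub$motif[sub$canonical_pair == cp]),
                decreasing = TRUE)
    # tie -> alphabetically first among the most frequent observed motifs
    top <- names(obs)[obs == max(obs)]
    sort(top)[1L]
  }, character(1))
  out <- data.frame(
    canonical_pair = names(counts),
    motif = unname(rep_motif),
    count = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / total, 2),
    percent_int = as.integer(round_half_up(100 * as.integer(counts) / total,
                                           0)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$canonical_pair), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- as.integer(total)
  out
}

#' Distribution of loci over motif lengths
#'
#' @param loci loci `data.frame`.
#' @return `data.frame` with `motif_length`, `count`, `percent` (percents
#'   sum to 100 up to rounding); zero rows on empty input.
#' @export
length_class_spectrum <- function(loci) {
  if (nrow(loci) == 0L) {
    return(data.frame(motif_length = integer(), count = integer(),
                      percent = numeric()))
  }
  counts <- table(factor(loci$motif_length, levels = 1:10))
  keep <- counts > 0
  data.frame(
    motif_length = as.integer(names(counts))[keep],
    count = as.integer(counts)[keep],
    percent = round_half_up(100 * as.integer(counts)[keep] / sum(counts), 2)
  )
}

#' Unweighted mean across databases
#'
#' @param values per-database numbers (e.g. GC percentages).
#' @return arithmetic mean, 2 decimals.
#' @examples
#' cross_database_mean(c(1, 2, 3))
#' @export
cross_database_mean <- function(values) {
  if (length(values) == 0L) stop("empty value list")
  round_half_up(mean(values), 2)
}

#' Most frequent canonical pairs per database and shared pairs
#'
#' @param tables named list of [motif_frequency_table()] outputs, one per
#'   database.
#' @param top_k how many top pairs to report per database.
#' @return list with `per_database` (`data.frame`: `database`, `rank`,
#'   `canonical_pair`, `count`; count desc, ties alphabetical) and
#'   `shared`, the canonical pairs present in every database.
#' @export
rank_motifs <- function(tables, top_k = 5L) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  per_db <- do.call(rbind, lapply(names(tables), function(db) {
    tab <- tables[[db]]
    if (nrow(tab) == 0L) return(NULL)
    tab <- tab[order(-tab$count, tab$canonical_pair), , drop = FALSE]
    k <- min(top_k, nrow(tab))
    data.frame(database = db, rank = seq_len(k),
               canonical_pair = tab$canonical_pair[seq_len(k)],
               count = tab$count[seq_len(k)], stringsAsFactors = FALSE)
  }))
  if (is.null(per_db)) {
    per_db <- data.frame(database = character(), rank = integer(),
                         canonical_pair = character(), count = integer())
  }
  shared <- Reduce(intersect,
                   lapply(tables, function(t) t$canonical_pair[t$count > 0]))
  list(per_database = per_db, shared = sort(shared))
}
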