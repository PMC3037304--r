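#' Mining configuration for perfect SSR detection
#'
#' Bundles the search parameters of the SSR survey. Class I loci are
#' perfect tandem repeats whose tract (whole motif copies only) spans at
#' least `min_tract_bp` bases; with the 20 bp default the implied minimum
#' repeat counts are mono >= 20, di >= 10, tri >= 7, tetra >= 5,
#' penta >= 4, hexa >= 4, 7-9-mers >= 3 and 10-mers >= 2.
#'
#' @param min_motif,max_motif primitive motif lengths searched (bases).
#' @param min_tract_bp class I tract-length threshold (bases).
#' @param compound_max_interruption maximum gap (bases) between consecutive
#'   class I loci merged into one compound SSR.
#' @param include_mononucleotide search mononucleotide runs too; they are
#'   always flagged `homopolymer` downstream because EST poly-A tails make
#'   them suspect markers.
#' @return a `mining_config` list.
#' @export
mining_config <- function(min_motif = 1L, max_motif = 10L,
                          min_tract_bp = 20L,
                          compound_max_interruption = 100L,
                          include_mononucleotide = TRUE) {
  min_motif <- as.integer(min_motif)
  max_motif <- as.integer(max_motif)
  min_tract_bp <- as.integer(min_tract_bp)
  compound_max_interruption <- as.integer(compound_max_interruption)
  if (min_motif < 1L || max_motif > 10L || min_motif > max_motif) {
    stop("need 1 <= min_motif <= max_motif <= 10")
  }
  if (min_tract_bp < 2L * min_motif) {
    stop("min_tract_bp must be at least 2 * min_motif")
  }
  if (compound_max_interruption < 0L) {
    stop("compound_max_interruption must be >= 0")
  }
  structure(list(min_motif = min_motif, max_motif = max_motif,
                 min_tract_bp = min_tract_bp,
                 compound_max_interruption = compound_max_interruption,
                 include_mononucleotide = isTRUE(include_mononucleotide)),
            class = "mining_config")
}

empty_loci <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             motif = character(), motif_length = integer(),
             repeat_count = integer(), tract_length = integer(),
             canonical_pair = character(), homopolymer = logical(),
             stringsAsFactors = FALSE)
}

loci_frame <- function(seq_id, start, end, motif) {
  p <- nchar(motif)
  tract <- end - start + 1L
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), motif = motif,
             motif_length = as.integer(p),
             repeat_count = as.integer(tract %/% p),
             tract_length = as.integer(tract),
             canonical_pair = canonical_pair(motif),
             homopolymer = p == 1L,
             stringsAsFactors = FALSE)
}

#' Canonical reverse-complement motif pair label
#'
#' Each motif is grouped with its reverse complement for strand-independent
#' reporting: `AG` and `CT` both label as `"AG/CT"`. Cyclic rotations are
#' kept distinct (`GA` labels as `"GA/TC"`, a different class), and
#' self-reverse-complementary motifs label as `"X/X"` (`GC` gives
#' `"GC/GC"`). The alphabetically smaller member of the pair is printed
#' first so the label is identical for both strands.
#'
#' @param motif character vector of motifs over `A`, `C`, `G`, `T`
#'   (lengths 1-10).
#' @return character vector of `"X/Y"` labels.
#' @examples
#' canonical_pair(c("AG", "CT", "GA", "GC"))
#' @export
canonical_pair <- function(motif) {
  if (length(motif) == 0L) return(character())
  if (any(!grepl("^[ACGT]+$", motif)) || any(nchar(motif) > 10L)) {
    stop("motifs must be 1-10 bases over A/C/G/T")
  }
  rc <- revcomp_chr(motif)
  paste(pmin(motif, rc), pmax(motif, rc), sep = "/")
}

#' Find all maximal perfect tandem repeats in one record
#'
#' Returns every maximal perfect tandem repeat with a primitive motif of
#' length `min_motif`..`max_motif` and at least 2 complete copies, before
#' any class filtering. Maximal means the tract cannot be extended by a
#' full motif copy on either side; only whole copies count towards the
#' tract (trailing partial copies are dropped). Ambiguity characters
#' terminate tracts. Loci are sorted by `(start, motif_length)`.
#'
#' @param record a single sequence: character scalar, or a length-1 named
#'   `DNAStringSet` / named character vector.
#' @param config a [mining_config()].
#' @param seq_id record id; defaults to the record's name.
#' @return a loci `data.frame` (columns `seq_id`, `start`, `end`, `motif`,
#'   `motif_length`, `repeat_count`, `tract_length`, `canonical_pair`,
#'   `homopolymer`); coordinates are 1-based inclusive.
#' @export
find_perfect_repeats <- function(record, config = mining_config(),
                                 seq_id = NULL) {
  stopifnot(inherits(config, "mining_config"))
  if (methods::is(record, "DNAStringSet")) {
    stopifnot(length(record) == 1L)
    if (is.null(seq_id)) seq_id <- names(record)
    record <- as.character(record)
  }
  stopifnot(is.character(record), length(record) == 1L)
  if (is.null(seq_id)) seq_id <- names(record)
  if (is.null(seq_id)) seq_id <- "seq"
  seq <- toupper(unname(record))
  n <- nchar(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- x %in% DNA_BASES

  starts <- integer(); ends <- integer(); motifs <- character()
  for (p in config$min_motif:config$max_motif) {
    if (p == 1L && !config$include_mononucleotide) next
    if (n < 2L * p) break
    m <- x[seq_len(n - p)] == x[(p + 1L):n] & ok[seq_len(n - p)]
    r <- rle(m)
    rend <- cumsum(r$lengths)
    rstart <- rend - r$lengths + 1L
    for (j in which(r$values & r$lengths >= p)) {
      i <- rstart[j]
      k <- (r$lengths[j] + p) %/% p
      motif <- substr(seq, i, i + p - 1L)
      if (!is_primitive_motif(motif)) next
      starts <- c(starts, i)
      ends <- c(ends, i + k * p - 1L)
      motifs <- c(motifs, motif)
    }
  }
  if (length(starts) == 0L) return(empty_loci())
  out <- loci_frame(seq_id, starts, ends, motifs)
  out[order(out$start, out$motif_length), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Keep class I loci only
#'
#' @param loci loci `data.frame` from [find_perfect_repeats()].
#' @param config a [mining_config()]; loci with
#'   `tract_length >= min_tract_bp` are kept, order preserved.
#' @return filtered loci `data.frame`.
#' @export
filter_class_I <- function(loci, config = mining_config()) {
  loci[loci$tract_length >= config$min_tract_bp, , drop = FALSE] |>
    `rownames<-`(NULL)
}

rotate_motif <- function(motif, d) {
  p <- nchar(motif)
  d <- d %% p
  if (d == 0L) return(motif)
  paste0(substr(motif, d + 1L, p), substr(motif, 1L, d))
}

#' Eliminate overlapping repeat calls on one record
#'
#' Greedy selection: longer tract first, ties broken by leftmost start,
#' then smaller motif length. A candidate overlapping an already selected
#' locus is truncated to its largest remaining non-overlapping interval,
#' trimmed to whole motif copies (the motif is rotated to stay in phase
#' with the retained substring), and re-enters the pool only while it still
#' satisfies the class I threshold; otherwise it is dropped. Identical
#' duplicates collapse to one locus.
#'
#' @param loci class-filtered loci of one record.
#' @param config a [mining_config()] (supplies `min_tract_bp`).
#' @return pairwise non-overlapping loci, sorted by `(start, motif_length)`.
#' @export
resolve_overlaps <- function(loci, config = mining_config()) {
  if (nrow(loci) <= 1L) return(`rownames<-`(loci, NULL))
  if (length(unique(loci$seq_id)) > 1L) {
    parts <- lapply(split(loci, loci$seq_id), resolve_overlaps, config)
    out <- do.call(rbind, parts)
    return(`rownames<-`(out[order(out$seq_id, out$start, out$motif_length), ,
                            drop = FALSE], NULL))
  }
  pool <- loci
  sel <- empty_loci()
  while (nrow(pool) > 0L) {
    o <- order(-pool$tract_length, pool$start, pool$motif_length)
    pool <- pool[o, , drop = FALSE]
    cand <- pool[1L, , drop = FALSE]
    pool <- pool[-1L, , drop = FALSE]
    ovl <- nrow(sel) > 0L &&
      any(cand$start <= sel$end & cand$end >= sel$start)
    if (!ovl) {
      dup <- nrow(sel) > 0L &&
        any(sel$start == cand$start & sel$end == cand$end &
              sel$motif == cand$motif)
      if (!dup) sel <- rbind(sel, cand)
      next
    }
    # free sub-intervals of the candidate tract outside selected loci
    free <- free_intervals(cand$start, cand$end, sel)
    if (nrow(free) == 0L) next
    lens <- free$end - free$start + 1L
    best <- which(lens == max(lens))[1L]
    a <- free$start[best]; b <- free$end[best]
    p <- cand$motif_length
    k <- (b - a + 1L) %/% p
    if (k < 2L || k * p < config$min_tract_bp) next
    new_motif <- rotate_motif(cand$motif, (a - cand$start) %% p)
    pool <- rbind(pool, loci_frame(cand$seq_id, a, a + k * p - 1L, new_motif))
  }
  sel <- sel[order(sel$start, sel$motif_length), , drop = FALSE]
  `rownames<-`(sel, NULL)
}

# sub-intervals of [s, e] not covered by any selected interval
free_intervals <- function(s, e, sel) {
  cov <- sel[sel$start <= e & sel$end >= s, c("start", "end"), drop = FALSE]
  cov <- cov[order(cov$start), , drop = FALSE]
  out <- data.frame(start = integer(), end = integer())
  cur <- s
  for (i in seq_len(nrow(cov))) {
    if (cov$start[i] > cur) {
      out <- rbind(out, data.frame(start = cur, end = cov$start[i] - 1L))
    }
    cur <- max(cur, cov$end[i] + 1L)
  }
  if (cur <= e) out <- rbind(out, data.frame(start = cur, end = e))
  out
}

#' Partition non-overlapping loci into single and compound SSRs
#'
#' Consecutive class I loci on the same record whose gap does not exceed
#' `compound_max_interruption` are merged transitively into one compound
#' SSR; every other locus is a single. Every input locus appears in
#' exactly one of the two outputs.
#'
#' @param loci non-overlapping class I loci (one or more records).
#' @param config a [mining_config()].
#' @return list with `singles` (loci `data.frame`) and `compounds` (loci
#'   `data.frame` with extra columns `compound_id` and `gap_before`, the
#'   interruption in bases before each member, `NA` for the first).
#' @export
assemble_compounds <- function(loci, config = mining_config()) {
  if (nrow(loci) == 0L) {
    cmp <- cbind(empty_loci(),
                 data.frame(compound_id = character(),
                            gap_before = integer()))
    return(list(singles = empty_loci(), compounds = cmp))
  }
  loci <- loci[order(loci$seq_id, loci$start), , drop = FALSE]
  singles <- list(); compounds <- list()
  for (sid in unique(loci$seq_id)) {
    sub <- loci[loci$seq_id == sid, , drop = FALSE]
    gap <- c(Inf, sub$start[-1L] - sub$end[-nrow(sub)] - 1L)
    grp <- cumsum(gap > config$compound_max_interruption)
    for (g in unique(grp)) {
      block <- sub[grp == g, , drop = FALSE]
      if (nrow(block) == 1L) {
        singles[[length(singles) + 1L]] <- block
      } else {
        block$compound_id <- sprintf("%s_c%d", sid, g)
        block$gap_before <-
          c(NA_integer_, block$start[-1L] - block$end[-nrow(block)] - 1L)
        compounds[[length(compounds) + 1L]] <- block
      }
    }
  }
  singles <- if (length(singles)) do.call(rbind, singles) else empty_loci()
  compounds <- if (length(compounds)) {
    do.call(rbind, compounds)
  } else {
    cbind(empty_loci(), data.frame(compound_id = character(),
                                   gap_before = integer()))
  }
  list(singles = `rownames<-`(singles, NULL),
       compounds = `rownames<-`(compounds, NULL))
}

#' Mine a whole database for class I SSR loci
#'
#' Per-record composition of [find_perfect_repeats()], [filter_class_I()],
#' [resolve_overlaps()] and [assemble_compounds()]. Deterministic for a
#' fixed input and configuration.
#'
#' @param records named `DNAStringSet` or named character vector.
#' @param config a [mining_config()].
#' @param database database label carried into reports.
#' @return an `ssr_mining` list: `database`, `n_sequences`, `loci` (all
#'   class I loci with `locus_type` `"single"`/`"compound-member"` and
#'   `compound_id`), `compounds` (compound members with `gap_before`) and
#'   `config`.
#' @export
mine_database <- function(records, config = mining_config(),
                          database = "db") {
  chars <- as_record_chars(records)
  per_rec <- lapply(names(chars), function(sid) {
    found <- find_perfect_repeats(chars[[sid]], config, seq_id = sid)
    resolve_overlaps(filter_class_I(found, config), config)
  })
  all_loci <- do.call(rbind, c(list(empty_loci()), per_rec))
  parts <- assemble_compounds(all_loci, config)
  singles <- parts$singles
  if (nrow(singles)) {
    singles$locus_type <- "single"
    singles$compound_id <- NA_character_
    singles$gap_before <- NA_integer_
  } else {
    singles <- cbind(singles,
                     data.frame(locus_type = character(),
                                compound_id = character(),
                                gap_before = integer()))
  }
  members <- parts$compounds
  if (nrow(members)) {
    members$locus_type <- "compound-member"
  } else {
    members$locus_type <- character()
  }
  cols <- c(names(empty_loci()), "locus_type", "compound_id", "gap_before")
  loci <- rbind(singles[, cols, drop = FALSE], members[, cols, drop = FALSE])
  loci <- loci[order(loci$seq_id, loci$start, loci$motif_length), ,
               drop = FALSE]
  structure(list(database = database,
                 n_sequences = length(chars),
                 loci = `rownames<-`(loci, NULL),
                 compounds = parts$compounds,
                 config = config),
            class = "ssr_mining")
}

#' @export
print.ssr_mining <- function(x, ...) {
  cat("SSR mining of database '", x$database, "': ",
      nrow(x$loci), " class I loci on ", x$n_sequences, " sequences (",
      sum(x$loci$locus_type == "single"), " single, ",
      sum(x$loci$locus_type == "compound-member"),
      " in compound formation)\n", sep = "")
  invisible(x)
}

#' Write mined loci as TSV
#'
#' @param mining an `ssr_mining` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(mining, path) {
  loci <- mining$loci
  out <- data.frame(database = mining$database, loci[setdiff(
    names(loci), "gap_before")], homopolymer_flag = loci$homopolymer)
  out$homopolymer <- NULL
  write_tsv_versioned(out, path, "loci")
}
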