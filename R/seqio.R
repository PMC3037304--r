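#' Read an EST/cDNA database from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file into a
#' [Biostrings::DNAStringSet]. Residues are uppercased on read, record ids
#' are the first whitespace-delimited token of each header and must be
#' unique, and the remainder of the header is kept as a per-record
#' `description` in the element metadata. Records with an empty sequence
#' and sequence lines containing non-IUPAC characters are rejected with an
#' error naming the offending line.
#'
#' @param path path to a FASTA file. CRLF line endings are tolerated;
#'   `>` may appear only at the start of a header line.
#' @return a named `DNAStringSet`; `S4Vectors::mcols(x)$description` holds
#'   the free-text part of each header.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first record", "ACGTacgt", ">b", "GG"), fa)
#' ests <- read_fasta(fa)
#' width(ests)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) parse_error("FASTA file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) parse_error("empty FASTA file: ", path)
  if (!startsWith(lines[nonblank[1L]], ">")) {
    parse_error("not FASTA: line ", nonblank[1L],
                " should be a '>' header in ", path)
  }
  is_hdr <- startsWith(lines, ">")
  hdr_idx <- which(is_hdr)
  headers <- sub("^>\\s*", "", lines[hdr_idx])
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    parse_error("malformed FASTA header (empty id) at line ",
                hdr_idx[which(!nzchar(ids))[1L]])
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    parse_error("duplicate record id '", dup, "' at line ",
                hdr_idx[which(ids == dup)[2L]])
  }
  seq_lines <- !is_hdr & nzchar(trimws(lines))
  bad <- which(seq_lines &
                 !grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$", lines))
  if (length(bad)) {
    parse_error("non-IUPAC character in sequence at line ", bad[1L])
  }
  # residues between consecutive headers
  grp <- cumsum(is_hdr)
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    paste(lines[!is_hdr & grp == i], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    parse_error("record '", ids[empty[1L]], "' (line ",
                hdr_idx[empty[1L]], ") has an empty sequence")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  desc <- trimws(sub("^\\S+", "", headers))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write records to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` reproduces
#' `x` (ids, descriptions, residues).
#'
#' @param records named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  chars <- as_record_chars(records)
  desc <- NULL
  if (methods::is(records, "DNAStringSet") &&
      !is.null(S4Vectors::mcols(records)$description)) {
    desc <- S4Vectors::mcols(records)$description
  }
  headers <- names(chars)
  if (!is.null(desc)) {
    has <- nzchar(desc)
    headers[has] <- paste(headers[has], desc[has])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(chars)) {
    writeLines(paste0(">", headers[i]), con)
    s <- chars[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Pooled GC content of a sequence database
#'
#' GC percent pooled over all residues of all records:
#' `100 * (G + C) / (A + C + G + T)`. `N` and other IUPAC ambiguity codes
#' are excluded from both numerator and denominator, so GC stays
#' well-defined on masked ESTs.
#'
#' @param records `DNAStringSet` or character vector of sequences.
#' @return percent, rounded half away from zero to 2 decimals.
#' @examples
#' gc_content(c("ATGC", "GGCC"))
#' @export
gc_content <- function(records) {
  chars <- as_record_chars(records, require_names = FALSE)
  set <- Biostrings::DNAStringSet(chars)
  counts <- colSums(Biostrings::letterFrequency(set, letters = DNA_BASES))
  total <- sum(counts)
  if (total == 0) {
    stop("GC content undefined: records contain no unambiguous bases")
  }
  round_half_up(100 * (counts[["G"]] + counts[["C"]]) / total, 2)
}

#' Average EST length, reported as an integer
#'
#' Mean bases per sequence, rounded half away from zero so that the value
#' matches integer bp-per-EST columns of published survey tables.
#'
#' @param total_bp total bases in the database.
#' @param n_sequences number of sequences.
#' @return integer average length in bp.
#' @examples
#' avg_bp_per_est(18318250, 19830)
#' @export
avg_bp_per_est <- function(total_bp, n_sequences) {
  stopifnot(n_sequences > 0)
  as.integer(round_half_up(total_bp / n_sequences, 0))
}

#' Database-level sequence statistics
#'
#' @param records `DNAStringSet` or named character vector; must be
#'   non-empty.
#' @param database optional database label for the output row.
#' @return one-row `data.frame` with `n_sequences`, `total_bp`,
#'   `avg_bp_per_est` and `gc_percent`.
#' @export
database_stats <- function(records, database = NA_character_) {
  chars <- as_record_chars(records)
  if (length(chars) == 0L) stop("empty database")
  total <- sum(nchar(chars))
  data.frame(
    database = database,
    n_sequences = length(chars),
    total_bp = total,
    avg_bp_per_est = avg_bp_per_est(total, length(chars)),
    gc_percent = gc_content(chars),
    stringsAsFactors = FALSE
  )
}

#' Write database statistics as TSV
#'
#' @param stats data.frame from [database_stats()] (rows may be bound
#'   across databases).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  write_tsv_versioned(stats, path, "database_stats")
}

# all TSV reports share one dialect: a versioned '#' comment line with the
# fixed column order, then tab-separated values
write_tsv_versioned <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ssrmine ", what, " v1: ",
                    paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
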