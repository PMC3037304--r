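# internal numeric / string helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_DNA <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

# Round half away from zero (reported tables use commercial rounding,
# not the banker's rounding of base round()).  The epsilon absorbs
# binary representation error in ratios of integers.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Truncate towards zero at `digits` decimals.
trunc_decimals <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 1e-9) / m
}

revcomp_chr <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# TRUE when `motif` is not a repetition of a shorter unit
is_primitive_motif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L &&
        strrep(substr(motif, 1L, q), p %/% q) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# Normalize any supported record container to a named uppercase
# character vector; ids must be unique and non-empty.
as_record_chars <- function(records, require_names = TRUE) {
  if (methods::is(records, "DNAStringSet")) {
    out <- as.character(records)
  } else if (is.character(records)) {
    out <- records
  } else {
    stop("records must be a DNAStringSet or a character vector of sequences")
  }
  out <- toupper(out)
  if (require_names) {
    ids <- names(out)
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
      stop("every record needs a non-empty id (the names attribute)")
    }
    if (anyDuplicated(ids)) {
      stop("duplicate record ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  out
}

parse_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ssrmine_parse_error", "error", "condition")))
}

usage_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ssrmine_usage_error", "error", "condition")))
}
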