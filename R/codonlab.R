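#' Translate a trimer, hexamer or nonamer SSR motif
#'
#' Translates the repeat unit itself under the standard genetic code,
#' yielding the 1, 2 or 3 residues a perfect repeat of that motif would
#' encode in frame. `frame` rotates the repeat unit left before
#' translation (frame 1 of `GCA` is `CAG`), covering the three possible
#' phases of the repeat within a reading frame. Stop codons are rendered
#' `*`.
#'
#' @param motif motif of length divisible by 3, unambiguous DNA.
#' @param frame 0, 1 or 2.
#' @return amino acid string (single-letter code).
#' @examples
#' translate_motif("GCA")       # "A"
#' translate_motif("AGCAGG")    # "SR"
#' @export
translate_motif <- function(motif, frame = 0L) {
  stopifnot(length(motif) == 1L, frame %in% 0:2)
  motif <- toupper(motif)
  L <- nchar(motif)
  if (L == 0L || L %% 3L != 0L) {
    stop("motif length must be a positive multiple of 3")
  }
  if (!grepl("^[ACGT]+$", motif)) {
    stop("motif contains ambiguity characters; cannot translate")
  }
  rot <- rotate_motif(motif, frame)
  codons <- substring(rot, seq(1L, L, 3L), seq(3L, L, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Amino acid profile of SSR loci
#'
#' Aggregates the residues encoded by trimer, hexamer and nonamer motifs
#' (other motif lengths are skipped and counted as untranslatable). Each
#' residue of a multi-residue translation counts once; counts are
#' normalized to percent of all residue occurrences.
#'
#' @param loci loci `data.frame` (typically `mining$loci`).
#' @param frame translation frame passed to [translate_motif()].
#' @return `data.frame` with `amino_acid` (single-letter, stop = `*`),
#'   `count`, `percent`, sorted by count desc; attributes
#'   `n_translatable_loci` and `n_untranslatable_loci`.
#' @export
amino_acid_profile <- function(loci, frame = 0L) {
  translatable <- loci$motif_length %in% c(3L, 6L, 9L) &
    grepl("^[ACGT]+$", loci$motif)
  sub <- loci[translatable, , drop = FALSE]
  if (nrow(sub) == 0L) {
    out <- data.frame(amino_acid = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_translatable_loci") <- 0L
    attr(out, "n_untranslatable_loci") <- sum(!translatable)
    return(out)
  }
  residues <- unlist(strsplit(
    vapply(sub$motif, translate_motif, character(1), frame = frame),
    "", fixed = TRUE))
  counts <- sort(table(residues), decreasing = TRUE)
  out <- data.frame(
    amino_acid = names(counts),
    count = as.integer(counts),
    percent = round_half_up(100 * as.integer(counts) / sum(counts), 2),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_translatable_loci") <- nrow(sub)
  attr(out, "n_untranslatable_loci") <- sum(!translatable)
  out
}

all_codons <- function() {
  b <- DNA_BASES
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

#' Construct a codon-usage table
#'
#' @param fractions numeric vector named by the 64 DNA codons; values are
#'   normalized to sum to 1.
#' @param species species label.
#' @return a `codon_usage` list with `species` and `fractions`.
#' @export
codon_usage_table <- function(fractions, species = "unknown") {
  codons <- toupper(chartr("U", "T", names(fractions)))
  if (length(fractions) != 64L || anyDuplicated(codons) ||
      !all(sort(codons) == sort(all_codons()))) {
    stop("need exactly the 64 DNA codons, each once")
  }
  if (any(fractions < 0) || sum(fractions) <= 0) {
    stop("codon usage values must be non-negative and not all zero")
  }
  f <- as.numeric(fractions) / sum(fractions)
  names(f) <- codons
  f <- f[all_codons()]
  structure(list(species = species, fractions = f), class = "codon_usage")
}

#' Uniform codon-usage table (each codon 1/64)
#'
#' @param species species label.
#' @return a `codon_usage` object.
#' @export
uniform_codon_usage <- function(species = "uniform") {
  codon_usage_table(stats::setNames(rep(1, 64L), all_codons()), species)
}

#' Read a Kazusa-style codon-usage table
#'
#' Accepts the usual codon-usage text layout of
#' `CODON frequency-per-thousand (count)` fields (RNA or DNA alphabet),
#' or a plain two-column `codon<TAB>value` file. Values are normalized to
#' per-codon usage fractions; when occurrence counts are present they take
#' precedence over the per-thousand frequencies.
#'
#' @param path path to the table, or a character vector of its lines.
#' @param species species label.
#' @return a `codon_usage` object.
#' @export
read_codon_usage <- function(path, species = "unknown") {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    path
  }
  txt <- paste(lines, collapse = "\n")
  m <- gregexpr("([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)(\\s*\\(\\s*([0-9]+)\\s*\\))?",
                txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1]]
  if (length(hits) < 64L) stop("could not parse 64 codons from input")
  codon <- toupper(chartr("Uu", "Tt", substr(hits, 1L, 3L)))
  rest <- trimws(substr(hits, 4L, nchar(hits)))
  freq <- as.numeric(sub("\\s*\\(.*$", "", rest))
  count <- suppressWarnings(as.numeric(sub("^.*\\(\\s*([0-9]+)\\s*\\).*$",
                                           "\\1", rest)))
  value <- if (!anyNA(count)) count else freq
  codon_usage_table(stats::setNames(value, codon), species)
}

#' GC frequency at each codon position
#'
#' `GCk` is 100 times the total usage fraction of codons whose k-th base is
#' G or C.
#'
#' @param table a `codon_usage` object.
#' @return named numeric `c(GC1, GC2, GC3)`, percents to 2 decimals.
#' @examples
#' gc_by_codon_position(uniform_codon_usage())
#' @export
gc_by_codon_position <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  f <- table$fractions
  codons <- names(f)
  out <- vapply(1:3, function(k) {
    gc <- substr(codons, k, k) %in% c("G", "C")
    round_half_up(100 * sum(f[gc]), 2)
  }, numeric(1))
  stats::setNames(out, c("GC1", "GC2", "GC3"))
}

#' Concordance of frequent trimer motifs with codon usage
#'
#' For each of the top-k trimer classes, reads the representative observed
#' motif as a codon, looks up its usage fraction, and ranks it among the
#' synonymous codons of the same amino acid (usage desc, ties
#' alphabetical). A motif is flagged concordant when it is the most used
#' synonymous codon with non-zero usage.
#'
#' @param trimer_table a [motif_frequency_table()] for `motif_length = 3`.
#' @param usage a `codon_usage` object.
#' @param top_k how many top trimer classes to assess.
#' @return `data.frame` with `canonical_pair`, `motif`, `count`,
#'   `amino_acid`, `usage_fraction`, `synonymous_rank`, `concordant`.
#' @export
motif_codon_concordance <- function(trimer_table, usage, top_k = 3L) {
  stopifnot(inherits(usage, "codon_usage"))
  if (nrow(trimer_table) == 0L) {
    return(data.frame(canonical_pair = character(), motif = character(),
                      count = integer(), amino_acid = character(),
                      usage_fraction = numeric(),
                      synonymous_rank = integer(), concordant = logical()))
  }
  if (any(nchar(trimer_table$motif) != 3L)) {
    stop("trimer_table must contain trimer motifs only")
  }
  top <- trimer_table[seq_len(min(top_k, nrow(trimer_table))), ,
                      drop = FALSE]
  f <- usage$fractions
  code <- Biostrings::GENETIC_CODE
  rows <- lapply(seq_len(nrow(top)), function(i) {
    codon <- top$motif[i]
    aa <- unname(code[codon])
    syn <- names(code)[code == aa]
    syn <- syn[order(-f[syn], syn)]
    rank <- match(codon, syn)
    data.frame(canonical_pair = top$canonical_pair[i], motif = codon,
               count = top$count[i], amino_acid = aa,
               usage_fraction = unname(f[codon]),
               synonymous_rank = rank,
               concordant = rank == 1L && f[codon] > 0,
               stringsAsFactors = FALSE)
  })
  `rownames<-`(do.call(rbind, rows), NULL)
}
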