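# Independent oracles, kept deliberately naive and separate from the
# package's implementations.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# deterministic filler: same n and seed always give the same bases
random_dna_fixed <- function(n, seed = n + 1000L) {
  set.seed(seed)
  random_dna(n)
}

oracle_is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L && strrep(substr(motif, 1L, q), p %/% q) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

# Quadratic brute-force scan over all (start, period) candidates: a locus
# starts at i with period p when the first two copies match base-by-base,
# the start is left-maximal (extending one base left breaks periodicity),
# and the motif is primitive. The tract is then grown base by base and cut
# to whole copies.
oracle_perfect_repeats <- function(seq, min_motif = 1L, max_motif = 10L) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(x)
  acgt <- x %in% c("A", "C", "G", "T")
  rows <- list()
  for (p in min_motif:max_motif) {
    if (n < 2L * p) next
    for (i in seq_len(n - 2L * p + 1L)) {
      span <- i:(i + 2L * p - 1L)
      if (!all(acgt[span])) next
      if (!all(x[i:(i + p - 1L)] == x[(i + p):(i + 2L * p - 1L)])) next
      left_ok <- i == 1L ||
        !(acgt[i - 1L] && x[i - 1L] == x[i - 1L + p])
      if (!left_ok) next
      j <- i + 2L * p - 1L
      while (j + 1L <= n && acgt[j + 1L] && x[j + 1L] == x[j + 1L - p]) {
        j <- j + 1L
      }
      k <- (j - i + 1L) %/% p
      motif <- paste(x[i:(i + p - 1L)], collapse = "")
      if (k >= 2L && oracle_is_primitive(motif)) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = i, end = i + k * p - 1L, motif = motif,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Eager greedy overlap elimination on a coverage mask, same ordering as the
# spec'd rule: longest effective tract first, then leftmost start, then
# smaller motif length; truncation keeps the longest free stretch cut to
# whole (phase-rotated) copies.
oracle_resolve_overlaps <- function(loci, min_tract) {
  if (nrow(loci) == 0L) return(loci)
  mask <- rep(FALSE, max(loci$end))
  cand <- lapply(seq_len(nrow(loci)), function(i) loci[i, , drop = FALSE])
  sel <- list()
  repeat {
    # recompute every candidate's best free sub-tract under the mask
    eff <- lapply(cand, function(lc) {
      free <- rle(!mask[lc$start:lc$end])
      ends <- cumsum(free$lengths)
      best <- NULL
      for (r in which(free$values)) {
        a <- lc$start + ends[r] - free$lengths[r]
        len <- free$lengths[r]
        p <- lc$motif_length
        k <- len %/% p
        if (k >= 2L && k * p >= min_tract) {
          if (is.null(best) || k * p > (best$end - best$start + 1L)) {
            d <- (a - lc$start) %% p
            motif <- paste0(substr(lc$motif, d + 1L, p),
                            substr(lc$motif, 1L, d))
            best <- data.frame(seq_id = lc$seq_id, start = a,
                               end = a + k * p - 1L, motif = motif,
                               motif_length = p,
                               stringsAsFactors = FALSE)
          }
        }
      }
      best
    })
    keep <- !vapply(eff, is.null, logical(1))
    eff <- eff[keep]; cand <- cand[keep]
    if (!length(eff)) break
    lens <- vapply(eff, function(e) e$end - e$start + 1L, integer(1))
    starts <- vapply(eff, function(e) e$start, integer(1))
    ps <- vapply(eff, function(e) e$motif_length, integer(1))
    pick <- order(-lens, starts, ps)[1L]
    chosen <- eff[[pick]]
    dup <- length(sel) && any(vapply(sel, function(s) {
      s$start == chosen$start && s$end == chosen$end &&
        s$motif == chosen$motif
    }, logical(1)))
    if (!dup) {
      sel[[length(sel) + 1L]] <- chosen
      mask[chosen$start:chosen$end] <- TRUE
    }
    cand <- cand[-pick]
  }
  out <- do.call(rbind, sel)
  out <- out[order(out$start, out$motif_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# standard genetic code from the classic TCAG wheel encoding -- an
# independent source for the 64 translations
oracle_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0("FFLLSSSSYY**CC*W",
                        "LLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRR",
                        "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(vapply(bases, function(b1)
    vapply(bases, function(b2)
      vapply(bases, function(b3) paste0(b1, b2, b3), character(1)),
      character(4)), matrix(character(1), 4, 4)))
  stats::setNames(aa, codons)
}

# a mixed bag of motif lengths, scaled to at most one tract per sequence
plant_rules_default <- function(n_total) {
  motifs <- c("AG", "CT", "GCA", "AAG", "AAGG", "TTCGA", "ACGTAC")
  reps <- c(12L, 10L, 8L, 7L, 6L, 4L, 4L)
  data.frame(
    motif = motifs, repeat_count = reps,
    n_loci = tabulate(rep(seq_along(motifs), length.out = n_total),
                      nbins = length(motifs)),
    stringsAsFactors = FALSE
  )
}

small_synth_db <- function(seed, n_sequences = 60L, rules = NULL) {
  if (is.null(rules)) {
    rules <- plant_rules_default(floor(0.8 * n_sequences))
  }
  generate_database(synthetic_spec(
    n_sequences = n_sequences, length_range = c(500L, 900L),
    plant_rules = rules, seed = seed))
}
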