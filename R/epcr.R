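#' In-silico PCR parameters
#'
#' Defaults for primer design and electronic-PCR scanning. Primer picking
#' is a deterministic window rule, not thermodynamic design: the point of
#' the in-silico transfer assay is where primer sites survive across
#' species, not primer optimization.
#'
#' @param max_mismatches_per_primer mismatches tolerated per primer outside
#'   the 3' anchor.
#' @param three_prime_anchor bases at the primer 3' end that must match
#'   exactly.
#' @param max_product_bp maximum reported product length.
#' @param primer_length window length used by the primer picker.
#' @param flank_offset minimum distance (bases) between a primer window and
#'   the repeat tract.
#' @param max_homopolymer_run windows containing a mononucleotide run
#'   longer than this are rejected.
#' @return an `epcr_params` list.
#' @export
epcr_params <- function(max_mismatches_per_primer = 1L,
                        three_prime_anchor = 5L,
                        max_product_bp = 5000L,
                        primer_length = 20L,
                        flank_offset = 3L,
                        max_homopolymer_run = 5L) {
  if (primer_length < 15L || primer_length > 30L) {
    stop("primer_length must be 15-30 bases")
  }
  if (three_prime_anchor > primer_length) {
    stop("three_prime_anchor cannot exceed the primer length")
  }
  if (max_product_bp < 2L * primer_length) {
    stop("max_product_bp must allow both primer sites")
  }
  structure(list(max_mismatches_per_primer =
                   as.integer(max_mismatches_per_primer),
                 three_prime_anchor = as.integer(three_prime_anchor),
                 max_product_bp = as.integer(max_product_bp),
                 primer_length = as.integer(primer_length),
                 flank_offset = as.integer(flank_offset),
                 max_homopolymer_run = as.integer(max_homopolymer_run)),
            class = "epcr_params")
}

valid_primer_window <- function(window, max_run) {
  if (!grepl("^[ACGT]+$", window)) return(FALSE)
  max(rle(strsplit(window, "", fixed = TRUE)[[1]])$lengths) <= max_run
}

#' Design a flanking primer pair for one SSR locus
#'
#' Picks a fixed-length window on each flank, at least `flank_offset` bases
#' away from the tract, scanning outward from the tract and taking the
#' first window free of ambiguity characters and of mononucleotide runs
#' longer than `max_homopolymer_run`. Returns `NULL` when either flank has
#' no admissible window. The reverse primer is reported 5'->3' on the
#' opposite strand.
#'
#' @param locus one-row loci `data.frame` (needs `seq_id`, `start`, `end`,
#'   `canonical_pair`).
#' @param record the sequence the locus lies on (character scalar).
#' @param params an [epcr_params()].
#' @return one-row `data.frame` (`pair_id`, `source_seq`, `source_start`,
#'   `source_end`, `source_pair`, `forward`, `reverse`, `fwd_site_start`,
#'   `rev_site_end`) or `NULL`.
#' @export
design_flanking_primers <- function(locus, record,
                                    params = epcr_params()) {
  stopifnot(is.character(record), length(record) == 1L)
  record <- toupper(unname(record))
  n <- nchar(record)
  if (locus$end > n || locus$start < 1L) {
    stop("locus does not lie on the supplied record")
  }
  pl <- params$primer_length
  off <- params$flank_offset

  fwd <- NULL; fwd_start <- NA_integer_
  e5 <- locus$start - 1L - off
  while (is.null(fwd) && e5 >= pl) {
    w <- substr(record, e5 - pl + 1L, e5)
    if (valid_primer_window(w, params$max_homopolymer_run)) {
      fwd <- w; fwd_start <- e5 - pl + 1L
    }
    e5 <- e5 - 1L
  }
  if (is.null(fwd)) return(NULL)

  rev_site <- NULL; rev_end <- NA_integer_
  s3 <- locus$end + 1L + off
  while (is.null(rev_site) && s3 + pl - 1L <= n) {
    w <- substr(record, s3, s3 + pl - 1L)
    if (valid_primer_window(w, params$max_homopolymer_run)) {
      rev_site <- w; rev_end <- s3 + pl - 1L
    }
    s3 <- s3 + 1L
  }
  if (is.null(rev_site)) return(NULL)

  data.frame(
    pair_id = sprintf("%s_%d", locus$seq_id, locus$start),
    source_seq = locus$seq_id,
    source_start = locus$start,
    source_end = locus$end,
    source_pair = locus$canonical_pair,
    forward = fwd,
    reverse = revcomp_chr(rev_site),
    fwd_site_start = fwd_start,
    rev_site_end = rev_end,
    stringsAsFactors = FALSE
  )
}

#' Design primer pairs for all loci of a mined database
#'
#' @param mining an `ssr_mining` object.
#' @param records the records the database was mined from.
#' @param params an [epcr_params()].
#' @param exclude_homopolymer skip mononucleotide loci (default), whose
#'   tracts are poor marker candidates.
#' @return `data.frame` of primer pairs (one row per locus with usable
#'   flanks) with a `source_db` column.
#' @export
design_primers <- function(mining, records, params = epcr_params(),
                           exclude_homopolymer = TRUE) {
  chars <- as_record_chars(records)
  loci <- mining$loci
  if (exclude_homopolymer) loci <- loci[!loci$homopolymer, , drop = FALSE]
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    design_flanking_primers(loci[i, , drop = FALSE],
                            chars[[loci$seq_id[i]]], params)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pair_id = character(), source_seq = character(),
               source_start = integer(), source_end = integer(),
               source_pair = character(), forward = character(),
               reverse = character(), fwd_site_start = integer(),
               rev_site_end = integer(), stringsAsFactors = FALSE)
  }
  out <- cbind(data.frame(source_db = rep(mining$database, nrow(out)),
                          stringsAsFactors = FALSE), out)
  `rownames<-`(out, NULL)
}

# all plus-strand binding sites of `primer` in `subject` with at most
# `mm` mismatches, the anchor region matching exactly.
# anchor_at "end": primer 3' end is the site's right edge (forward primer);
# "start": primer 3' end is the site's left edge (reverse primer site given
# as the plus-strand reverse complement).
primer_sites <- function(primer, subject, mm, anchor, anchor_at = "end") {
  hits <- Biostrings::matchPattern(primer, Biostrings::DNAString(subject),
                                   max.mismatch = mm)
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  }
  pchars <- strsplit(primer, "", fixed = TRUE)[[1]]
  pl <- length(pchars)
  anchor_idx <- if (anchor_at == "end") {
    seq.int(pl - anchor + 1L, pl)
  } else {
    seq_len(anchor)
  }
  st <- Biostrings::start(hits)
  en <- Biostrings::end(hits)
  keep <- logical(length(st)); nmm <- integer(length(st))
  for (i in seq_along(st)) {
    schars <- strsplit(substr(subject, st[i], en[i]), "", fixed = TRUE)[[1]]
    diffs <- which(schars != pchars)
    nmm[i] <- length(diffs)
    keep[i] <- nmm[i] <= mm && !any(diffs %in% anchor_idx)
  }
  data.frame(start = st[keep], end = en[keep], mismatches = nmm[keep])
}

#' Scan target databases for virtual amplicons
#'
#' Reports every (pair, target sequence, site pair) where the forward
#' primer matches the plus strand and the reverse primer matches the minus
#' strand downstream, each with at most `max_mismatches_per_primer`
#' mismatches outside an exactly matching 3' anchor, the two sites do not
#' overlap, and the product (primer sites included) is at most
#' `max_product_bp`. Multiple products per pair and target are all
#' reported.
#'
#' @param pairs primer `data.frame` from [design_primers()].
#' @param targets named `DNAStringSet` or named character vector.
#' @param params an [epcr_params()].
#' @param target_db label of the target database.
#' @return amplicon `data.frame` (`pair_id`, `target_db`, `target_seq`,
#'   `start`, `end`, `product_length`, `mismatches_fwd`, `mismatches_rev`),
#'   ordered by pair, target, start.
#' @export
epcr_scan <- function(pairs, targets, params = epcr_params(),
                      target_db = "target") {
  chars <- as_record_chars(targets)
  mm <- params$max_mismatches_per_primer
  anchor <- params$three_prime_anchor
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    fwd <- pairs$forward[i]
    rev_plus <- revcomp_chr(pairs$reverse[i])
    for (sid in names(chars)) {
      subject <- chars[[sid]]
      fsites <- primer_sites(fwd, subject, mm, anchor, anchor_at = "end")
      if (nrow(fsites) == 0L) next
      rsites <- primer_sites(rev_plus, subject, mm, anchor,
                             anchor_at = "start")
      if (nrow(rsites) == 0L) next
      for (a in seq_len(nrow(fsites))) {
        for (b in seq_len(nrow(rsites))) {
          if (rsites$start[b] <= fsites$end[a]) next
          len <- rsites$end[b] - fsites$start[a] + 1L
          if (len > params$max_product_bp) next
          out[[length(out) + 1L]] <- data.frame(
            pair_id = pairs$pair_id[i], target_db = target_db,
            target_seq = sid, start = fsites$start[a],
            end = rsites$end[b], product_length = len,
            mismatches_fwd = fsites$mismatches[a],
            mismatches_rev = rsites$mismatches[b],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pair_id = character(), target_db = character(),
                      target_seq = character(), start = integer(),
                      end = integer(), product_length = integer(),
                      mismatches_fwd = integer(),
                      mismatches_rev = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$pair_id, res$target_seq, res$start), , drop = FALSE]
  `rownames<-`(res, NULL)
}

#' Flag amplicons that contain the expected SSR class
#'
#' An amplicon is on-target when its product span contains at least one
#' class I locus of the target database whose canonical pair equals the
#' canonical pair of the locus the primers were designed around.
#'
#' @param amplicons output of [epcr_scan()].
#' @param target_mining `ssr_mining` of the target database.
#' @param pairs the primer `data.frame` (supplies `source_pair`).
#' @return `amplicons` with a logical `on_target` column.
#' @export
classify_on_target <- function(amplicons, target_mining, pairs) {
  loci <- target_mining$loci
  src <- stats::setNames(pairs$source_pair, pairs$pair_id)
  amplicons$on_target <- vapply(seq_len(nrow(amplicons)), function(i) {
    a <- amplicons[i, ]
    hit <- loci$seq_id == a$target_seq &
      loci$start >= a$start & loci$end <= a$end &
      loci$canonical_pair == src[[a$pair_id]]
    any(hit)
  }, logical(1))
  amplicons
}

#' Cross-database transferability rates
#'
#' The transfer rate from a source to a target database is the percentage
#' of primer pairs with at least one virtual amplicon in the target. The
#' per-pair amplicon counts (one, two, three ... products) are returned
#' alongside.
#'
#' @param pairs primer `data.frame` (single source, or several stacked with
#'   distinct `source_db`).
#' @param targets named list of target databases (`DNAStringSet` or named
#'   character vectors).
#' @param params an [epcr_params()].
#' @param target_minings optional named list of `ssr_mining` objects for the
#'   targets; when given, amplicons carry an `on_target` flag.
#' @return list with `rates` (`source_db`, `target_db`, `n_pairs`,
#'   `n_amplifying`, `rate_pct`), `pair_counts` (per pair and target) and
#'   the combined `amplicons`.
#' @export
transferability_matrix <- function(pairs, targets, params = epcr_params(),
                                   target_minings = NULL) {
  stopifnot(length(targets) >= 1L, !is.null(names(targets)))
  sources <- unique(pairs$source_db)
  amp_all <- list(); rates <- list(); counts <- list()
  for (tdb in names(targets)) {
    for (sdb in sources) {
      p <- pairs[pairs$source_db == sdb, , drop = FALSE]
      amps <- epcr_scan(p, targets[[tdb]], params, target_db = tdb)
      if (!is.null(target_minings) && tdb %in% names(target_minings)) {
        amps <- classify_on_target(amps, target_minings[[tdb]], p)
      }
      amp_all[[length(amp_all) + 1L]] <- cbind(
        data.frame(source_db = rep(sdb, nrow(amps))), amps)
      n_amp <- vapply(p$pair_id,
                      function(id) sum(amps$pair_id == id), integer(1))
      counts[[length(counts) + 1L]] <- data.frame(
        source_db = sdb, target_db = tdb, pair_id = p$pair_id,
        n_amplicons = unname(n_amp), stringsAsFactors = FALSE)
      rates[[length(rates) + 1L]] <- data.frame(
        source_db = sdb, target_db = tdb, n_pairs = nrow(p),
        n_amplifying = sum(n_amp >= 1L),
        rate_pct = if (nrow(p)) {
          round_half_up(100 * sum(n_amp >= 1L) / nrow(p), 2)
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(rates = `rownames<-`(do.call(rbind, rates), NULL),
       pair_counts = `rownames<-`(do.call(rbind, counts), NULL),
       amplicons = `rownames<-`(do.call(rbind, amp_all), NULL))
}

#' Group amplicons into virtual gel lanes
#'
#' Lanes are keyed by (primer pair, target database); each lane is the
#' descending list of product sizes. Duplicate sizes collapse to one band
#' annotated with its multiplicity.
#'
#' @param amplicons amplicon `data.frame`.
#' @return a `virtual_gel` list: `lanes` (named list of descending size
#'   vectors) and `bands` (`lane`, `size`, `count`).
#' @export
virtual_gel <- function(amplicons) {
  if (nrow(amplicons) == 0L) {
    return(structure(list(lanes = list(),
                          bands = data.frame(lane = character(),
                                             size = integer(),
                                             count = integer())),
                     class = "virtual_gel"))
  }
  key <- paste(amplicons$pair_id, amplicons$target_db, sep = "@")
  lanes <- lapply(split(amplicons$product_length, key),
                  function(s) sort(s, decreasing = TRUE))
  bands <- do.call(rbind, lapply(names(lanes), function(k) {
    t <- table(lanes[[k]])
    data.frame(lane = k, size = as.integer(names(t)),
               count = as.integer(t), stringsAsFactors = FALSE)
  }))
  bands <- bands[order(bands$lane, -bands$size), , drop = FALSE]
  structure(list(lanes = lanes, bands = `rownames<-`(bands, NULL)),
            class = "virtual_gel")
}

#' Render a virtual gel as text
#'
#' A log-spaced size ladder runs down the left margin; each lane shows
#' `==` bands at the nearest ladder rung, with `xN` marking co-migrating
#' duplicate products.
#'
#' @param gel a `virtual_gel` object.
#' @param n_rungs number of ladder rungs.
#' @return character vector of gel lines.
#' @export
render_gel <- function(gel, n_rungs = 12L) {
  if (length(gel$lanes) == 0L) return("(no amplicons)")
  sizes <- gel$bands$size
  lo <- max(1, min(sizes) * 0.8)
  hi <- max(sizes) * 1.2
  rungs <- round(exp(seq(log(hi), log(lo), length.out = n_rungs)))
  lanes <- names(gel$lanes)
  wl <- max(nchar(lanes), 6L)
  header <- paste0(formatC("bp", width = 6),
                   paste(formatC(lanes, width = wl + 2L), collapse = ""))
  rows <- vapply(rungs, function(r) {
    cells <- vapply(lanes, function(k) {
      b <- gel$bands[gel$bands$lane == k, , drop = FALSE]
      # nearest rung in log space gets the band
      rung_of <- rungs[vapply(b$size, function(s) {
        which.min(abs(log(rungs) - log(s)))
      }, integer(1))]
      hit <- b[rung_of == r, , drop = FALSE]
      if (nrow(hit) == 0L) {
        "  .  "
      } else if (any(hit$count > 1L)) {
        sprintf(" ==x%d", max(hit$count))
      } else {
        " === "
      }
    }, character(1))
    paste0(formatC(r, width = 6),
           paste(formatC(cells, width = wl + 2L), collapse = ""))
  }, character(1))
  c(header, rows)
}
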