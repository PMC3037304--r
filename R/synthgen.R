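#' Specification of a synthetic EST database
#'
#' Describes a database of random "EST" sequences with planted perfect
#' repeat tracts and a machine-readable truth table, emulating clustered
#' non-redundant EST collections: 300-1000 bp sequences, a configurable GC
#' background, optional 3' poly-A tails, and repeat tracts of chosen motif
#' and copy number. Planted tracts are separated from each other and from
#' the sequence ends by at least `margin` bases; background regions are
#' redrawn until they contain no accidental tandem repeat reaching
#' `min_tract_guard` bases, so the truth table is the complete class I
#' locus set by construction.
#'
#' @param n_sequences number of sequences.
#' @param length_range `c(min, max)` sequence length in bases.
#' @param gc_background GC fraction of background bases.
#' @param plant_rules `data.frame` with columns `motif`, `repeat_count`,
#'   `n_loci`: how many tracts of each kind to plant, distributed
#'   round-robin over sequences.
#' @param polyA_fraction fraction of sequences given a 3' poly-A tail.
#' @param polyA_length tail length; must stay below `min_tract_guard` so
#'   tails never become unplanted class I homopolymer loci.
#' @param margin minimum distance (bases) between tracts and from sequence
#'   ends; the default exceeds the default compound interruption limit, so
#'   planted loci mine as singles.
#' @param min_tract_guard tract length from which accidental background
#'   repeats are rejected (the class I threshold).
#' @param seed integer seed governing all randomness.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_sequences = 100L,
                           length_range = c(300L, 1000L),
                           gc_background = 0.5,
                           plant_rules = NULL,
                           polyA_fraction = 0,
                           polyA_length = 15L,
                           margin = 120L,
                           min_tract_guard = 20L,
                           seed = 1L) {
  if (is.null(plant_rules)) {
    plant_rules <- data.frame(motif = character(), repeat_count = integer(),
                              n_loci = integer())
  }
  stopifnot(n_sequences >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2], length_range[1] >= 1L,
            gc_background > 0, gc_background < 1,
            polyA_fraction >= 0, polyA_fraction <= 1,
            margin >= 1L, min_tract_guard >= 2L)
  if (nrow(plant_rules)) {
    stopifnot(all(grepl("^[ACGT]+$", plant_rules$motif)),
              all(nchar(plant_rules$motif) <= 10L),
              all(plant_rules$repeat_count >= 2L),
              all(plant_rules$n_loci >= 0L))
    if (!all(vapply(plant_rules$motif, is_primitive_motif, logical(1)))) {
      stop("planted motifs must be primitive")
    }
  }
  if (polyA_fraction > 0 && polyA_length >= min_tract_guard) {
    stop("polyA_length must stay below min_tract_guard")
  }
  if (polyA_fraction > 0 && margin <= polyA_length) {
    stop("margin must exceed polyA_length")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 gc_background = gc_background,
                 plant_rules = plant_rules,
                 polyA_fraction = polyA_fraction,
                 polyA_length = as.integer(polyA_length),
                 margin = as.integer(margin),
                 min_tract_guard = as.integer(min_tract_guard),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

draw_background <- function(n, gc) {
  if (n == 0L) return(character(0))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# redraw a single base until it differs from `forbidden`
draw_base_not <- function(gc, forbidden) {
  repeat {
    b <- draw_background(1L, gc)
    if (!b %in% forbidden) return(b)
  }
}

# class I loci the miner would report on one sequence
mine_one <- function(seqchar, sid, guard) {
  cfg <- mining_config(min_tract_bp = guard)
  resolve_overlaps(filter_class_I(
    find_perfect_repeats(seqchar, cfg, seq_id = sid), cfg), cfg)
}

#' Generate a synthetic EST database with planted SSR tracts
#'
#' Background bases are drawn per-base from the GC-parameterized
#' distribution; planted tracts are inserted verbatim with the requested
#' margins. Each sequence is verified by mining it: when the background
#' accidentally creates, extends or distorts a class I locus the background
#' is redrawn, so mining the emitted database returns exactly the truth
#' rows. The same seed always yields byte-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (named `DNAStringSet`), `truth`
#'   (`data.frame`: `seq_id`, `start`, `end`, `motif`, `repeat_count`) and
#'   `spec`.
#' @export
generate_database <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rules <- spec$plant_rules
  tract_motif <- rep(rules$motif, rules$n_loci)
  tract_reps <- rep(rules$repeat_count, rules$n_loci)
  n <- spec$n_sequences
  assign_to <- if (length(tract_motif)) {
    ((seq_along(tract_motif) - 1L) %% n) + 1L
  } else integer(0)

  with_seed(spec$seed, {
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   n, replace = TRUE)
    has_tail <- stats::runif(n) < spec$polyA_fraction

    # feasibility before any emission
    for (i in seq_len(n)) {
      idx <- which(assign_to == i)
      need <- sum(nchar(tract_motif[idx]) * tract_reps[idx]) +
        (length(idx) + 1L) * spec$margin
      if (need > lens[i]) {
        stop("infeasible spec: planted tracts do not fit in sequence ", i,
             " (need ", need, " bp, have ", lens[i], ")")
      }
    }

    ids <- sprintf("synth_%05d", seq_len(n))
    seqs <- character(n)
    truth <- list()
    for (i in seq_len(n)) {
      idx <- which(assign_to == i)
      motifs <- tract_motif[idx]
      reps <- tract_reps[idx]
      tracts <- strrep(motifs, reps)
      m <- length(tracts)
      L <- lens[i]
      slack <- L - sum(nchar(tracts)) - (m + 1L) * spec$margin
      for (attempt in seq_len(100L)) {
        gaps <- rep(spec$margin, m + 1L)
        if (slack > 0L) {
          extra <- tabulate(sample.int(m + 1L, slack, replace = TRUE),
                            nbins = m + 1L)
          gaps <- gaps + extra
        }
        segs <- lapply(gaps, function(g)
          draw_background(g, spec$gc_background))
        # guard the junctions against single-base tract extension
        for (j in seq_len(m)) {
          p <- nchar(motifs[j])
          left_ban <- substr(motifs[j], p, p)
          right_ban <- substr(motifs[j], 1L, 1L)
          g <- segs[[j]]
          if (length(g) && g[length(g)] == left_ban) {
            segs[[j]][length(g)] <-
              draw_base_not(spec$gc_background, left_ban)
          }
          g2 <- segs[[j + 1L]]
          if (length(g2) && g2[1L] == right_ban) {
            segs[[j + 1L]][1L] <-
              draw_base_not(spec$gc_background, right_ban)
          }
        }
        if (has_tail[i]) {
          last <- segs[[m + 1L]]
          tail_at <- (length(last) - spec$polyA_length + 1L):length(last)
          last[tail_at] <- "A"
          if (tail_at[1L] > 1L && last[tail_at[1L] - 1L] == "A") {
            last[tail_at[1L] - 1L] <-
              draw_base_not(spec$gc_background, "A")
          }
          segs[[m + 1L]] <- last
        }
        pieces <- character(2L * m + 1L)
        pieces[seq(1L, 2L * m + 1L, by = 2L)] <-
          vapply(segs, paste, character(1), collapse = "")
        if (m) pieces[seq(2L, 2L * m, by = 2L)] <- tracts
        seqchar <- paste(pieces, collapse = "")
        starts <- integer(m)
        pos <- 1L
        for (j in seq_len(m)) {
          pos <- pos + gaps[j]
          starts[j] <- pos
          pos <- pos + nchar(tracts[j])
        }
        mined <- mine_one(seqchar, ids[i], spec$min_tract_guard)
        expect_class1 <- nchar(tracts) >= spec$min_tract_guard
        want <- data.frame(start = starts[expect_class1],
                           end = (starts + nchar(tracts) - 1L)[expect_class1],
                           motif = motifs[expect_class1])
        clean <- nrow(mined) == nrow(want) &&
          (nrow(want) == 0L ||
             all(mined$start == want$start & mined$end == want$end &
                   mined$motif == want$motif))
        if (clean) break
        if (attempt == 100L) {
          stop("could not draw a clean background for sequence ", i)
        }
      }
      seqs[i] <- seqchar
      if (m) {
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = ids[i], start = starts,
          end = starts + nchar(tracts) - 1L,
          motif = motifs, repeat_count = reps, stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) {
      `rownames<-`(do.call(rbind, truth), NULL)
    } else {
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 motif = character(), repeat_count = integer())
    }
    records <- Biostrings::DNAStringSet(seqs)
    names(records) <- ids
    list(records = records, truth = truth, spec = spec)
  })
}

#' Derive a diverged "ortholog" database
#'
#' Applies point substitutions at the given per-base rate to a generated
#' database, emulating sequence divergence between species. Planted tracts
#' are untouched by default (truth table carries over); with
#' `flank_conservation` the primer-design windows next to each tract
#' (within `frozen_flank` bases) are frozen as well, so self-designed
#' primers keep exact binding sites. With `mutate_tracts` substitutions may
#' also fall inside tracts and the truth table is rebuilt by re-mining.
#'
#' @param records named `DNAStringSet` or named character vector.
#' @param truth truth `data.frame` from [generate_database()].
#' @param divergence substitution rate per base, in `[0, 1]`.
#' @param flank_conservation freeze the flanking windows around each tract.
#' @param frozen_flank width (bases) of the frozen flank windows.
#' @param mutate_tracts allow substitutions inside planted tracts.
#' @param min_tract_guard class threshold used when re-mining mutated
#'   tracts.
#' @param seed integer seed.
#' @return list with mutated `records` and updated `truth`.
#' @export
derive_ortholog_database <- function(records, truth, divergence,
                                     flank_conservation = TRUE,
                                     frozen_flank = 30L,
                                     mutate_tracts = FALSE,
                                     min_tract_guard = 20L,
                                     seed = 1L) {
  if (divergence < 0 || divergence > 1) {
    stop("divergence must be in [0, 1]")
  }
  chars <- as_record_chars(records)
  with_seed(seed, {
    out <- vapply(names(chars), function(sid) {
      x <- strsplit(chars[[sid]], "", fixed = TRUE)[[1]]
      n <- length(x)
      frozen <- rep(FALSE, n)
      rows <- truth[truth$seq_id == sid, , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        if (!mutate_tracts) {
          frozen[rows$start[j]:rows$end[j]] <- TRUE
        }
        if (flank_conservation) {
          a <- max(1L, rows$start[j] - frozen_flank)
          b <- min(n, rows$end[j] + frozen_flank)
          frozen[a:b] <- TRUE
          if (mutate_tracts) frozen[rows$start[j]:rows$end[j]] <- FALSE
        }
      }
      hit <- which(stats::runif(n) < divergence & !frozen)
      for (i in hit) x[i] <- sample(setdiff(DNA_BASES, x[i]), 1L)
      paste(x, collapse = "")
    }, character(1))
    new_records <- Biostrings::DNAStringSet(out)
    names(new_records) <- names(chars)
    new_truth <- if (mutate_tracts) {
      mined <- lapply(names(out), function(sid) {
        loc <- mine_one(out[[sid]], sid, min_tract_guard)
        loc[, c("seq_id", "start", "end", "motif", "repeat_count"),
            drop = FALSE]
      })
      `rownames<-`(do.call(rbind, mined), NULL)
    } else {
      truth
    }
    list(records = new_records, truth = new_truth)
  })
}
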