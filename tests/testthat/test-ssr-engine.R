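test_that("find_perfect_repeats returns maximal primitive tandem repeats", {
  # the TT run is the only unit repeated twice in GATTACA
  pre <- find_perfect_repeats("GATTACA")
  expect_equal(nrow(pre), 1L)
  expect_equal(pre$motif, "T")
  expect_equal(c(pre$start, pre$end, pre$repeat_count), c(3L, 4L, 2L))

  # a clean dimer tract flanked by C runs
  loci <- find_perfect_repeats(paste0("CC", strrep("AG", 12), "CC"))
  ag <- loci[loci$motif == "AG", ]
  expect_equal(nrow(ag), 1L)
  expect_equal(c(ag$start, ag$end, ag$repeat_count), c(3L, 26L, 12L))

  # primitive motif only: AT, never ATAT
  loci <- find_perfect_repeats(strrep("AT", 10))
  expect_equal(loci$motif, "AT")
  expect_equal(loci$repeat_count, 10L)

  # ambiguity characters terminate tracts
  split <- find_perfect_repeats(paste0(strrep("AG", 6), "N", strrep("AG", 6)))
  expect_equal(nrow(split), 2L)
  expect_equal(split$repeat_count, c(6L, 6L))

  expect_equal(nrow(find_perfect_repeats("ACGTACGATCAG")), 0L)
})

test_that("find_perfect_repeats matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:40) {
    gc <- sample(c(0.3, 0.5, 0.7), 1)
    s <- random_dna(sample(100:400, 1), gc = gc)
    # low-complexity stretches provoke overlapping periodicities
    if (rep %% 3 == 0) {
      ins <- paste(sample(c("A", "G"), 40, replace = TRUE), collapse = "")
      at <- sample(nchar(s) - 45, 1)
      s <- paste0(substr(s, 1, at), ins, substr(s, at + 1, nchar(s)))
    }
    got <- find_perfect_repeats(s)
    want <- oracle_perfect_repeats(s)
    expect_equal(got[, c("start", "end", "motif")], want,
                 ignore_attr = TRUE)
  }
})

test_that("class I filter keeps tracts of at least 20 bp of whole copies", {
  cfg <- mining_config()
  mk <- function(motif, k) find_perfect_repeats(
    paste0("CTGCTA", strrep(motif, k), "TCAGGT"))
  expect_equal(nrow(filter_class_I(mk("AG", 9), cfg)), 0L)   # 18 bp
  expect_equal(nrow(filter_class_I(mk("AG", 10), cfg)), 1L)  # 20 bp boundary
  expect_equal(nrow(filter_class_I(mk("GCA", 7), cfg)), 1L)  # 21 bp
  expect_equal(nrow(filter_class_I(mk("GCA", 6), cfg)), 0L)  # 18 bp
  # order preserved
  s <- paste0(strrep("AG", 10), "CCTAGCTTACGATCAGTTACGAGTCAACT",
              strrep("GCA", 7))
  kept <- filter_class_I(find_perfect_repeats(s), cfg)
  expect_equal(kept$motif, c("AG", "GCA"))
})

test_that("resolve_overlaps yields a non-overlapping set matching the greedy oracle", {
  cfg <- mining_config()
  # adjacent AAG and AG tracts produce overlapping maximal repeats
  s <- paste0(strrep("AAG", 7), strrep("AG", 10))
  pre <- filter_class_I(find_perfect_repeats(s), cfg)
  expect_true(nrow(pre) >= 2L)
  got <- resolve_overlaps(pre, cfg)
  want <- oracle_resolve_overlaps(pre, cfg$min_tract_bp)
  expect_equal(got[, c("start", "end", "motif")],
               want[, c("start", "end", "motif")], ignore_attr = TRUE)

  # two disjoint loci are returned unchanged
  s2 <- paste0(strrep("AG", 10), "CCTAGCTTACGATCAGTTACGAGTCAACT",
               strrep("GCA", 7))
  pre2 <- filter_class_I(find_perfect_repeats(s2), cfg)
  expect_equal(resolve_overlaps(pre2, cfg), pre2)

  # identical duplicates collapse to one
  dup <- rbind(pre2[1, ], pre2[1, ])
  expect_equal(nrow(resolve_overlaps(dup, cfg)), 1L)

  # property: low-complexity sequences, implementation == oracle,
  # and the output is pairwise non-overlapping
  set.seed(23)
  cfg8 <- mining_config(min_tract_bp = 8L)
  for (i in 1:25) {
    s <- paste(sample(c("A", "G", "T"), 150, replace = TRUE,
                      prob = c(0.45, 0.45, 0.1)), collapse = "")
    pre <- filter_class_I(find_perfect_repeats(s, cfg8), cfg8)
    got <- resolve_overlaps(pre, cfg8)
    if (nrow(got) > 1L) {
      o <- order(got$start)
      expect_true(all(got$start[o][-1L] > got$end[o][-nrow(got)]))
    }
    want <- oracle_resolve_overlaps(pre, cfg8$min_tract_bp)
    expect_equal(got[, c("start", "end", "motif")],
                 want[, c("start", "end", "motif")], ignore_attr = TRUE)
  }
})

test_that("assemble_compounds merges nearby loci transitively and conserves loci", {
  cfg <- mining_config()
  two_tracts <- function(gap) {
    set.seed(gap)  # fixed aperiodic filler between the tracts
    s <- paste0(strrep("AG", 10), random_dna(gap), strrep("GCA", 7))
    loci <- resolve_overlaps(filter_class_I(
      find_perfect_repeats(s, cfg), cfg), cfg)
    stopifnot(nrow(loci) == 2L)  # filler stayed repeat-free
    loci
  }
  near <- assemble_compounds(two_tracts(5L), cfg)
  expect_equal(nrow(near$singles), 0L)
  expect_equal(nrow(near$compounds), 2L)
  expect_equal(near$compounds$gap_before, c(NA_integer_, 5L))

  far <- assemble_compounds(two_tracts(150L), cfg)
  expect_equal(nrow(far$singles), 2L)
  expect_equal(nrow(far$compounds), 0L)

  # transitive merging of three tracts with gaps 10 and 10
  s3 <- paste0(strrep("AG", 10), strrep("CTGAT", 2),
               strrep("GCA", 7), strrep("TCAGR", 2), strrep("TTAGGC", 4))
  loci3 <- resolve_overlaps(filter_class_I(
    find_perfect_repeats(s3, cfg), cfg), cfg)
  expect_equal(nrow(loci3), 3L)
  comp3 <- assemble_compounds(loci3, cfg)
  expect_equal(nrow(comp3$compounds), 3L)
  expect_equal(length(unique(comp3$compounds$compound_id)), 1L)

  # conservation: every input locus lands in exactly one output
  expect_equal(nrow(comp3$singles) + nrow(comp3$compounds), nrow(loci3))
})

test_that("canonical_pair folds reverse complements but not rotations", {
  expect_equal(canonical_pair("AG"), "AG/CT")
  expect_equal(canonical_pair("CT"), "AG/CT")
  expect_equal(canonical_pair("GA"), "GA/TC")
  expect_equal(canonical_pair("GC"), "GC/GC")
  expect_error(canonical_pair("AN"), "A/C/G/T")

  # exhaustive for lengths 1-4: label is strand-invariant
  for (p in 1:4) {
    motifs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), p)),
                    1, paste, collapse = "")
    rc <- vapply(motifs, function(m) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1]]),
            collapse = "")
    }, character(1))
    expect_equal(canonical_pair(motifs), canonical_pair(unname(rc)))
  }
  # sampled for lengths 5-10
  set.seed(5)
  for (p in 5:10) {
    motifs <- vapply(1:20, function(i) random_dna(p), character(1))
    rc <- vapply(motifs, function(m) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1]]),
            collapse = "")
    }, character(1))
    expect_equal(canonical_pair(motifs), canonical_pair(unname(rc)))
  }
})

test_that("mine_database composes the pipeline deterministically", {
  expect_equal(nrow(mine_database(
    stats::setNames(character(), character()))$loci), 0L)

  recs <- c(est1 = paste0("CC", strrep("AG", 12), "CC"))
  m <- mine_database(recs, database = "one")
  expect_equal(nrow(m$loci), 1L)
  expect_equal(m$loci$locus_type, "single")

  db <- small_synth_db(seed = 41, n_sequences = 30L)
  m1 <- mine_database(db$records, database = "sim")
  m2 <- mine_database(db$records, database = "sim")
  expect_identical(m1$loci, m2$loci)
  # recovered loci are exactly the planted truth
  expect_equal(m1$loci[, c("seq_id", "start", "end", "motif")],
               db$truth[order(db$truth$seq_id, db$truth$start),
                        c("seq_id", "start", "end", "motif")],
               ignore_attr = TRUE)
})

test_that("loci TSV export carries the report schema", {
  db <- small_synth_db(seed = 19, n_sequences = 10L)
  m <- mine_database(db$records, database = "sim")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_loci_tsv(m, tsv)
  got <- utils::read.delim(tsv, comment.char = "#")
  expect_equal(nrow(got), nrow(m$loci))
  expect_true(all(c("database", "seq_id", "start", "end", "motif",
                    "canonical_pair", "locus_type", "homopolymer_flag")
                  %in% names(got)))
})
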