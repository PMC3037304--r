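mk_locus <- function(seq_id, start, end, pair = "AG/CT") {
  data.frame(seq_id = seq_id, start = start, end = end,
             canonical_pair = pair, stringsAsFactors = FALSE)
}

test_that("design_flanking_primers picks clean windows or declines", {
  params <- epcr_params()
  tract <- strrep("AG", 12)
  left <- random_dna_fixed(50, seed = 101)
  right <- random_dna_fixed(50, seed = 102)
  rec <- paste0(left, tract, right)
  locus <- mk_locus("r1", 51L, 74L)
  pair <- design_flanking_primers(locus, rec, params)
  expect_false(is.null(pair))
  expect_equal(nchar(pair$forward), 20L)
  expect_equal(nchar(pair$reverse), 20L)
  # product brackets the tract
  expect_lt(pair$fwd_site_start, locus$start)
  expect_gt(pair$rev_site_end, locus$end)

  # insufficient 5' flank
  rec2 <- paste0("ACG", tract, right)
  expect_null(design_flanking_primers(mk_locus("r2", 4L, 27L), rec2, params))

  # every 5' window poisoned by a long mononucleotide run
  rec3 <- paste0(strrep("A", 50), tract, right)
  expect_null(design_flanking_primers(mk_locus("r3", 51L, 74L), rec3,
                                      params))

  # ambiguity characters also disqualify windows
  left_n <- paste0(substr(left, 1, 20), "N", substr(left, 22, 50))
  rec4 <- paste0(left_n, tract, right)
  p4 <- design_flanking_primers(mk_locus("r4", 51L, 74L), rec4, params)
  expect_false(grepl("N", p4$forward))
})

test_that("epcr_scan reports products under anchor and mismatch rules", {
  params <- epcr_params(max_mismatches_per_primer = 1L)
  fwd <- "ACGTACGGTTCAGCATGCTA"
  rev <- "TGCATCAGGATCCGATTACG"   # 5'->3' on the minus strand
  insert <- random_dna_fixed(60, seed = 103)
  template <- c(t1 = paste0(random_dna_fixed(10, seed = 104), fwd, insert,
                            revcomp <- paste(rev(strsplit(chartr(
                              "ACGT", "TGCA", rev), "")[[1]]), collapse = ""),
                            random_dna_fixed(10, seed = 105)))
  pairs <- data.frame(pair_id = "p1", forward = fwd, reverse = rev,
                      stringsAsFactors = FALSE)
  amps <- epcr_scan(pairs, template, params, target_db = "t")
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$product_length, 100L)     # 20 + 60 + 20
  expect_equal(amps$start, 11L)
  expect_equal(amps$end, 110L)

  # one mismatch inside the forward 3' anchor kills the site
  bad_anchor <- template
  x <- strsplit(bad_anchor[[1]], "")[[1]]
  x[30] <- setdiff(c("A", "C", "G", "T"), x[30])[1]   # last base of fwd site
  bad_anchor[1] <- paste(x, collapse = "")
  expect_equal(nrow(epcr_scan(pairs, bad_anchor, params)), 0L)

  # the same substitution outside the anchor is tolerated at mm=1, not mm=0
  bad_mid <- template
  y <- strsplit(bad_mid[[1]], "")[[1]]
  y[13] <- setdiff(c("A", "C", "G", "T"), y[13])[1]   # 3rd base of fwd site
  bad_mid[1] <- paste(y, collapse = "")
  expect_equal(nrow(epcr_scan(pairs, bad_mid, params)), 1L)
  expect_equal(nrow(epcr_scan(pairs, bad_mid,
                              epcr_params(max_mismatches_per_primer = 0L))),
               0L)

  # two downstream reverse sites yield two products
  two_rev <- c(t2 = paste0(random_dna_fixed(10, seed = 104), fwd, insert,
                           revcomp, random_dna_fixed(30, seed = 106),
                           revcomp, random_dna_fixed(10, seed = 105)))
  amps2 <- epcr_scan(pairs, two_rev, params)
  expect_equal(nrow(amps2), 2L)
  expect_equal(amps2$product_length, c(100L, 150L))

  # ...unless the product cap rules the distal one out
  capped <- epcr_params(max_product_bp = 120L)
  expect_equal(nrow(epcr_scan(pairs, two_rev, capped)), 1L)
})

test_that("epcr_scan with zero mismatches equals exact substring search", {
  set.seed(31)
  targets <- stats::setNames(
    vapply(1:5, function(i) random_dna(500), character(1)),
    paste0("t", 1:5))
  fwd <- substr(targets[[2]], 100, 119)
  rev_site <- substr(targets[[2]], 300, 319)
  rev <- paste(rev(strsplit(chartr("ACGT", "TGCA", rev_site), "")[[1]]),
               collapse = "")
  pairs <- data.frame(pair_id = "q", forward = fwd, reverse = rev)
  params0 <- epcr_params(max_mismatches_per_primer = 0L)
  amps <- epcr_scan(pairs, targets, params0)
  # oracle: exact fixed-string positions
  for (sid in names(targets)) {
    f_at <- gregexpr(fwd, targets[[sid]], fixed = TRUE)[[1]]
    r_at <- gregexpr(rev_site, targets[[sid]], fixed = TRUE)[[1]]
    n_expected <- 0L
    for (f in f_at[f_at > 0]) {
      for (r in r_at[r_at > 0]) {
        if (r > f + 19 && r + 19 - f + 1 <= params0$max_product_bp) {
          n_expected <- n_expected + 1L
        }
      }
    }
    expect_equal(sum(amps$target_seq == sid), n_expected)
  }
})

test_that("amplicon sets grow monotonically with allowance and product cap", {
  db <- small_synth_db(seed = 55, n_sequences = 25L)
  m <- mine_database(db$records, database = "src")
  pairs <- design_primers(m, db$records)
  div <- derive_ortholog_database(db$records, db$truth, divergence = 0.05,
                                  flank_conservation = FALSE, seed = 56)
  key <- function(a) paste(a$pair_id, a$target_seq, a$start, a$end)
  prev <- character(0)
  for (mm in 0:2) {
    amps <- epcr_scan(pairs, div$records,
                      epcr_params(max_mismatches_per_primer = mm))
    expect_true(all(prev %in% key(amps)))
    prev <- key(amps)
  }
  a_small <- epcr_scan(pairs, div$records,
                       epcr_params(max_product_bp = 150L))
  a_big <- epcr_scan(pairs, div$records,
                     epcr_params(max_product_bp = 5000L))
  expect_true(all(key(a_small) %in% key(a_big)))
})

test_that("on-target classification requires the source canonical class", {
  tract <- strrep("AG", 12)              # AG/CT
  other <- strrep("GCA", 8)              # GCA/TGC
  mkdb <- function(core) {
    c(x = paste0(random_dna_fixed(40, seed = 107), core,
                 random_dna_fixed(40, seed = 108)))
  }
  src <- mkdb(tract)
  msrc <- mine_database(src, database = "src")
  pairs <- design_primers(msrc, src)
  for (core in list(tract, other, random_dna_fixed(24, seed = 109))) {
    tgt <- mkdb(core)
    mt <- mine_database(tgt, database = "tgt")
    amps <- epcr_scan(pairs, tgt, target_db = "tgt")
    expect_equal(nrow(amps), 1L)
    amps <- classify_on_target(amps, mt, pairs)
    expect_equal(amps$on_target, identical(core, tract))
  }
})

test_that("transferability rates count pairs with at least one product", {
  db <- small_synth_db(seed = 77, n_sequences = 20L)
  m <- mine_database(db$records, database = "src")
  pairs <- design_primers(m, db$records)
  # conserved-flank ortholog: every pair still amplifies, all on target
  cons <- derive_ortholog_database(db$records, db$truth, divergence = 0.3,
                                   flank_conservation = TRUE, seed = 78)
  mt <- mine_database(cons$records, database = "orth")
  res <- transferability_matrix(pairs, list(orth = cons$records),
                                target_minings = list(orth = mt))
  expect_equal(res$rates$rate_pct, 100)
  expect_true(all(res$amplicons$on_target))
  # unrelated target: no amplification
  set.seed(79)
  rnd <- stats::setNames(vapply(1:20, function(i) random_dna(600),
                                character(1)), paste0("r", 1:20))
  res0 <- transferability_matrix(pairs, list(rnd = rnd))
  expect_equal(res0$rates$rate_pct, 0)
  expect_equal(res0$rates$n_amplifying, 0L)
})

test_that("virtual gel lanes sort sizes and collapse duplicate bands", {
  amps <- data.frame(
    pair_id = c("p1", "p1", "p2", "p2"),
    target_db = "t",
    target_seq = c("a", "b", "a", "b"),
    product_length = c(110L, 240L, 180L, 180L),
    stringsAsFactors = FALSE)
  gel <- virtual_gel(amps)
  expect_equal(gel$lanes[["p1@t"]], c(240, 110))
  expect_equal(gel$bands$count[gel$bands$lane == "p2@t"], 2L)
  txt <- render_gel(gel)
  expect_true(any(grepl("x2", txt)))
  empty <- virtual_gel(amps[0, ])
  expect_equal(length(empty$lanes), 0L)
  expect_equal(render_gel(empty), "(no amplicons)")
})
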