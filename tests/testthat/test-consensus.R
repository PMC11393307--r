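ref300 <- setNames(strrep("A", 300), "chr1")   # all-A toy reference

test_that("tandem copies grouped by reciprocal span overlap", {
  seq150 <- strrep("A", 150)
  recs <- rbind(aln_record("rp1", 1, "chr1", 100, seq150),
                aln_record("rp1", 1, "chr1", 100, seq150),
                aln_record("rp1", 1, "chr1", 100, seq150))
  g <- segment_tandem_copies(recs)
  expect_length(g, 1)
  expect_length(g[[1]], 3)

  # copies from both mates of one read pair combine into one group
  recs2 <- rbind(aln_record("rp1", 1, "chr1", 100, seq150),
                 aln_record("rp1", 1, "chr1", 100, seq150),
                 aln_record("rp1", 2, "chr1", 100, seq150),
                 aln_record("rp1", 2, "chr1", 100, seq150))
  g2 <- segment_tandem_copies(recs2)
  expect_length(g2, 1)
  expect_length(g2[[1]], 4)

  # different chromosomes never merge
  recs3 <- rbind(aln_record("rp1", 1, "chr1", 100, seq150),
                 aln_record("rp1", 2, "chr2", 100, seq150))
  g3 <- segment_tandem_copies(recs3)
  expect_length(g3, 2)
  expect_true(all(lengths(g3) == 1))

  # overlap below the reciprocal threshold starts a new group
  recs4 <- rbind(aln_record("rp1", 1, "chr1", 0, seq150),
                 aln_record("rp1", 1, "chr1", 100, seq150))
  expect_length(segment_tandem_copies(recs4), 2)

  expect_length(segment_tandem_copies(recs[0]), 0)  # no mapped records
})

test_that("repeat confirmation requires full agreement of >= 2 high-quality copies", {
  cps <- list(make_copy("chr1", 10, c("T", "A"), qual = 30),
              make_copy("chr1", 10, c("T", "A"), qual = 30),
              make_copy("chr1", 10, c("T", "A"), qual = 30))
  r <- repeat_confirm(cps, 10, ref_base = "C")
  expect_equal(r$status, "CONFIRMED_ALT")
  expect_equal(r$base, "T")
  expect_equal(r$support, 3)

  # disagreement between copies: discarded as error
  cps2 <- list(make_copy("chr1", 10, "T", qual = 30),
               make_copy("chr1", 10, "C", qual = 30))
  expect_equal(repeat_confirm(cps2, 10, ref_base = "C")$status, "UNCONFIRMED")

  # only one usable copy (others below the quality threshold)
  cps3 <- list(make_copy("chr1", 10, "T", qual = 30),
               make_copy("chr1", 10, "T", qual = 20),
               make_copy("chr1", 10, "T", qual = 20))
  expect_equal(repeat_confirm(cps3, 10, ref_base = "C")$status, "UNCONFIRMED")

  # the quality comparison is strict: Q24 is ignored, Q25 is kept
  cps4 <- list(make_copy("chr1", 10, "T", qual = 24),
               make_copy("chr1", 10, "T", qual = 25),
               make_copy("chr1", 10, "T", qual = 25))
  expect_equal(repeat_confirm(cps4, 10, ref_base = "C")$support, 2)

  # position outside all copy spans
  expect_equal(repeat_confirm(cps, 99, ref_base = "C")$status, "UNCONFIRMED")
})

test_that("strict single-mate mode rejects support split across mates", {
  cps <- list(make_copy("chr1", 10, "T", mate = 1L),
              make_copy("chr1", 10, "T", mate = 2L))
  expect_equal(repeat_confirm(cps, 10, ref_base = "C")$status, "CONFIRMED_ALT")
  expect_equal(
    repeat_confirm(cps, 10, ref_base = "C", strict_single_mate = TRUE)$status,
    "UNCONFIRMED")
  # two copies within one mate satisfy strict mode
  cps2 <- list(make_copy("chr1", 10, "T", mate = 1L),
               make_copy("chr1", 10, "T", mate = 1L))
  expect_equal(
    repeat_confirm(cps2, 10, ref_base = "C", strict_single_mate = TRUE)$status,
    "CONFIRMED_ALT")
})

test_that("molecule calling labels the full template span", {
  b <- rep("A", 150)
  cps <- list(make_copy("chr1", 50, b), make_copy("chr1", 50, b),
              make_copy("chr1", 50, b))
  m <- call_molecule(cps, ref300)
  expect_s3_class(m, "molecule_call")
  expect_equal(c(m$start, m$end, m$n_copies), c(50, 200, 3))
  expect_equal(sum(m$calls$status == "CONFIRMED_REF"), 150)

  # one injected per-copy error leaves exactly that position unconfirmed
  b2 <- b; b2[30] <- "G"
  m2 <- call_molecule(list(make_copy("chr1", 50, b), make_copy("chr1", 50, b2),
                           make_copy("chr1", 50, b)), ref300)
  expect_equal(m2$calls[status == "UNCONFIRMED", pos], 79)
  expect_equal(sum(m2$calls$status == "CONFIRMED_REF"), 149)

  # a template variant present in all copies is confirmed as a variant
  b3 <- b; b3[30] <- "G"
  m3 <- call_molecule(rep(list(make_copy("chr1", 50, b3)), 3), ref300)
  expect_equal(m3$calls[pos == 79, status], "CONFIRMED_ALT")
  expect_equal(m3$calls[pos == 79, base], "G")
})

test_that("deduplication keys on (chrom, start, end) and demotes conflicts", {
  b <- rep("A", 150)
  mk <- function(start, bases) call_molecule(
    rep(list(make_copy("chr1", start, bases)), 2), ref300)
  expect_length(dedup_molecules(list(mk(100, b), mk(100, b))), 1)
  m151 <- call_molecule(rep(list(make_copy("chr1", 100, rep("A", 151))), 2),
                        ref300)
  expect_length(dedup_molecules(list(mk(100, b), m151)), 2)

  # 5 molecules, 3 distinct keys
  mols <- list(mk(0, b), mk(0, b), mk(10, b), mk(10, b), mk(20, b))
  expect_length(dedup_molecules(mols), 3)

  # conflicting confirmed calls at one position demote to UNCONFIRMED
  bA <- b; bG <- b; bG[5] <- "G"
  merged <- dedup_molecules(list(mk(100, bA), mk(100, bG)))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$calls[pos == 104, status], "UNCONFIRMED")
  expect_equal(merged[[1]]$calls[pos == 105, status], "CONFIRMED_REF")
})

test_that("pileup depth counts confirmed unique molecules only", {
  b <- rep("A", 50)
  bT <- b; bT[32] <- "T"   # alt at reference position 99 + 31 = 130
  mols <- c(lapply(0:9 * 3, function(s) call_molecule(
              rep(list(make_copy("chr1", 100 + s, b)), 2), ref300)),
            list(call_molecule(rep(list(make_copy("chr1", 99, bT)), 2),
                               ref300)))
  uniq <- dedup_molecules(mols)
  p <- build_pileup(uniq, ref300)
  site <- p[pos == 130]
  expect_equal(site$depth, 11)      # 10 ref molecules + 1 alt molecule
  expect_equal(site$n_T, 1L)

  # a site covered only by unconfirmed calls has depth 0 (absent)
  single <- call_molecule(list(make_copy("chr1", 280, rep("A", 10))), ref300)
  p2 <- build_pileup(list(single), ref300)
  expect_equal(nrow(p2), 0)

  # conservation: total depth equals total confirmed calls over molecules
  total_conf <- sum(vapply(uniq, function(m)
    sum(m$calls$status != "UNCONFIRMED"), numeric(1)))
  expect_equal(sum(p$depth), total_conf)
})

test_that("consensus output is invariant to record order and survives SAM round trip", {
  ref <- generate_reference(20000, seed = 3)
  fx <- fixture_config(ref, n_molecules = 80, per_copy_error = 1e-3, seed = 11)
  rd <- generate_concatemer_reads(fx)
  cons <- consensus_call(rd$alignments, ref)
  set.seed(42)
  cons_shuf <- consensus_call(rd$alignments[sample(.N)], ref)
  data.table::setindex(cons$pileup, NULL)
  data.table::setindex(cons_shuf$pileup, NULL)
  expect_equal(cons$pileup, cons_shuf$pileup)
  expect_equal(cons$molecule_table, cons_shuf$molecule_table)

  sam <- tempfile(fileext = ".sam")
  write_sam(rd$alignments, ref, sam)
  back <- read_concatemer_alignments(sam)
  expect_equal(nrow(back), nrow(rd$alignments))
  cons_rt <- consensus_call(back, ref)
  data.table::setindex(cons_rt$pileup, NULL)
  expect_equal(cons_rt$pileup, cons$pileup)
})

test_that("independent per-copy errors never survive; template variants always do", {
  ref <- generate_reference(20000, seed = 5)
  # template variants on every covered molecule
  pos <- c(2500L, 7500L, 12500L)
  rb <- substring(ref[["chr1"]], pos + 1, pos + 1)
  tv <- data.frame(chrom = "chr1", pos = pos, ref = rb,
                   alt = ifelse(rb == "A", "T", "A"), vaf = 1)
  fx <- fixture_config(ref, n_molecules = 150, per_copy_error = 2e-3,
                       template_variants = tv, p_high = 1, seed = 23)
  rd <- generate_concatemer_reads(fx)
  cons <- consensus_call(rd$alignments, ref)
  p <- cons$pileup
  alts <- p[n_A + n_C + n_G + n_T > 0]
  # all confirmed alts sit at the template variant positions: per-copy
  # errors at distinct positions are all removed
  expect_true(all(alts$pos %in% pos))
  # signal preservation: every confirmed molecule covering a variant
  # position carries the variant
  for (i in seq_along(pos)) {
    row <- p[pos == tv$pos[i]]
    if (nrow(row) == 1L)
      expect_equal(row[[paste0("n_", tv$alt[i])]], row$depth)
  }
})
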