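test_that("depth-equivalent variant counts follow the 60x scaling", {
  expect_identical(equivalent_variant_count(2000, 30), 4000L)
  expect_identical(equivalent_variant_count(2000, 60), 2000L)
  expect_identical(equivalent_variant_count(10000, 120), 5000L)
  expect_identical(equivalent_variant_count(5000, 45), 6667L)  # rounded
  expect_error(equivalent_variant_count(2000, 0))
})

test_that("Poisson molecule-count model gives the germline/somatic split", {
  m0 <- expected_molecule_pmf(60, 0)
  expect_equal(unname(m0$pmf[["0"]]), 1)
  expect_equal(m0$p_ge2, 0)
  # germline at 50% VAF, 60x: essentially always >= 2 molecules
  mg <- expected_molecule_pmf(60, 0.5)
  expect_equal(1 - mg$p_ge2, exp(-30) * 31, tolerance = 1e-6)
  # somatic at 0.1%, 60x: rarely >= 2 molecules
  ms <- expected_molecule_pmf(60, 1e-3)
  expect_equal(ms$p_ge2, 1 - exp(-0.06) * 1.06, tolerance = 1e-9)
  expect_lt(ms$p_ge2, 2e-3)
})

test_that("tumor variants seen in >= 2 plasma molecules, and CpG C>T, are filtered", {
  tv <- data.table::data.table(
    chrom = "chr1", pos = 1:4,
    ref = c("C", "C", "C", "A"),
    alt = c("A", "A", "T", "G"),
    context = c("ACA", "ACA", "ACG", "CAT"))  # row 3 is CpG C>T
  p <- pileup_row(pos = 1:4, ref = tv$ref, context = tv$context, depth = 60)
  p$n_A[1] <- 2L   # germline-like: removed
  p$n_A[2] <- 1L   # single molecule: retained
  out <- wbc_free_filter(tv, p)
  expect_equal(unname(out$removed["multimolecule"]), 1)
  expect_equal(unname(out$removed["cpg_ct"]), 1)
  expect_equal(nrow(out$markers), 2)
  expect_true(all(out$markers$pos %in% c(2L, 4L)))
  expect_identical(attr(out$markers, "provenance"), "wbc_free")
  expect_error(wbc_free_filter(tv[0], p), "empty")
  # removing nearly everything warns about high tumor fraction
  p2 <- data.table::copy(p); p2$n_A <- 5L; p2$n_G <- 5L; p2$n_T <- 5L
  expect_warning(wbc_free_filter(tv, p2), "high tumor fraction")
})

test_that("germline sites are removed and somatic sites kept at 40-60x", {
  # synthetic plasma: germline at cVAF 50%/100%, somatic at 0.1%
  set.seed(13)
  n <- 2000
  ger <- data.table::data.table(chrom = "chr1", pos = 0:(n - 1), ref = "C",
                                alt = "T", context = "ACA",
                                germline_vaf = sample(c(0.5, 1), n, TRUE))
  som <- data.table::data.table(chrom = "chr1", pos = n:(2 * n - 1),
                                ref = "C", alt = "T", context = "ACA",
                                germline_vaf = NA_real_)
  sites <- rbind(ger, som)
  pile <- generate_plasma_pileup(sites, depth = 50, cvaf = 1e-3,
                                 model = error_model(4.2e-7), seed = 14)
  out <- wbc_free_filter(sites[, -"germline_vaf"], pile)
  kept <- out$markers
  frac_ger_removed <- 1 - sum(kept$pos < n) / n
  frac_som_removed <- 1 - sum(kept$pos >= n) / n
  expect_gte(frac_ger_removed, 0.999)
  expect_lte(frac_som_removed, 0.05)
})

test_that("profile-constrained subsampling meets its quotas exactly", {
  pool <- data.table::data.table(
    chrom = "chr1", pos = 1:6000,
    type = rep(variant_types(), each = 1000))
  unif <- setNames(rep(1 / 6, 6), variant_types())
  set.seed(3)
  s6 <- subsample_markers_profile(pool, 6, unif)
  expect_equal(sort(s6$type), sort(variant_types()))

  # largest-remainder bound: |n_v - n f_v| <= 1 for an uneven profile
  prof <- synthetic_tumor_profile()
  s <- subsample_markers_profile(pool, 997, prof)
  expect_equal(nrow(s), 997)
  tab <- table(factor(s$type, levels = variant_types()))
  expect_true(all(abs(tab - 997 * prof) <= 1))

  # degenerate profile: every marker of the single massed class
  dg <- setNames(c(1, 0, 0, 0, 0, 0), variant_types())
  sd1 <- subsample_markers_profile(pool, 50, dg)
  expect_true(all(sd1$type == "C-T"))

  # repeated draws differ (sampling without replacement inside classes)
  set.seed(4)
  draws <- replicate(25, paste(sort(subsample_markers_profile(
    pool, 100, unif)$pos), collapse = ","))
  expect_equal(length(unique(draws)), 25)

  # shortfall in one class reallocates with a warning
  small <- pool[type != "C-T" | pos <= 10]
  expect_warning(s2 <- subsample_markers_profile(small, 3000, prof),
                 "insufficient")
  expect_equal(nrow(s2), 3000)
})

test_that("titration SNP criteria are applied in order with counted removals", {
  snps <- data.table::data.table(
    chrom = "chr1", pos = 1:10, ref = "C", alt = "A", context = "ACA",
    test_genotype       = c("het", "hom", "het", "het", "het", "het", "het",
                            "het", "het", "het"),
    background_genotype = c("ref", "ref", "het", "ref", "ref", "ref", "ref",
                            "ref", "ref", "ref"),
    background_alt_molecules = c(0, 0, 0, 2, 0, 0, 0, 0, 0, 0),
    depth_min = c(40, 40, 40, 40, 15, 40, 40, 40, 40, 40),
    depth_max = c(60, 60, 60, 60, 60, 150, 60, 60, 60, 60),
    vaf_undiluted = c(0.48, 0.5, 0.5, 0.5, 0.5, 0.5, 0.25, 0.5, 0.5, 0.52),
    in_repeat = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                  FALSE, FALSE),
    n_plasma_detected = c(1, 1, 1, 1, 1, 1, 1, 1, 3, 1))
  out <- titration_snp_filter(snps)
  # hand-tallied fates: rows 2,3,4 genotype; 5,6 depth; 7 vaf; 8 repeat;
  # 9 multi-plasma; rows 1 and 10 survive
  expect_equal(unname(out$removed),
               c(3L, 2L, 1L, 1L, 1L))
  expect_equal(sort(out$markers$pos), c(1L, 10L))
  expect_error(titration_snp_filter(snps[, -"depth_min"]), "missing columns")
})

test_that("mismatched-tumor specificity is near 1 and guards self-variants", {
  set.seed(8)
  prof <- synthetic_tumor_profile()
  ty <- sample(names(prof), 4000, TRUE, prob = prof)
  pool <- concatMRD:::.make_variant_sites(4000, ty)
  pool[, `:=`(chrom = "chr1", pos = seq_len(4000) - 1L)]
  pool <- finalize_marker_set(pool, "mismatched")
  em <- error_model(4.2e-7)
  # error-free plasma: no variant molecule can ever be observed
  pile0 <- generate_plasma_pileup(pool, 60, 0, error_model(0), seed = 9)
  r0 <- mismatched_specificity(list(s1 = pile0), pool, em,
                               levels = 2000, n_reps = 50)
  expect_equal(r0$per_sample$specificity, 1.0)
  expect_equal(r0$per_sample$v_i, 2000L)
  # plasma with background at the modelled rate: specificity ~ 0.99
  pile <- generate_plasma_pileup(pool, 60, 0, em, seed = 10)
  r <- mismatched_specificity(list(s1 = pile), pool, em,
                              levels = 2000, n_reps = 400)
  expect_gte(r$per_sample$specificity, 0.96)
  # a pool containing the patient's own variants is rejected
  expect_error(
    mismatched_specificity(list(s1 = pile), pool, em, levels = 2000,
                           n_reps = 10,
                           patient_variants = list(s1 = pool[1:5])),
    "self-patient")
  # pool smaller than the required draw
  expect_error(
    mismatched_specificity(list(s1 = pile), pool[1:100], em, levels = 2000,
                           n_reps = 10),
    "smaller")
})

test_that("WBC-paired and WBC-free marker sets give identical MRD calls", {
  co <- generate_cohort(6, n_somatic = 1500, n_germline = 800, depth = 60,
                        pre_cvaf = 2e-4, post_cvaf_positive = 1e-3,
                        seed = 100)
  em <- error_model(4.2e-7)
  calls <- data.table::rbindlist(lapply(names(co), function(nm) {
    pt <- co[[nm]]
    paired <- finalize_marker_set(pt$somatic_variants, "wbc_paired")
    free <- wbc_free_filter(pt$tumor_variants, pt$pileup_post)$markers
    do_call <- function(mk, pile) lr_test(
      collect_marker_observations(pile, mk), em, compute_ci = FALSE)
    rp <- do_call(paired, pt$pileup_pre); rf <- do_call(free, pt$pileup_pre)
    qp <- do_call(paired, pt$pileup_post); qf <- do_call(free, pt$pileup_post)
    data.table::data.table(
      patient = nm,
      pre_same = rp$call == rf$call, post_same = qp$call == qf$call,
      pre_paired = rp$cvaf_hat, pre_free = rf$cvaf_hat,
      post_truth = pt$truth$post_positive, post_call = qp$call == "POSITIVE")
  }))
  expect_true(all(calls$pre_same))
  expect_true(all(calls$post_same))
  # cVAF estimates from the two workflows agree tightly on positives
  fit <- summary(lm(pre_free ~ pre_paired, data = calls))
  expect_gt(fit$r.squared, 0.95)
  # truth labels recovered on the post-treatment samples
  expect_equal(calls$post_call, calls$post_truth)
})
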