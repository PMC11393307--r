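test_that("marker observations aggregate counts and depths per class", {
  # 10,000 markers of one class, depth 60, one site with one alt molecule
  mk <- data.table::data.table(chrom = "chr1", pos = 0:9999, ref = "C",
                               alt = "A", context = "ACA")
  p <- pileup_row(pos = 0:9999, ref = "C", context = "ACA", depth = 60)
  p$n_A[5] <- 1L
  obs <- collect_marker_observations(p, mk)
  expect_equal(sum(obs$c_v), 1)
  expect_equal(sum(obs$d_v), 600000)
  expect_equal(obs$c_v[["C-A"]], 1)

  # a 2-molecule site is excluded (count and depth) in low-burden mode
  p$n_A[5] <- 2L
  obs2 <- collect_marker_observations(p, mk)
  expect_equal(sum(obs2$c_v), 0)
  expect_equal(sum(obs2$d_v), 599940)
  expect_equal(obs2$n_excluded_multimolecule, 1)

  # ... but retained with c = 2 in high-burden mode
  obs3 <- collect_marker_observations(p, mk, high_burden_mode = TRUE)
  expect_equal(sum(obs3$c_v), 2)
  expect_equal(sum(obs3$d_v), 600000)
  expect_true(obs3$high_burden_flag)

  # markers absent from the pileup contribute zero depth, silently
  mk2 <- rbind(mk, data.table::data.table(chrom = "chr9", pos = 1L,
                                          ref = "C", alt = "T",
                                          context = "ACA"))
  p$n_A[5] <- 1L
  obs4 <- collect_marker_observations(p, mk2)
  expect_equal(sum(obs4$d_v), 600000)
  expect_error(collect_marker_observations(p, mk[0]), "empty")
})

test_that("log-likelihood matches its closed forms", {
  e <- c("C-T" = 1e-6, "C-G" = 2e-6, "C-A" = 0, "A-T" = 0, "A-G" = 0,
         "A-C" = 0)
  d <- setNames(c(1e5, 2e5, 3e5, 0, 0, 0), variant_types())
  obs <- marker_obs(setNames(rep(0, 6), variant_types()), d)
  em <- error_model(e)
  # all-zero counts at vaf 0: sum d_v log(1 - e_v)
  expect_equal(log_likelihood(obs, em, 0),
               1e5 * log(1 - 1e-6) + 2e5 * log(1 - 2e-6))
  expect_error(log_likelihood(obs, em, -1e-9), "non-negative")
})

test_that("constrained MLE equals the binomial fraction in the single-type case", {
  em0 <- uniform_model(0)
  expect_equal(mle_cvaf(obs1(5, 1000), em0), 0.005, tolerance = 1e-10)
  expect_equal(mle_cvaf(obs1(6, 600000), em0), 1e-5, tolerance = 1e-8)
  # all-zero counts: boundary estimate
  expect_equal(mle_cvaf(obs1(0, 1000), em0), 0)
  # error rate above the observed fraction: clipped to 0
  expect_equal(mle_cvaf(obs1(1, 1e6), uniform_model(2e-6)), 0)
  # no depth at all: undefined
  expect_error(mle_cvaf(marker_obs(numeric(6), numeric(6)), em0),
               "undefined")
})

test_that("MLE and CI agree with a brute-force grid scan", {
  # two classes with different error rates (grid step 1e-9)
  cv <- c(3, 1); dv <- c(1e5, 1e5); ev <- c(1e-6, 1e-7)
  obs <- marker_obs(setNames(c(cv, 0, 0, 0, 0), variant_types()),
                    setNames(c(dv, 0, 0, 0, 0), variant_types()))
  em <- error_model(setNames(c(ev, 0, 0, 0, 0), variant_types()))
  g <- oracle_mle_grid(cv, dv, ev, 0, 1e-4, 1e-9)
  expect_equal(mle_cvaf(obs, em), g, tolerance = 2e-9 / g)

  # single class, c = 5, d = 1000: MLE and both CI bounds vs 1e-8 grid
  obs2 <- obs1(5, 1000)
  em0 <- uniform_model(0)
  expect_lt(abs(mle_cvaf(obs2, em0) -
                oracle_mle_grid(5, 1000, 0, 0.001, 0.02, 1e-8)), 2e-8)
  ci <- confidence_interval(obs2, em0)
  ci_g <- oracle_ci_grid(5, 1000, 0, 0.0005, 0.02, 1e-8)
  expect_lt(abs(ci[1] - ci_g[1]), 5e-8)
  expect_lt(abs(ci[2] - ci_g[2]), 5e-8)
})

test_that("likelihood-ratio decision matches the chi-square quantile rule", {
  em0 <- uniform_model(0)
  # no signal: Lambda = 0, negative
  r0 <- lr_test(obs1(0, 1000), em0)
  expect_equal(r0$lr_statistic, 0)
  expect_equal(r0$call, "NEGATIVE")
  expect_equal(r0$p_value, 1)
  expect_equal(r0$ci_low, 0)
  # one-tailed upper bound, closed form: 1 - exp(-3.841 / (2 d))
  expect_equal(r0$ci_high, 1 - exp(-3.841 / 2000), tolerance = 1e-9)

  # the decision threshold sits at the 0.98 chi-square(1) quantile
  lam_cut <- qchisq(0.98, df = 1)
  e <- 4.2e-7; D <- 6e5
  em <- uniform_model(e)
  lam_of <- function(cc) lr_test(obs1(cc, D), em)$lr_statistic
  # find counts straddling the cutoff and check the calls flip there
  cc <- 1
  while (lam_of(cc) <= lam_cut) cc <- cc + 1
  expect_equal(lr_test(obs1(cc - 1, D), em)$call, "NEGATIVE")
  expect_equal(lr_test(obs1(cc, D), em)$call, "POSITIVE")
  # decision via CDF cutoff equals decision via quantile for a spread of counts
  for (k in 1:8) {
    r <- lr_test(obs1(k, D), em)
    expect_identical(r$call == "POSITIVE", r$lr_statistic > lam_cut)
  }

  # 3 error-free tumor molecules over 10K markers at 60x: positive
  r3 <- lr_test(obs1(3, 6e5), uniform_model(4.2e-7))
  expect_equal(r3$call, "POSITIVE")
  expect_gt(r3$ci_low, 0)   # positive call implies CI excluding 0
})

test_that("vaf_hat and Lambda are monotone in the observed counts", {
  em <- uniform_model(1e-6)
  prev_v <- -1; prev_l <- -1
  for (cc in 0:10) {
    obs <- obs1(cc, 2e5)
    v <- mle_cvaf(obs, em)
    l <- lr_test(obs, em, compute_ci = FALSE)$lr_statistic
    expect_gte(v, prev_v)
    expect_gte(l, prev_l)
    prev_v <- v; prev_l <- l
  }
})

test_that("null calibration: positive rate near 1% and below 2%", {
  # c_v ~ Binomial(d_v, e_v) under the null across 10^4 replicates
  set.seed(2024)
  e <- c("C-T" = 5e-6, "C-G" = 1e-6, "C-A" = 3e-6, "A-T" = 1e-6,
         "A-G" = 2e-6, "A-C" = 1e-6)
  em <- error_model(e)
  d <- setNames(rep(1e5, 6), variant_types())
  n_rep <- 1e4
  pos <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cc <- setNames(rbinom(6, 1e5, e), variant_types())
    r <- lr_test(marker_obs(cc, d), em, compute_ci = FALSE)
    pos[i] <- r$call == "POSITIVE"
  }
  expect_lte(mean(pos), 0.02)
  expect_gt(mean(pos), 0.001)   # not pathologically conservative
})

test_that("cVAF recovery across three orders of magnitude", {
  set.seed(77)
  em <- uniform_model(4.2e-7)
  d_total <- 6e5
  for (vaf in c(1e-5, 1e-4, 1e-3)) {
    est <- replicate(200, {
      cc <- rbinom(1, d_total, vaf + 4.2e-7)
      mle_cvaf(obs1(cc, d_total), em)
    })
    expect_lt(abs(median(est) - vaf) / vaf, 0.20)
  }
})

test_that("MRD result JSON serialisation round-trips the call", {
  r <- lr_test(obs1(4, 6e5), uniform_model(4.2e-7))
  f <- tempfile(fileext = ".json")
  write_mrd_result(r, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$call, r$call)
  expect_equal(x$cvaf_hat, r$cvaf_hat)
  expect_equal(x$lr_statistic, r$lr_statistic)
})
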