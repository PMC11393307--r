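## The MRD likelihood-ratio test.
##
## Variant molecules observed over a tumor-informed marker set are modelled
## per substitution class v as Binomial(d_v, p_v) with p_v = VAF + e_v:
## variant molecules arise either from circulating tumor DNA (probability
## VAF) or from residual background error (probability e_v). The
## circulating VAF is estimated by maximising the binomial log-likelihood
## under the constraint VAF >= 0, and MRD is called by a likelihood-ratio
## test of VAF = 0. Because the null value sits on the boundary of the
## parameter space, the null distribution of the LR statistic is the
## mixture (1/2) delta_0 + (1/2) chi-square(1): rejecting when the
## chi-square(1) CDF at the statistic exceeds 0.98 gives a one-sided
## p-value of 0.01 and a nominal specificity of 99%.

#' Aggregate marker-site observations into the MRD sufficient statistic
#'
#' For each marker the confirmed molecule depth and the variant-molecule
#' count for the marker's alternate allele are collected, then aggregated
#' per collapsed substitution class. In a low-tumor-burden sample a true
#' somatic variant is expected at most once among ~60 molecules, whereas
#' germline or clonal-hematopoiesis variants recur; marker sites carrying
#' `>= multimolecule_cutoff` variant molecules are therefore excluded
#' (count and depth) unless `high_burden_mode` retains them. With
#' `high_burden_mode = "auto"` the exclusion is lifted when more than 10%
#' of covered markers carry `>=` cutoff molecules.
#'
#' @param pileup Pileup `data.table` (see [build_pileup()]).
#' @param markers Marker set: `data.frame` with `chrom`, `pos` (0-based),
#'   `ref`, `alt` (CpG C>T markers should already have been removed, see
#'   [finalize_marker_set()]).
#' @param multimolecule_cutoff Variant-molecule count at which a site is
#'   excluded (default 2).
#' @param high_burden_mode `FALSE` (default), `TRUE`, or `"auto"`.
#' @return A `marker_obs` object: per-type counts `c_v`, depths `d_v`,
#'   `n_excluded_multimolecule`, `n_markers_used`, `n_markers`,
#'   `high_burden_flag`.
#' @export
collect_marker_observations <- function(pileup, markers,
                                        multimolecule_cutoff = 2,
                                        high_burden_mode = FALSE) {
  markers <- as.data.table(markers)
  if (nrow(markers) == 0L) stop("empty marker set")
  pileup <- as.data.table(pileup)
  mk <- copy(markers)
  if (!"type" %in% names(mk)) {
    ctx <- if ("context" %in% names(mk)) mk$context else NA_character_
    mk[, type := classify_substitution(ref, alt, ctx)$type]
  }
  idx <- match(paste(mk$chrom, mk$pos), paste(pileup$chrom, pileup$pos))
  dep <- ifelse(is.na(idx), 0L, pileup$depth[idx])
  cnt <- integer(nrow(mk))
  for (ab in c("A", "C", "G", "T")) {
    j <- which(mk$alt == ab & !is.na(idx))
    cnt[j] <- pileup[[paste0("n_", ab)]][idx[j]]
  }
  multi <- cnt >= multimolecule_cutoff
  frac_multi <- if (any(dep > 0)) sum(multi) / sum(dep > 0) else 0
  high_flag <- isTRUE(high_burden_mode) ||
    (identical(high_burden_mode, "auto") && frac_multi > 0.10)
  keep <- if (high_flag) rep(TRUE, nrow(mk)) else !multi
  tys <- variant_types()
  c_v <- setNames(numeric(6L), tys)
  d_v <- setNames(numeric(6L), tys)
  agg_c <- tapply(cnt[keep], mk$type[keep], sum)
  agg_d <- tapply(dep[keep], mk$type[keep], sum)
  c_v[names(agg_c)] <- agg_c
  d_v[names(agg_d)] <- agg_d
  marker_obs(c_v, d_v, n_excluded_multimolecule = sum(multi & !keep),
             n_markers_used = sum(keep), n_markers = nrow(mk),
             high_burden_flag = high_flag)
}

#' Construct a marker observation (per-type counts and depths)
#'
#' @param c_v,d_v Named numeric vectors over [variant_types()] (or
#'   unnamed length-6 in canonical order): variant-molecule counts and
#'   total confirmed molecule depths per class. `0 <= c_v <= d_v`.
#' @param n_excluded_multimolecule,n_markers_used,n_markers,high_burden_flag
#'   Bookkeeping fields (optional).
#' @return A `marker_obs` object.
#' @export
marker_obs <- function(c_v, d_v, n_excluded_multimolecule = 0L,
                       n_markers_used = NA_integer_,
                       n_markers = NA_integer_, high_burden_flag = FALSE) {
  tys <- variant_types()
  if (is.null(names(c_v))) names(c_v) <- tys[seq_along(c_v)]
  if (is.null(names(d_v))) names(d_v) <- tys[seq_along(d_v)]
  cc <- setNames(numeric(6L), tys); dd <- setNames(numeric(6L), tys)
  cc[names(c_v)] <- c_v; dd[names(d_v)] <- d_v
  if (any(cc < 0) || any(dd < 0) || any(cc > dd))
    stop("require 0 <= c_v <= d_v for every type")
  structure(list(c_v = cc, d_v = dd,
                 n_excluded_multimolecule = n_excluded_multimolecule,
                 n_markers_used = n_markers_used, n_markers = n_markers,
                 high_burden_flag = high_burden_flag),
            class = "marker_obs")
}

.obs_em_vectors <- function(obs, model) {
  e <- model$rates[variant_types()]
  if (any(is.na(e) & obs$d_v > 0))
    stop("error model has undefined rates for types with observed depth")
  keep <- obs$d_v > 0
  list(c = obs$c_v[keep], d = obs$d_v[keep], e = e[keep])
}

## core log-likelihood / MLE on plain (c, d, e) vectors, shared by the
## user-facing functions and the bulk simulator
.ll_core <- function(v, V) {
  p <- V + v$e
  if (any(p >= 1)) return(-Inf)
  sum(ifelse(v$c > 0, v$c * log(p), 0) + (v$d - v$c) * log1p(-p))
}

.mle_core <- function(v, tol = 1e-12) {
  if (length(v$d) == 0L || sum(v$d) == 0)
    stop("no interrogated molecules: cVAF estimate undefined")
  if (sum(v$c) == 0) return(0)
  hi <- 1 - max(v$e) - 1e-12
  zero_e_signal <- any(v$e == 0 & v$c > 0)
  if (!zero_e_signal && .score(v, 0) <= 0) return(0)
  lo <- if (zero_e_signal) 1e-18 else 0
  f <- function(V) .score(v, V)
  if (f(hi) >= 0) return(hi)
  r <- uniroot(f, lower = lo, upper = hi,
               tol = tol * max(sum(v$c) / sum(v$d), tol))
  max(r$root, 0)
}

## LR statistic only (no CI), for bulk simulation
.lambda_core <- function(c_v, d_v, e) {
  keep <- d_v > 0
  v <- list(c = c_v[keep], d = d_v[keep], e = e[keep])
  if (sum(v$c) == 0) return(0)
  vhat <- .mle_core(v)
  ll0 <- .ll_core(v, 0)
  if (is.infinite(ll0)) return(Inf)
  max(0, 2 * (.ll_core(v, vhat) - ll0))
}

#' Binomial log-likelihood of the typed marker observations
#'
#' Computes (up to the additive binomial-coefficient constant)
#' `sum_v [ c_v log(vaf + e_v) + (d_v - c_v) log(1 - vaf - e_v) ]`.
#' Types with zero depth contribute nothing. When `vaf + e_v = 0` with
#' `c_v > 0` the likelihood is `-Inf`.
#'
#' @param obs A `marker_obs` (see [collect_marker_observations()]).
#' @param model An [error_model()].
#' @param vaf Candidate variant allele fraction, `>= 0` (vectorised).
#' @return Log-likelihood value(s).
#' @export
log_likelihood <- function(obs, model, vaf) {
  v <- .obs_em_vectors(obs, model)
  if (any(vaf < 0)) stop("vaf must be non-negative")
  vapply(vaf, function(V) .ll_core(v, V), numeric(1))
}

## Derivative of the log-likelihood in VAF:
## sum_v (c_v - d_v p_v) / (p_v (1 - p_v)); strictly decreasing on the
## feasible interval, so the constrained MLE is found by safeguarded
## root-finding.
.score <- function(obs_v, V) {
  p <- V + obs_v$e
  sum((obs_v$c - obs_v$d * p) / (p * (1 - p)))
}

#' Constrained maximum-likelihood estimate of the circulating VAF
#'
#' Finds the root of the score function on `(0, 1 - max e_v)`; when the
#' score at 0+ is already non-positive the estimate is clipped to 0
#' (the boundary of the constraint `VAF >= 0`).
#'
#' @inheritParams log_likelihood
#' @param tol Relative tolerance of the root (default 1e-12).
#' @return The point estimate `vaf_hat >= 0`.
#' @export
mle_cvaf <- function(obs, model, tol = 1e-12) {
  .mle_core(.obs_em_vectors(obs, model), tol)
}

#' Likelihood-ratio MRD test
#'
#' Tests the boundary null `VAF = 0` (all variant observations are error)
#' against the constrained MLE. The statistic is
#' `Lambda = 2 (logL(vaf_hat) - logL(0))`; the sample is called POSITIVE
#' when the chi-square(1) CDF at `Lambda` exceeds `cdf_cutoff` (default
#' 0.98, i.e. mixture p-value 0.01, 99% nominal specificity). A 95%
#' likelihood-ratio confidence interval is attached: two-tailed for
#' positive samples, one-tailed upper bound (lower bound 0) for negative
#' samples.
#'
#' @inheritParams log_likelihood
#' @param cdf_cutoff Decision cutoff on the chi-square(1) CDF; for nominal
#'   specificity `s` use `1 - 2 (1 - s)`.
#' @param ci_delta Likelihood-ratio CI threshold (default 3.841, the
#'   chi-square(1) 0.95 quantile).
#' @param compute_ci Set to `FALSE` to skip the confidence interval (used
#'   in bulk simulation where only the call is needed).
#' @return An `mrd_result`: `call` ("POSITIVE"/"NEGATIVE"), `cvaf_hat`,
#'   `ci_low`, `ci_high`, `lr_statistic`, `chi2_cdf_value`, `p_value`
#'   (mixture tail), `nominal_specificity`, `high_burden_flag`, `obs`.
#' @export
lr_test <- function(obs, model, cdf_cutoff = 0.98, ci_delta = 3.841,
                    compute_ci = TRUE) {
  stopifnot(cdf_cutoff > 0, cdf_cutoff < 1)
  vhat <- mle_cvaf(obs, model)
  ll1 <- log_likelihood(obs, model, vhat)
  ll0 <- log_likelihood(obs, model, 0)
  lambda <- if (is.infinite(ll0)) Inf else max(0, 2 * (ll1 - ll0))
  cdf <- pchisq(lambda, df = 1)
  positive <- cdf > cdf_cutoff
  pval <- if (lambda > 0) 0.5 * pchisq(lambda, df = 1, lower.tail = FALSE) else 1
  ci <- if (compute_ci) {
    confidence_interval(obs, model, delta = ci_delta, vaf_hat = vhat,
                        positive = positive)
  } else c(NA_real_, NA_real_)
  structure(list(call = if (positive) "POSITIVE" else "NEGATIVE",
                 cvaf_hat = vhat, ci_low = ci[1], ci_high = ci[2],
                 lr_statistic = lambda, chi2_cdf_value = cdf,
                 p_value = pval,
                 nominal_specificity = 1 - (1 - cdf_cutoff) / 2,
                 high_burden_flag = isTRUE(obs$high_burden_flag),
                 obs = obs),
            class = "mrd_result")
}

#' @exportS3Method base::print
print.mrd_result <- function(x, ...) {
  cat(sprintf("MRD %s: cVAF = %.3g [%.3g, %.3g], Lambda = %.3f, p = %.4g\n",
              x$call, x$cvaf_hat, x$ci_low, x$ci_high, x$lr_statistic,
              x$p_value))
  invisible(x)
}

#' Likelihood-ratio confidence interval for the circulating VAF
#'
#' Bounds are the non-negative VAF values at which twice the log-likelihood
#' drop from the maximum equals `delta` (default 3.841, the chi-square(1)
#' 0.95 quantile), found by monotone root-finding on each side of the MLE
#' and intersected with `[0, 1 - max e_v)`. For a negative call the lower
#' bound is reported as 0 (one-tailed upper bound).
#'
#' @inheritParams log_likelihood
#' @param delta Log-likelihood-ratio threshold (`> 0`).
#' @param vaf_hat Optional precomputed MLE.
#' @param positive Optional logical: is the sample called positive? When
#'   `NULL` it is derived from the default 0.98 CDF cutoff.
#' @return `c(ci_low, ci_high)`.
#' @export
confidence_interval <- function(obs, model, delta = 3.841, vaf_hat = NULL,
                                positive = NULL) {
  stopifnot(delta > 0)
  v <- .obs_em_vectors(obs, model)
  if (is.null(vaf_hat)) vaf_hat <- mle_cvaf(obs, model)
  ll_max <- log_likelihood(obs, model, vaf_hat)
  hi <- 1 - max(v$e) - 1e-12
  drop2 <- function(V) 2 * (ll_max - log_likelihood(obs, model, V)) - delta
  if (is.null(positive)) {
    ll0 <- log_likelihood(obs, model, 0)
    lam <- if (is.infinite(ll0)) Inf else max(0, 2 * (ll_max - ll0))
    positive <- pchisq(lam, df = 1) > 0.98
  }
  ## upper bound: drop2 increases monotonically above the MLE
  upper <- if (drop2(hi) <= 0) hi else
    uniroot(drop2, lower = vaf_hat, upper = hi, tol = 1e-15)$root
  ## lower bound
  lower <- 0
  if (positive && vaf_hat > 0) {
    at0 <- drop2(0)
    lower <- if (at0 <= 0) 0 else {
      lo_start <- if (any(v$e == 0 & v$c > 0)) vaf_hat * 1e-12 else 0
      uniroot(drop2, lower = lo_start, upper = vaf_hat, tol = 1e-15)$root
    }
  }
  c(lower, upper)
}
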