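# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own likelihood/MLE code paths: everything here is
# direct vector arithmetic on the binomial log-likelihood and brute-force
# grid scans.

# log-likelihood written out directly (not via the package)
oracle_ll <- function(cv, dv, ev, V) {
  p <- V + ev
  sum(ifelse(cv > 0, cv * log(p), 0) + (dv - cv) * log(1 - p))
}

# grid-scan MLE: argmax of the log-likelihood on [lo, hi] at `step`
oracle_mle_grid <- function(cv, dv, ev, lo, hi, step) {
  V <- seq(lo, hi, by = step)
  ll <- vapply(V, function(x) oracle_ll(cv, dv, ev, x), numeric(1))
  V[which.max(ll)]
}

# grid-scan likelihood-ratio CI: V with 2*(llmax - ll(V)) <= delta
oracle_ci_grid <- function(cv, dv, ev, lo, hi, step, delta = 3.841) {
  V <- seq(lo, hi, by = step)
  ll <- vapply(V, function(x) oracle_ll(cv, dv, ev, x), numeric(1))
  ok <- 2 * (max(ll) - ll) <= delta
  range(V[ok])
}

# semi-analytic detection approximation for a uniform error rate:
# smallest total count whose LR statistic clears the chi-square cutoff,
# then the Poisson tail at the expected total count
oracle_detection_poisson <- function(n_markers, depth, vaf, e,
                                     cdf_cutoff = 0.98) {
  D <- n_markers * depth
  lam_cut <- qchisq(cdf_cutoff, df = 1)
  lr_of <- function(cc) {
    vhat <- max(cc / D - e, 0)
    2 * (oracle_ll(cc, D, e, vhat) - oracle_ll(cc, D, e, 0))
  }
  cstar <- 1
  while (lr_of(cstar) <= lam_cut) cstar <- cstar + 1
  ppois(cstar - 1, D * (vaf + e), lower.tail = FALSE)
}

# a uniform-rate error model shared by many tests
uniform_model <- function(e) error_model(e)

# one-type observation helper
obs1 <- function(c, d, type = "C-T") {
  marker_obs(setNames(c, type), setNames(d, type))
}
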