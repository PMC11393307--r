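## Monte-Carlo engine for detection rate, null specificity and limit of
## detection of the MRD likelihood-ratio test.
##
## Each replicate draws, per marker site, a molecule depth (fixed or
## Poisson) and a variant-molecule count that is the sum of two binomials —
## one with the circulating VAF as success probability (tumor signal) and
## one with the substitution-class error rate (background) — truncated at
## the depth. Replicates are aggregated with the same multi-molecule
## exclusion as the real caller and passed through the likelihood-ratio
## test. For the tiny success probabilities of interest the engine uses an
## exact sparse equivalent: the total number of successes over a block of
## site-depth trials is binomial, and the successful trials are a uniform
## draw without replacement, so only the (few) variant molecules are ever
## materialised.

#' Simulation configuration
#'
#' @param n_markers Number of marker sites (e.g. 2000, 5000, 10000, 20000).
#' @param depth Expected confirmed molecule depth per site (10-100 in the
#'   regimes of interest).
#' @param vaf True circulating variant allele fraction (0 for null runs).
#' @param error_rates Background error rate: scalar applied to all classes
#'   or named vector over [variant_types()], or an [error_model()].
#' @param n_reps Number of Monte-Carlo replicates (default 10000).
#' @param seed Optional RNG seed applied at the start of each simulation
#'   call for reproducibility.
#' @param nominal_specificity Nominal specificity of the caller (default
#'   0.99; the chi-square CDF cutoff is `1 - 2 (1 - s)`).
#' @param type_profile Fractions of markers per substitution class (named
#'   over [variant_types()], summing to 1); default uniform.
#' @param depth_law `"fixed"` (every site at `depth`) or `"poisson"`
#'   (site depths drawn Poisson with mean `depth`).
#' @param multimolecule_cutoff Sites with this many variant molecules are
#'   excluded from the call, as in [collect_marker_observations()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_markers, depth, vaf, error_rates,
                       n_reps = 10000, seed = NULL,
                       nominal_specificity = 0.99,
                       type_profile = NULL,
                       depth_law = c("fixed", "poisson"),
                       multimolecule_cutoff = 2) {
  depth_law <- match.arg(depth_law)
  if (methods::is(error_rates, "error_model")) error_rates <- error_rates$rates
  if (length(error_rates) == 1L && is.null(names(error_rates)))
    error_rates <- setNames(rep(as.numeric(error_rates), 6L), variant_types())
  stopifnot(all(variant_types() %in% names(error_rates)))
  if (is.null(type_profile))
    type_profile <- setNames(rep(1 / 6, 6L), variant_types())
  stopifnot(abs(sum(type_profile) - 1) < 1e-8, all(type_profile >= 0),
            n_reps >= 1, vaf >= 0, depth > 0, n_markers >= 1)
  structure(list(n_markers = as.integer(n_markers), depth = depth,
                 vaf = vaf, error_rates = error_rates[variant_types()],
                 n_reps = as.integer(n_reps), seed = seed,
                 nominal_specificity = nominal_specificity,
                 type_profile = type_profile[variant_types()],
                 depth_law = depth_law,
                 multimolecule_cutoff = multimolecule_cutoff),
            class = "sim_config")
}

## integer quotas n * frac by largest remainder; sums exactly to n
.largest_remainder <- function(n, frac) {
  raw <- n * frac / sum(frac)
  fl <- floor(raw)
  short <- n - sum(fl)
  if (short > 0) {
    add <- order(raw - fl, decreasing = TRUE)[seq_len(short)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

.sites_per_type <- function(config) {
  setNames(.largest_remainder(config$n_markers, config$type_profile),
           variant_types())
}

#' Simulate the marker observations of a single replicate
#'
#' Draws per-site depths and variant-molecule counts under the two-binomial
#' observation model and aggregates them per class with the multi-molecule
#' exclusion. Uses the current RNG state (set `config$seed` upstream or via
#' [detection_rate()] for reproducibility).
#'
#' @param config A [sim_config()].
#' @return A `marker_obs` (see [marker_obs()]).
#' @export
simulate_marker_counts <- function(config) {
  nt <- .sites_per_type(config)
  tys <- variant_types()
  c_v <- setNames(numeric(6L), tys)
  d_v <- setNames(numeric(6L), tys)
  n_excl <- 0L
  for (v in tys) {
    n <- nt[[v]]
    if (n == 0L) next
    d <- if (config$depth_law == "fixed") rep(config$depth, n)
         else rpois(n, config$depth)
    cc <- pmin(rbinom(n, d, config$vaf) + rbinom(n, d, config$error_rates[[v]]), d)
    multi <- cc >= config$multimolecule_cutoff
    n_excl <- n_excl + sum(multi)
    c_v[v] <- sum(cc[!multi])
    d_v[v] <- sum(d[!multi])
  }
  marker_obs(c_v, d_v, n_excluded_multimolecule = n_excl,
             n_markers_used = config$n_markers - n_excl,
             n_markers = config$n_markers)
}

## Run all replicates, returning the logical positive-call vector.
## Sparse exact path for small success probabilities under the fixed depth
## law; dense per-site sampling otherwise.
.sim_calls <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cutoff_cdf <- 1 - 2 * (1 - config$nominal_specificity)
  nt <- .sites_per_type(config)
  e_type <- config$error_rates
  tys <- variant_types()
  use_sparse <- config$depth_law == "fixed" && config$vaf < 0.01 &&
    all(e_type < 0.01)
  n <- config$n_markers
  depth <- config$depth
  mm <- config$multimolecule_cutoff
  ## site -> type layout (sites 1..n grouped by type)
  type_of_site <- rep.int(seq_along(tys), nt)
  site_offset <- c(0L, cumsum(nt))
  base_d <- nt * depth  # per-type depth totals before exclusion
  positive <- logical(config$n_reps)
  e_vec <- unname(e_type)
  lambda_cut <- qchisq(cutoff_cdf, df = 1)

  chunk <- max(1L, min(config$n_reps, as.integer(5e6 / max(n, 1))))
  done <- 0L
  while (done < config$n_reps) {
    k <- min(chunk, config$n_reps - done)
    if (use_sparse) {
      ev <- vector("list", 12L); nev <- 0L
      for (ti in seq_along(tys)) {
        if (nt[ti] == 0L) next
        Nt <- as.numeric(nt[ti]) * depth          # trials per rep, this type
        Ntot <- Nt * k
        for (p in c(config$vaf, e_type[[ti]])) {
          if (p <= 0) next
          S <- rbinom(1L, Ntot, p)
          if (S == 0L) next
          idx <- sample(Ntot, S) - 1
          nev <- nev + 1L
          ev[[nev]] <- data.table(
            rep_id = as.integer(idx %/% Nt) + 1L,
            site = site_offset[ti] + as.integer((idx %% Nt) %/% depth) + 1L)
        }
      }
      if (nev == 0L) { done <- done + k; next }
      events <- rbindlist(ev[seq_len(nev)])
      counts <- events[, .(count = .N), by = .(rep_id, site)]
      counts[, count := pmin(count, depth)]
      counts[, type := type_of_site[site]]
      for (cr in split(counts, by = "rep_id")) {
        r <- cr$rep_id[1]
        excl <- cr$count >= mm
        d_v <- unname(base_d)
        if (any(excl)) {
          sub <- tapply(rep(depth, sum(excl)), cr$type[excl], sum)
          ii <- as.integer(names(sub))
          d_v[ii] <- d_v[ii] - sub
        }
        c_v <- numeric(6L)
        if (any(!excl)) {
          ag <- tapply(cr$count[!excl], cr$type[!excl], sum)
          c_v[as.integer(names(ag))] <- ag
        }
        if (sum(c_v) > 0)
          positive[done + r] <- .lambda_core(c_v, d_v, e_vec) > lambda_cut
      }
    } else {
      e_site <- e_type[type_of_site]
      d <- if (config$depth_law == "fixed") rep(depth, n * k)
           else rpois(n * k, depth)
      cc <- pmin(rbinom(n * k, d, config$vaf) +
                 rbinom(n * k, d, rep(e_site, k)), d)
      ty <- rep(type_of_site, k)
      excl <- cc >= mm
      for (r in seq_len(k)) {
        rows <- (r - 1L) * n + seq_len(n)
        kk <- rows[!excl[rows]]
        c_v <- numeric(6L); d_v <- numeric(6L)
        agc <- tapply(cc[kk], ty[kk], sum); agd <- tapply(d[kk], ty[kk], sum)
        c_v[as.integer(names(agc))] <- agc
        d_v[as.integer(names(agd))] <- agd
        positive[done + r] <- sum(c_v) > 0 &&
          .lambda_core(c_v, d_v, e_vec) > lambda_cut
      }
    }
    done <- done + k
  }
  positive
}

#' Monte-Carlo detection rate
#'
#' Fraction of replicates called MRD positive at the configured nominal
#' specificity, with its binomial standard error.
#'
#' @param config A [sim_config()].
#' @return A list: `detection_rate`, `se`, `n_positive`, `n_reps`.
#' @export
detection_rate <- function(config) {
  pos <- .sim_calls(config)
  p <- mean(pos)
  list(detection_rate = p, se = sqrt(p * (1 - p) / length(pos)),
       n_positive = sum(pos), n_reps = length(pos))
}

#' Simulated specificity under the null (cVAF = 0)
#'
#' @param config A [sim_config()] with `vaf = 0`.
#' @return A list: `specificity`, `se`, `n_negative`, `n_reps`.
#' @export
specificity_at_null <- function(config) {
  if (config$vaf != 0) stop("specificity_at_null() requires vaf = 0")
  pos <- .sim_calls(config)
  p <- mean(!pos)
  list(specificity = p, se = sqrt(p * (1 - p) / length(pos)),
       n_negative = sum(!pos), n_reps = length(pos))
}

#' Limit of detection by grid search over cVAF
#'
#' Detection rate is monotone in the cVAF under the observation model, so
#' the LOD at `target_prob` is the smallest grid value whose simulated
#' detection rate reaches the target.
#'
#' @param config A [sim_config()] (its `vaf` is ignored).
#' @param target_prob Target detection probability (default 0.95, "LOD95").
#' @param vaf_grid Ascending cVAF grid to scan.
#' @return The smallest grid cVAF with detection `>= target_prob`, or `NA`
#'   (with a warning) if the target is not reached on the grid. The
#'   detection rates scanned are attached as attribute `"scan"`.
#' @export
find_lod <- function(config, target_prob = 0.95,
                     vaf_grid = c(1e-6, 2e-6, 5e-6, 1e-5, 2e-5, 5e-5,
                                  1e-4, 2e-4, 5e-4, 1e-3)) {
  vaf_grid <- sort(vaf_grid)
  rates <- numeric(0)
  for (i in seq_along(vaf_grid)) {
    cfg <- config
    cfg$vaf <- vaf_grid[i]
    if (!is.null(config$seed)) cfg$seed <- config$seed + i
    rates[i] <- detection_rate(cfg)$detection_rate
    if (rates[i] >= target_prob) {
      out <- vaf_grid[i]
      attr(out, "scan") <- data.table(vaf = vaf_grid[seq_len(i)],
                                      detection_rate = rates)
      return(out)
    }
  }
  warning("target detection probability not reached on the cVAF grid")
  out <- NA_real_
  attr(out, "scan") <- data.table(vaf = vaf_grid, detection_rate = rates)
  out
}

#' Detection/specificity surface over a lattice of conditions
#'
#' Runs [detection_rate()] for every combination of the supplied marker
#' counts, depths, cVAFs and error rates; suitable for regenerating
#' power-curve figures.
#'
#' @param n_markers,depths,vafs,error_rates Vectors of conditions.
#' @param n_reps,seed,... Passed to [sim_config()].
#' @return A `data.table` with one row per condition: `n_markers`, `depth`,
#'   `vaf`, `error_rate`, `detection_rate`, `se`, `n_reps`.
#' @export
simulate_grid <- function(n_markers, depths, vafs, error_rates,
                          n_reps = 10000, seed = NULL, ...) {
  grid <- data.table(expand.grid(n_markers = n_markers, depth = depths,
                                 vaf = vafs, error_rate = error_rates))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(grid$n_markers[i], grid$depth[i], grid$vaf[i],
                      grid$error_rate[i], n_reps = n_reps,
                      seed = if (is.null(seed)) NULL else seed + i, ...)
    r <- detection_rate(cfg)
    out[[i]] <- data.table(grid[i], detection_rate = r$detection_rate,
                           se = r$se, n_reps = r$n_reps)
  }
  rbindlist(out)
}
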