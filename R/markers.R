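## Tumor-informed marker handling: white-blood-cell-free tumor-specific
## variant filtering, the Poisson molecule-count model behind it,
## profile-constrained subsampling, titration SNP selection, and the
## mismatched-tumor specificity procedure.

#' Construct and finalise a marker set
#'
#' A marker set is a table of tracked substitutions with their collapsed
#' class. Finalisation removes duplicates and CpG C>T entries (their
#' deamination background would inflate the MRD signal).
#'
#' @param variants `data.frame` with `chrom`, `pos` (0-based), `ref`,
#'   `alt`, optionally `context`.
#' @param provenance One of `"wbc_paired"`, `"wbc_free"`, `"titration"`,
#'   `"mismatched"` or any free-text tag.
#' @return A `data.table` with class column `type`, `cpg_ct` flag and a
#'   `"provenance"` attribute; CpG C>T rows and duplicates removed.
#' @export
finalize_marker_set <- function(variants, provenance = "wbc_paired") {
  mk <- as.data.table(variants)
  if (nrow(mk) == 0L) stop("empty marker set")
  ctx <- if ("context" %in% names(mk)) mk$context else NA_character_
  cls <- classify_substitution(mk$ref, mk$alt, ctx)
  mk[, `:=`(type = cls$type, cpg_ct = cls$cpg_ct)]
  mk <- mk[!(cpg_ct)]
  mk <- unique(mk, by = c("chrom", "pos", "ref", "alt"))
  setattr(mk, "provenance", provenance)
  mk[]
}

#' White-blood-cell-free tumor-specific marker filter
#'
#' Pairs the tumor variant list with a post-treatment (presumed
#' low-tumor-burden) plasma pileup instead of sequenced white blood cells.
#' At 40-60x molecule depth a germline variant (cVAF 50% or 100%) is
#' essentially always seen in >= 2 unique cfDNA molecules, while a residual
#' somatic variant (cVAF < 0.1%) almost never is (see
#' [expected_molecule_pmf()]); tumor variants observed with
#' `>= max_molecules` plasma molecules are therefore removed as
#' germline/CHIP proxies. CpG C>T variants are removed as well.
#'
#' @param tumor_variants Tumor variant list (`chrom`, `pos` 0-based, `ref`,
#'   `alt`, optional `context`).
#' @param plasma_pileup Post-treatment plasma pileup (see [build_pileup()]).
#' @param max_molecules Plasma molecule count at which a tumor variant is
#'   removed (default 2).
#' @return A list: `markers` (finalised marker set, provenance
#'   `"wbc_free"`), `removed` (named counts by reason: `multimolecule`,
#'   `cpg_ct`, `duplicate`). Warns when > 95% of tumor variants are
#'   removed, which suggests a high-tumor-fraction plasma rather than a
#'   clean post-treatment sample.
#' @export
wbc_free_filter <- function(tumor_variants, plasma_pileup, max_molecules = 2) {
  tv <- as.data.table(tumor_variants)
  if (nrow(tv) == 0L) stop("empty tumor variant list")
  n0 <- nrow(tv)
  tv <- unique(tv, by = c("chrom", "pos", "ref", "alt"))
  n_dup <- n0 - nrow(tv)
  pileup <- as.data.table(plasma_pileup)
  idx <- match(paste(tv$chrom, tv$pos), paste(pileup$chrom, pileup$pos))
  cnt <- integer(nrow(tv))
  for (ab in c("A", "C", "G", "T")) {
    j <- which(tv$alt == ab & !is.na(idx))
    cnt[j] <- pileup[[paste0("n_", ab)]][idx[j]]
  }
  multi <- cnt >= max_molecules
  ctx <- if ("context" %in% names(tv)) tv$context else NA_character_
  cls <- classify_substitution(tv$ref, tv$alt, ctx)
  cpg <- cls$cpg_ct & !multi   # count each removal once, multimolecule first
  keep <- !multi & !cpg
  if (sum(!keep) + n_dup > 0.95 * n0) {
    warning("more than 95% of tumor variants removed: plasma sample may ",
            "have a high tumor fraction (few or no tumor-specific markers left)")
  }
  mk <- if (any(keep)) finalize_marker_set(tv[keep], provenance = "wbc_free")
        else setattr(tv[keep], "provenance", "wbc_free")
  list(markers = mk,
       removed = c(multimolecule = sum(multi), cpg_ct = sum(cpg),
                   duplicate = n_dup))
}

#' Poisson model of variant-molecule counts at a marker site
#'
#' The number of variant molecules observed at a site with molecule depth
#' `d` and circulating VAF `f` is modelled Poisson with mean `d * f`. The
#' probability of seeing 2 or more molecules is the discriminator between
#' germline variants (cVAF 0.5 or 1: nearly always >= 2) and residual
#' somatic variants (cVAF < 0.1%: almost never), which underpins
#' [wbc_free_filter()].
#'
#' @param depth Molecule depth (`> 0`).
#' @param cvaf Circulating variant allele fraction in `[0, 1]`.
#' @param max_count Largest count tabulated in the returned pmf.
#' @return A list: `lambda`, `pmf` (named vector over counts
#'   `0..max_count`), `p_ge2` = P(count >= 2).
#' @export
#' @examples
#' expected_molecule_pmf(60, 1e-3)$p_ge2   # ~1.7e-3: somatic site survives
#' expected_molecule_pmf(60, 0.5)$p_ge2    # ~1: germline site removed
expected_molecule_pmf <- function(depth, cvaf, max_count = 10) {
  stopifnot(depth > 0, cvaf >= 0, cvaf <= 1)
  lambda <- depth * cvaf
  counts <- 0:max_count
  list(lambda = lambda,
       pmf = setNames(dpois(counts, lambda), counts),
       p_ge2 = ppois(1, lambda, lower.tail = FALSE))
}

#' Subsample markers constrained to a substitution-type profile
#'
#' Draws exactly `n` markers whose class composition follows the given
#' profile (e.g. the substitution-type profile of a typical colorectal
#' tumor): per-class quotas are the largest-remainder rounding of
#' `n * fraction_v`, filled by uniform sampling without replacement within
#' class. Uses the current RNG state.
#'
#' @param pool Marker set to draw from (needs a `type` column, see
#'   [finalize_marker_set()]).
#' @param n Number of markers to draw.
#' @param profile Named fractions over [variant_types()] summing to 1.
#' @return A marker `data.table` of exactly `n` rows. If a class pool is
#'   too small its shortfall is reallocated proportionally to the other
#'   classes, with a warning.
#' @export
subsample_markers_profile <- function(pool, n, profile) {
  pool <- as.data.table(pool)
  if (!"type" %in% names(pool)) stop("pool needs a 'type' column")
  stopifnot(abs(sum(profile) - 1) < 1e-8, all(profile >= 0))
  tys <- variant_types()
  profile <- profile[tys]
  avail <- setNames(numeric(6L), tys)
  tb <- table(pool$type)
  avail[names(tb)] <- tb
  quota <- setNames(.largest_remainder(n, profile), tys)
  if (any(quota > avail)) {
    warning("insufficient pool for type(s) ",
            paste(tys[quota > avail], collapse = ", "),
            "; reallocating proportionally")
    fixed <- pmin(quota, avail)
    shortfall <- n - sum(fixed)
    while (shortfall > 0) {
      room <- avail - fixed
      open <- room > 0
      if (!any(open)) stop("pool smaller than requested subsample")
      extra <- .largest_remainder(shortfall, ifelse(open, profile + 1e-12, 0))
      fixed <- pmin(fixed + extra, avail)
      shortfall <- n - sum(fixed)
    }
    quota <- fixed
  }
  picks <- lapply(tys, function(v) {
    if (quota[[v]] == 0L) return(NULL)
    rows <- which(pool$type == v)
    pool[rows[sample.int(length(rows), quota[[v]])]]
  })
  out <- rbindlist(picks)
  setattr(out, "provenance", attr(pool, "provenance", exact = TRUE))
  out[]
}

## draw row indices following a type profile (largest-remainder quotas)
.profile_draw_idx <- function(types, n, profile) {
  tys <- variant_types()
  quota <- setNames(.largest_remainder(n, profile[tys]), tys)
  unlist(lapply(tys, function(v) {
    if (quota[[v]] == 0L) return(integer(0))
    rows <- which(types == v)
    rows[sample.int(length(rows), quota[[v]])]
  }), use.names = FALSE)
}

#' Select heterozygous SNPs for a titration (spike-in) experiment
#'
#' Applies, in order, the five selection criteria for tracking a "test"
#' individual's germline SNPs diluted into a "background" individual's
#' cfDNA: (1) heterozygous in the test individual and absent in the
#' background (hom-ref genotype and zero background alt molecules);
#' (2) sequencing depth within `depth_range` at the site for all
#' individuals; (3) observed VAF in the undiluted test sample within
#' `vaf_range`; (4) not in a repeat region and not a CpG C>T;
#' (5) not present in multiple plasma samples.
#'
#' @param snps Candidate table with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `test_genotype` (`"het"`, `"hom"`, `"ref"`),
#'   `background_genotype`, `background_alt_molecules`, `depth_min`,
#'   `depth_max` (min/max depth across individuals at the site),
#'   `vaf_undiluted`, `in_repeat` (logical), optional `context`, and
#'   `n_plasma_detected` (number of plasma samples where the SNP was seen).
#' @param depth_range Inclusive depth window (default `c(20, 100)`).
#' @param vaf_range Inclusive undiluted-VAF window (default `c(0.4, 0.6)`).
#' @param max_plasma_detected Maximum number of plasma samples a SNP may
#'   appear in (default 1).
#' @return A list: `markers` (surviving SNPs, provenance `"titration"`)
#'   and `removed` (named per-criterion removal counts, applied in order).
#' @export
titration_snp_filter <- function(snps, depth_range = c(20, 100),
                                 vaf_range = c(0.4, 0.6),
                                 max_plasma_detected = 1) {
  s <- as.data.table(snps)
  need <- c("chrom", "pos", "ref", "alt", "test_genotype",
            "background_genotype", "background_alt_molecules",
            "depth_min", "depth_max", "vaf_undiluted", "in_repeat",
            "n_plasma_detected")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("missing columns required for the selection criteria: ",
         paste(miss, collapse = ", "))
  removed <- c(genotype = 0L, depth = 0L, vaf = 0L, repeat_or_cpg = 0L,
               multi_plasma = 0L)
  ok1 <- s$test_genotype == "het" & s$background_genotype == "ref" &
    s$background_alt_molecules == 0
  removed["genotype"] <- sum(!ok1); s <- s[ok1]
  ok2 <- s$depth_min >= depth_range[1] & s$depth_max <= depth_range[2]
  removed["depth"] <- sum(!ok2); s <- s[ok2]
  ok3 <- s$vaf_undiluted >= vaf_range[1] & s$vaf_undiluted <= vaf_range[2]
  removed["vaf"] <- sum(!ok3); s <- s[ok3]
  ctx <- if ("context" %in% names(s)) s$context else NA_character_
  cpg <- if (nrow(s)) classify_substitution(s$ref, s$alt, ctx)$cpg_ct else logical(0)
  ok4 <- !s$in_repeat & !cpg
  removed["repeat_or_cpg"] <- sum(!ok4); s <- s[ok4]
  ok5 <- s$n_plasma_detected <= max_plasma_detected
  removed["multi_plasma"] <- sum(!ok5); s <- s[ok5]
  mk <- if (nrow(s)) finalize_marker_set(s, provenance = "titration") else s
  list(markers = mk, removed = removed)
}

#' Depth-equivalent variant count
#'
#' To compare MRD tests across plasma samples sequenced to different
#' molecule depths, the number of sampled variants is scaled so that the
#' expected total molecule count matches tracking `n` variants at the
#' reference depth of 60x: `v_i = (60 / plasma_depth) * n`, rounded to the
#' nearest integer.
#'
#' @param n Target variant count at 60x (e.g. 2000, 5000, 10000, 20000).
#' @param plasma_depth Mean confirmed molecule depth of the plasma sample.
#' @return Integer `v_i`.
#' @export
#' @examples
#' equivalent_variant_count(2000, 30)   # 4000
equivalent_variant_count <- function(n, plasma_depth) {
  stopifnot(plasma_depth > 0)
  as.integer(round(60 / plasma_depth * n))
}

#' Specificity against mismatched tumor variants
#'
#' Estimates the false-positive behaviour of the MRD caller by testing
#' plasma samples with tumor variants from *other* patients: for each
#' plasma sample and each equivalent variant count level `n`, draws
#' `v_i = (60 / depth) * n` variants from the mismatched pool `n_reps`
#' times, runs the likelihood-ratio test, and reports
#' `specificity = 1 - FP / n_reps`.
#'
#' @param plasma_pileups Named list of plasma pileups.
#' @param pool Marker pool of mismatched tumor variants (finalised; must
#'   not contain any variant of the tested patients, see `patient_variants`).
#' @param error_models An [error_model()] shared by all plasmas, or a named
#'   list parallel to `plasma_pileups`.
#' @param levels Equivalent variant count levels (default
#'   `c(2000, 5000, 10000, 20000)`).
#' @param n_reps Random samplings per plasma and level (default 2000).
#' @param plasma_depths Optional named mean depths; defaults to the mean
#'   pileup depth of each sample.
#' @param patient_variants Optional named list of each plasma's own
#'   patient variants; any overlap with `pool` is an error (self-variants
#'   must be excluded from a mismatched pool).
#' @param type_profile Optional profile for [subsample_markers_profile()];
#'   default draws uniformly from the pool.
#' @return A list: `per_sample` (`data.table`: plasma, level, v_i,
#'   n_false_positive, specificity) and `per_level` (mean specificity per
#'   level).
#' @export
mismatched_specificity <- function(plasma_pileups, pool, error_models,
                                   levels = c(2000, 5000, 10000, 20000),
                                   n_reps = 2000, plasma_depths = NULL,
                                   patient_variants = NULL,
                                   type_profile = NULL) {
  pool <- as.data.table(pool)
  if (!is.null(patient_variants)) {
    for (nm in names(plasma_pileups)) {
      own <- patient_variants[[nm]]
      if (is.null(own)) next
      overlap <- merge(pool, as.data.table(own),
                       by = c("chrom", "pos", "ref", "alt"))
      if (nrow(overlap) > 0L)
        stop("pool contains variants of patient '", nm,
             "'; self-patient variants must be excluded")
    }
  }
  single_model <- methods::is(error_models, "error_model")
  rows <- list()
  for (nm in names(plasma_pileups)) {
    pile <- as.data.table(plasma_pileups[[nm]])
    dp <- if (!is.null(plasma_depths)) plasma_depths[[nm]] else mean(pile$depth)
    em <- if (single_model) error_models else error_models[[nm]]
    ## per-pool-variant plasma observations, computed once per plasma
    idx <- match(paste(pool$chrom, pool$pos), paste(pile$chrom, pile$pos))
    dep_all <- ifelse(is.na(idx), 0L, pile$depth[idx])
    cnt_all <- integer(nrow(pool))
    for (ab in c("A", "C", "G", "T")) {
      j <- which(pool$alt == ab & !is.na(idx))
      cnt_all[j] <- pile[[paste0("n_", ab)]][idx[j]]
    }
    ty_all <- if ("type" %in% names(pool)) pool$type else
      classify_substitution(pool$ref, pool$alt)$type
    tys <- variant_types()
    for (n in levels) {
      v_i <- equivalent_variant_count(n, dp)
      if (v_i > nrow(pool))
        stop("pool (", nrow(pool), ") smaller than required draw v_i = ", v_i)
      fp <- 0L
      for (r in seq_len(n_reps)) {
        take <- if (is.null(type_profile)) sample.int(nrow(pool), v_i) else
          .profile_draw_idx(ty_all, v_i, type_profile)
        keep <- take[cnt_all[take] < 2L]   # multimolecule exclusion
        c_v <- setNames(numeric(6L), tys); d_v <- setNames(numeric(6L), tys)
        agc <- tapply(cnt_all[keep], ty_all[keep], sum)
        agd <- tapply(dep_all[keep], ty_all[keep], sum)
        c_v[names(agc)] <- agc; d_v[names(agd)] <- agd
        res <- lr_test(marker_obs(c_v, d_v), em, compute_ci = FALSE)
        if (res$call == "POSITIVE") fp <- fp + 1L
      }
      rows[[length(rows) + 1L]] <-
        data.table(plasma = nm, level = n, v_i = v_i,
                   n_false_positive = fp, specificity = 1 - fp / n_reps)
    }
  }
  per_sample <- rbindlist(rows)
  per_level <- per_sample[, .(mean_specificity = mean(specificity)),
                          by = level]
  list(per_sample = per_sample, per_level = per_level)
}
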