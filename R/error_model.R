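## Per-substitution-type background error rates from a molecule pileup.
##
## After consensus correction the residual background is summarised as six
## rates e_v, one per collapsed substitution class: the number of variant
## molecules observed divided by the number of molecules interrogated for
## that class. Sites are filtered before counting: known population
## variants (a gnomAD-style blocklist) are removed, C>T at CpG sites is
## excluded, and positions carrying >= 2 variant molecules are dropped
## entirely — such positions would also be excluded from the MRD call, so
## leaving them in would bias the noise estimate with real (germline/CHIP)
## signal.

#' Construct an error model from per-type rates
#'
#' Convenience constructor, mainly for simulations where the rates are
#' known rather than estimated.
#'
#' @param rates Either a single rate applied to all six classes or a named
#'   numeric vector over [variant_types()].
#' @param variant_molecules,total_molecules Optional per-type counts
#'   (numerator/denominator); when omitted only the rates are stored.
#' @param metadata Optional list of provenance (sampled positions, filters,
#'   seed).
#' @return An object of class `error_model` with elements `types`, `rates`,
#'   `variant_molecules`, `total_molecules`, `overall_rate`, `metadata`.
#' @export
#' @examples
#' error_model(4.2e-7)
error_model <- function(rates, variant_molecules = NULL,
                        total_molecules = NULL, metadata = list()) {
  tys <- variant_types()
  if (length(rates) == 1L && is.null(names(rates))) {
    rates <- setNames(rep(as.numeric(rates), 6L), tys)
  }
  if (!all(tys %in% names(rates))) stop("rates must cover all six classes")
  rates <- rates[tys]
  if (any(rates < 0 | rates > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]")
  if (is.null(variant_molecules)) variant_molecules <- setNames(rep(NA_real_, 6L), tys)
  if (is.null(total_molecules)) total_molecules <- setNames(rep(NA_real_, 6L), tys)
  overall <- if (all(is.finite(total_molecules)) && sum(total_molecules) > 0)
    sum(variant_molecules) / sum(total_molecules) else mean(rates, na.rm = TRUE)
  structure(list(types = tys, rates = rates,
                 variant_molecules = variant_molecules[tys],
                 total_molecules = total_molecules[tys],
                 overall_rate = overall, metadata = metadata),
            class = "error_model")
}

#' @exportS3Method base::print
print.error_model <- function(x, ...) {
  cat("error_model: overall rate", format(x$overall_rate, digits = 3), "\n")
  for (v in x$types) {
    cat(sprintf("  %s  e = %-12s (%s / %s)\n", v,
                format(x$rates[[v]], digits = 4),
                format(x$variant_molecules[[v]], big.mark = ","),
                format(x$total_molecules[[v]], big.mark = ",")))
  }
  invisible(x)
}

#' Estimate per-type error rates from a molecule pileup
#'
#' For each collapsed class v, `e_v` is the sum of observed variant
#' molecules divided by the total molecules interrogated for that class,
#' over the retained positions. A confirmed molecule at a C/G reference
#' position is interrogated for C-T, C-G and C-A; at an A/T position for
#' A-T, A-G and A-C. Exclusions, applied before counting:
#' \itemize{
#'   \item positions with `>= max_alt_molecules` variant molecules in total
#'     are dropped (numerator and denominator) — these would not enter an
#'     MRD call either;
#'   \item the C>T channel at CpG sites is excluded (deamination
#'     background), so CpG C>T contributes to neither `e_{C-T}` nor the
#'     overall rate;
#'   \item blocklisted substitutions (exact chrom/pos/ref/alt match, e.g. a
#'     population-variant database) are excluded from their channel.
#' }
#'
#' @param pileup A pileup `data.table` (see [build_pileup()]); `ref` and
#'   `context` must be populated.
#' @param blocklist Optional `data.frame` of population variants with
#'   columns `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param max_alt_molecules Positions with at least this many variant
#'   molecules are excluded entirely (default 2).
#' @param sample_positions Optional number of pileup positions to sample
#'   (uniformly, without replacement) before estimation; mirrors estimating
#'   on a random subset of the genome for cost. Uses the current RNG state.
#' @param floor_zero_rates When `TRUE`, a class with zero observed variant
#'   molecules gets `e_v = 1 / (3 * total_molecules_v)` instead of 0
#'   (a conservative floor); the default reports 0 and lets the MRD caller
#'   guard `log(0)`.
#' @return An [error_model()] object. Classes with zero denominator get
#'   `NA` rates and a warning.
#' @export
estimate_error_rates <- function(pileup, blocklist = NULL,
                                 max_alt_molecules = 2,
                                 sample_positions = NULL,
                                 floor_zero_rates = FALSE) {
  pileup <- as.data.table(pileup)
  if (nrow(pileup) == 0L) stop("empty pileup")
  if (any(is.na(pileup$ref))) stop("pileup must carry reference bases")
  meta <- list(n_positions_total = nrow(pileup),
               max_alt_molecules = max_alt_molecules,
               blocklist = !is.null(blocklist),
               floor_zero_rates = floor_zero_rates)
  if (!is.null(sample_positions) && sample_positions < nrow(pileup)) {
    pileup <- pileup[sample.int(nrow(pileup), sample_positions)]
    meta$n_positions_sampled <- sample_positions
  }
  total_alt <- pileup$n_A + pileup$n_C + pileup$n_G + pileup$n_T
  excluded_multi <- total_alt >= max_alt_molecules
  meta$n_excluded_multimolecule <- sum(excluded_multi)
  pp <- pileup[!excluded_multi]

  tys <- variant_types()
  num <- setNames(numeric(6L), tys)
  den <- setNames(numeric(6L), tys)

  bl_key <- if (!is.null(blocklist) && nrow(blocklist) > 0L) {
    blocklist <- as.data.frame(blocklist)
    paste(blocklist$chrom, blocklist$pos, toupper(blocklist$ref),
          toupper(blocklist$alt))
  } else character(0)

  is_cpg <- .is_cpg_site(pp$ref, pp$context)
  for (ab in c("A", "C", "G", "T")) {
    sel <- pp$ref != ab & pp$ref %in% c("A", "C", "G", "T")
    if (!any(sel)) next
    cls <- classify_substitution(pp$ref[sel], rep(ab, sum(sel)),
                                 pp$context[sel])
    ## channel exclusions: CpG C>T (either strand), blocklisted variant
    drop <- (cls$type == "C-T" & is_cpg[sel])
    if (length(bl_key)) {
      drop <- drop | paste(pp$chrom[sel], pp$pos[sel], pp$ref[sel], ab) %in% bl_key
    }
    keep <- which(sel)[!drop]
    cls <- cls[!drop, , drop = FALSE]
    cnt <- pp[[paste0("n_", ab)]][keep]
    dep <- pp$depth[keep]
    for (v in unique(cls$type)) {
      j <- cls$type == v
      num[v] <- num[v] + sum(cnt[j])
      den[v] <- den[v] + sum(dep[j])
    }
  }
  rates <- ifelse(den > 0, num / den, NA_real_)
  names(rates) <- tys
  if (any(den == 0)) {
    warning("zero interrogated molecules for type(s): ",
            paste(tys[den == 0], collapse = ", "),
            "; rate undefined (NA)")
  }
  if (floor_zero_rates) {
    z <- !is.na(rates) & rates == 0 & den > 0
    rates[z] <- 1 / (3 * den[z])
  }
  em <- error_model(ifelse(is.na(rates), 0, rates), num, den, meta)
  em$rates[is.na(rates)] <- NA_real_
  em$overall_rate <- if (sum(den) > 0) sum(num) / sum(den) else NA_real_
  em
}

#' Serialise / read an error model as JSON
#'
#' @param model An [error_model()].
#' @param path Output (input) file path.
#' @return `read_error_model()` returns the [error_model()];
#'   `write_error_model()` returns `path` invisibly.
#' @export
write_error_model <- function(model, path) {
  jsonlite::write_json(
    list(types = model$types, rates = as.list(model$rates),
         variant_molecules = as.list(model$variant_molecules),
         total_molecules = as.list(model$total_molecules),
         overall_rate = model$overall_rate, metadata = model$metadata),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fill <- function(v) {
    out <- setNames(rep(NA_real_, 6L), variant_types())
    v <- unlist(v)
    out[names(v)] <- v
    out
  }
  em <- error_model(fill(x$rates), fill(x$variant_molecules),
                    fill(x$total_molecules), as.list(x$metadata))
  if (!is.null(x$overall_rate)) em$overall_rate <- x$overall_rate
  em
}
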