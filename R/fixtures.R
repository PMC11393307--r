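## Synthetic data generators. Everything the pipeline consumes — reference
## sequences, concatemer read sets with known injected errors and template
## variants, plasma pileups, tumor variant lists and multi-patient cohorts
## — can be generated deterministically from a seed, so the package is
## fully testable without external data.

#' Generate a random reference sequence
#'
#' @param length Sequence length (>= 1000).
#' @param gc GC content (default 0.41, human-like).
#' @param seed RNG seed (mandatory: fixtures must be reproducible).
#' @param name Chromosome name (default `"chr1"`).
#' @return Named character vector of length 1 (chrom name -> sequence).
#'   Warns when `gc = 0` since no CpG dinucleotide can then occur and the
#'   CpG filters become untestable on this reference.
#' @export
generate_reference <- function(length, gc = 0.41, seed, name = "chr1") {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  set.seed(seed)
  if (gc == 0)
    warning("gc = 0: reference contains no C/G, CpG-dependent paths untestable")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  setNames(paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = ""), name)
}

#' Write/read a reference as FASTA
#' @param reference Named character vector of sequences.
#' @param path FASTA path.
#' @return `read_reference_fasta()` returns the named character vector.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Fixture configuration for the concatemer read generator
#'
#' @param reference Named character vector (see [generate_reference()]).
#' @param n_molecules Number of template cfDNA molecules.
#' @param fragment_size_mean,fragment_size_sd Fragment length distribution
#'   (default peak ~170 bp, the cfDNA mononucleosome peak).
#' @param min_fragment_size Lower clip for fragment lengths.
#' @param copy_probs Named probabilities of copies per read pair (default
#'   2-4 tandem copies).
#' @param per_copy_error Per-base probability of an independent
#'   PCR/sequencing error in each copy.
#' @param template_variants Optional `data.frame` (`chrom`, `pos` 0-based,
#'   `ref`, `alt`, `vaf`): template variants carried by all copies of a
#'   molecule with probability `vaf`.
#' @param qual_high,qual_low,p_high Two-point base-quality distribution
#'   (defaults Q37 with probability 0.95, else Q20), chosen to exercise
#'   the Q > 24 confirmation filter.
#' @param duplicate_rate Probability that a molecule reuses the endpoints
#'   of a previously drawn molecule (creates PCR duplicates for
#'   deduplication tests).
#' @param seed RNG seed (mandatory).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(reference, n_molecules,
                           fragment_size_mean = 170, fragment_size_sd = 25,
                           min_fragment_size = 60,
                           copy_probs = c("2" = 0.35, "3" = 0.40, "4" = 0.25),
                           per_copy_error = 1e-3,
                           template_variants = NULL,
                           qual_high = 37, qual_low = 20, p_high = 0.95,
                           duplicate_rate = 0.05, seed) {
  stopifnot(per_copy_error >= 0, per_copy_error <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            !missing(seed))
  structure(list(reference = reference, n_molecules = as.integer(n_molecules),
                 fragment_size_mean = fragment_size_mean,
                 fragment_size_sd = fragment_size_sd,
                 min_fragment_size = min_fragment_size,
                 copy_probs = copy_probs / sum(copy_probs),
                 per_copy_error = per_copy_error,
                 template_variants = template_variants,
                 qual_high = qual_high, qual_low = qual_low, p_high = p_high,
                 duplicate_rate = duplicate_rate, seed = seed),
            class = "fixture_config")
}

#' Generate concatemer read alignments with known truth
#'
#' Each synthetic molecule yields one read pair whose alignment records
#' encode its tandem copies (already placed at their reference
#' coordinates, so no aligner is needed). Template variants are injected
#' into all copies of a carrying molecule; per-copy errors are injected
#' independently per copy. Everything injected is recorded in truth
#' tables.
#'
#' @param config A [fixture_config()].
#' @return A list: `alignments` (table as in
#'   [read_concatemer_alignments()]), `truth` with `molecules`
#'   (`molecule_id`, chrom, start, end, n_copies), `variants` (template
#'   variants per molecule) and `errors` (every injected per-copy error),
#'   and `config`.
#' @export
generate_concatemer_reads <- function(config) {
  set.seed(config$seed)
  ref <- config$reference
  chroms <- names(ref)
  lens <- nchar(ref)
  aln <- list(); truth_mol <- list(); truth_var <- list(); truth_err <- list()
  endpoints <- list()
  tv <- if (!is.null(config$template_variants))
    as.data.table(config$template_variants) else NULL
  for (i in seq_len(config$n_molecules)) {
    if (i > 1L && runif(1) < config$duplicate_rate) {
      ep <- endpoints[[sample.int(length(endpoints), 1L)]]
    } else {
      chrom <- sample(chroms, 1L)
      L <- max(config$min_fragment_size,
               round(rnorm(1, config$fragment_size_mean,
                           config$fragment_size_sd)))
      L <- min(L, lens[[chrom]] - 1L)
      start <- sample.int(lens[[chrom]] - L, 1L) - 1L
      ep <- list(chrom = chrom, start = start, end = start + L)
    }
    endpoints[[i]] <- ep
    tmpl <- strsplit(substr(ref[[ep$chrom]], ep$start + 1L, ep$end), "")[[1]]
    ## template variants carried by this molecule
    if (!is.null(tv)) {
      cand <- tv[chrom == ep$chrom & pos >= ep$start & pos < ep$end]
      if (nrow(cand)) {
        carry <- runif(nrow(cand)) < cand$vaf
        for (j in which(carry)) {
          tmpl[cand$pos[j] - ep$start + 1L] <- cand$alt[j]
          truth_var[[length(truth_var) + 1L]] <-
            data.table(molecule_id = i, chrom = ep$chrom, pos = cand$pos[j],
                       ref = cand$ref[j], alt = cand$alt[j])
        }
      }
    }
    n_copies <- as.integer(sample(names(config$copy_probs), 1L,
                                  prob = config$copy_probs))
    L <- length(tmpl)
    for (cpy in seq_len(n_copies)) {
      bases <- tmpl
      err_at <- which(runif(L) < config$per_copy_error)
      for (j in err_at) {
        nb <- sample(setdiff(c("A", "C", "G", "T"), bases[j]), 1L)
        truth_err[[length(truth_err) + 1L]] <-
          data.table(molecule_id = i, copy_index = cpy - 1L,
                     chrom = ep$chrom, pos = ep$start + j - 1L,
                     from = bases[j], to = nb)
        bases[j] <- nb
      }
      quals <- ifelse(runif(L) < config$p_high, config$qual_high,
                      config$qual_low)
      aln[[length(aln) + 1L]] <- data.table(
        qname = sprintf("mol%06d", i),
        mate = ((cpy - 1L) %% 2L) + 1L,
        chrom = ep$chrom, pos = ep$start + 1L, strand = "+",
        cigar = paste0(L, "M"),
        seq = paste(bases, collapse = ""),
        qual = intToUtf8(quals + 33L))
    }
    truth_mol[[i]] <- data.table(molecule_id = i, chrom = ep$chrom,
                                 start = ep$start, end = ep$end,
                                 n_copies = n_copies)
  }
  list(alignments = rbindlist(aln),
       truth = list(
         molecules = rbindlist(truth_mol),
         variants = if (length(truth_var)) rbindlist(truth_var) else
           data.table(molecule_id = integer(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0)),
         errors = if (length(truth_err)) rbindlist(truth_err) else
           data.table(molecule_id = integer(0), copy_index = integer(0),
                      chrom = character(0), pos = integer(0),
                      from = character(0), to = character(0))),
       config = config)
}

#' Write an alignment table as SAM
#'
#' @param alignments Alignment table (see
#'   [read_concatemer_alignments()]).
#' @param reference Named character vector, for the `@SQ` header lines.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(reference))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(reference[[nm]])), con)
  a <- as.data.table(alignments)
  flag <- 1L + ifelse(a$mate == 2L, 128L, 64L) +
    ifelse(a$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                     a$qname, flag, a$chrom, a$pos, a$cigar, a$seq, a$qual),
             con)
  invisible(path)
}

## error rate of the collapsed class of (ref, alt, context) under a model
.channel_rates <- function(model, ref, alt, context) {
  cls <- classify_substitution(ref, alt, context)
  unname(model$rates[cls$type])
}

#' Generate a plasma pileup directly under the observation model
#'
#' Emulates the molecule pileup of a plasma sample at a set of sites
#' without simulating reads: each site gets `depth` confirmed molecules
#' (fixed or Poisson) and, per alternate base, a binomial variant-molecule
#' count with success probability `site VAF + e_class` for the designated
#' marker allele and `e_class` for the other alleles. Germline sites are
#' supported through a `germline_vaf` column (0.5/1.0), overriding `cvaf`
#' at those sites. Uses the current RNG state after `set.seed(seed)`.
#'
#' @param markers Site table: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   optional `context`, optional `germline_vaf`.
#' @param depth Expected molecule depth per site.
#' @param cvaf Circulating VAF of the marker alleles.
#' @param model An [error_model()] supplying the class error rates.
#' @param seed RNG seed.
#' @param depth_law `"fixed"` or `"poisson"`.
#' @return A pileup `data.table` (see [build_pileup()]).
#' @export
generate_plasma_pileup <- function(markers, depth, cvaf, model, seed,
                                   depth_law = c("fixed", "poisson")) {
  depth_law <- match.arg(depth_law)
  set.seed(seed)
  mk <- as.data.table(markers)
  n <- nrow(mk)
  ctx <- if ("context" %in% names(mk)) mk$context else rep(NA_character_, n)
  site_vaf <- if ("germline_vaf" %in% names(mk))
    ifelse(!is.na(mk$germline_vaf), mk$germline_vaf, cvaf) else rep(cvaf, n)
  d <- if (depth_law == "fixed") rep(as.integer(depth), n) else rpois(n, depth)
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  ## marker allele: signal + error
  e_mk <- .channel_rates(model, mk$ref, mk$alt, ctx)
  cm <- rbinom(n, d, pmin(site_vaf + e_mk, 1))
  for (ab in c("A", "C", "G", "T")) {
    j <- which(mk$alt == ab)
    counts[j, ab] <- cm[j]
    ## background-only channels
    k <- which(mk$alt != ab & mk$ref != ab)
    if (length(k)) {
      eb <- .channel_rates(model, mk$ref[k], rep(ab, length(k)), ctx[k])
      counts[k, ab] <- counts[k, ab] + rbinom(length(k), d[k], eb)
    }
  }
  ## truncate total variant molecules at depth (vanishingly rare)
  tot <- rowSums(counts)
  over <- which(tot > d)
  for (j in over) {
    top <- which.max(counts[j, ])
    counts[j, top] <- counts[j, top] - (tot[j] - d[j])
  }
  data.table(chrom = mk$chrom, pos = mk$pos, ref = mk$ref, context = ctx,
             depth = d, n_A = counts[, "A"], n_C = counts[, "C"],
             n_G = counts[, "G"], n_T = counts[, "T"])
}

#' Generate a background (non-marker) pileup for error-rate estimation
#'
#' Sites with random reference bases and trinucleotide contexts; every
#' substitution channel draws a binomial variant-molecule count at its
#' class error rate. This is the input the error-model estimator sees over
#' randomly sampled genome positions.
#'
#' @param n_sites Number of sites.
#' @param depth Molecule depth per site (fixed).
#' @param model An [error_model()] of true class rates.
#' @param seed RNG seed.
#' @param gc GC fraction of reference bases.
#' @return A pileup `data.table`.
#' @export
generate_background_pileup <- function(n_sites, depth, model, seed, gc = 0.42) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ref <- sample(bases, n_sites, replace = TRUE, prob = p)
  ctx <- paste0(sample(bases, n_sites, replace = TRUE, prob = p), ref,
                sample(bases, n_sites, replace = TRUE, prob = p))
  d <- rep(as.integer(depth), n_sites)
  counts <- matrix(0L, nrow = n_sites, ncol = 4L,
                   dimnames = list(NULL, bases))
  for (ab in bases) {
    k <- which(ref != ab)
    e <- .channel_rates(model, ref[k], rep(ab, length(k)), ctx[k])
    counts[k, ab] <- rbinom(length(k), d[k], e)
  }
  data.table(chrom = "chr1", pos = seq_len(n_sites) - 1L, ref = ref,
             context = ctx, depth = d, n_A = counts[, "A"],
             n_C = counts[, "C"], n_G = counts[, "G"], n_T = counts[, "T"])
}

#' Default substitution-type profile of the synthetic tumors
#'
#' A C>T-enriched profile used by the generators when drawing somatic
#' variant types. This is a package default for synthetic data, not a
#' measured tumor profile.
#'
#' @return Named fractions over [variant_types()], summing to 1.
#' @export
synthetic_tumor_profile <- function() {
  c("C-T" = 0.40, "C-G" = 0.09, "C-A" = 0.22,
    "A-T" = 0.06, "A-G" = 0.15, "A-C" = 0.08)
}

## one synthetic substitution of a given collapsed class; non-CpG C>T
.make_variant_sites <- function(n, types) {
  bases <- c("A", "C", "G", "T")
  ref <- character(n); alt <- character(n); ctx <- character(n)
  for (i in seq_len(n)) {
    tt <- strsplit(types[i], "-")[[1]]
    flip <- runif(1) < 0.5   # random strand representation
    r <- if (flip) .revcomp_base(tt[1]) else tt[1]
    a <- if (flip) .revcomp_base(tt[2]) else tt[2]
    repeat {
      c5 <- sample(bases, 1L); c3 <- sample(bases, 1L)
      cp <- (r == "C" && a == "T" && c3 == "G") ||
            (r == "G" && a == "A" && c5 == "C")
      if (!cp) break
    }
    ref[i] <- r; alt[i] <- a; ctx[i] <- paste0(c5, r, c3)
  }
  data.table(ref = ref, alt = alt, context = ctx)
}

#' Generate a synthetic multi-patient cohort
#'
#' A desk-scale stand-in for a clinical cohort: each patient gets a
#' disjoint set of somatic variant positions (typed by
#' [synthetic_tumor_profile()], never CpG C>T), a set of germline variants
#' (het/hom, which contaminate a tumor-only variant list), and paired
#' "pre-treatment" (high cVAF) and "post-treatment" plasma pileups with
#' truth MRD labels.
#'
#' @param n_patients Number of patients.
#' @param n_somatic,n_germline Variants per patient.
#' @param depth Plasma molecule depth.
#' @param pre_cvaf cVAF of the pre-treatment samples.
#' @param post_cvaf_positive cVAF of truth-positive post-treatment samples;
#'   truth-negative ones are at 0. Odd-numbered patients are
#'   truth-positive post treatment.
#' @param model [error_model()] of plasma background rates.
#' @param seed RNG seed.
#' @return Named list (one element per patient): `tumor_variants` (somatic
#'   plus germline, as a tumor-only caller would emit), `somatic_variants`,
#'   `germline_variants`, `pileup_pre`, `pileup_post`, `truth`
#'   (`data.table`: patient, pre_positive, post_positive).
#' @export
generate_cohort <- function(n_patients, n_somatic = 2000, n_germline = 1000,
                            depth = 60, pre_cvaf = 1e-3,
                            post_cvaf_positive = 1e-3,
                            model = error_model(4.2e-7), seed = 1) {
  set.seed(seed)
  out <- list()
  block <- (n_somatic + n_germline) * 10L
  prof <- synthetic_tumor_profile()
  for (p in seq_len(n_patients)) {
    offset <- (p - 1L) * block
    n_tot <- n_somatic + n_germline
    pos <- sort(sample.int(block - 1L, n_tot)) + offset
    som_ty <- sample(names(prof), n_somatic, replace = TRUE, prob = prof)
    som <- .make_variant_sites(n_somatic, som_ty)
    som[, `:=`(chrom = "chr1", pos = pos[seq_len(n_somatic)])]
    ger_ty <- sample(names(prof), n_germline, replace = TRUE, prob = prof)
    ger <- .make_variant_sites(n_germline, ger_ty)
    ger[, `:=`(chrom = "chr1", pos = pos[n_somatic + seq_len(n_germline)],
               germline_vaf = sample(c(0.5, 1), n_germline, replace = TRUE,
                                     prob = c(0.8, 0.2)))]
    post_pos <- (p %% 2L) == 1L
    sites <- rbind(som[, .(chrom, pos, ref, alt, context,
                           germline_vaf = NA_real_)],
                   ger[, .(chrom, pos, ref, alt, context, germline_vaf)])
    pre <- generate_plasma_pileup(sites, depth, pre_cvaf, model,
                                  seed = seed * 1000L + 2L * p)
    post <- generate_plasma_pileup(
      sites, depth, if (post_pos) post_cvaf_positive else 0, model,
      seed = seed * 1000L + 2L * p + 1L)
    out[[sprintf("patient%02d", p)]] <- list(
      tumor_variants = sites[, .(chrom, pos, ref, alt, context)],
      somatic_variants = som[, .(chrom, pos, ref, alt, context)],
      germline_variants = ger[, .(chrom, pos, ref, alt, context,
                                  germline_vaf)],
      pileup_pre = pre, pileup_post = post,
      truth = data.table(patient = sprintf("patient%02d", p),
                         pre_positive = TRUE, post_positive = post_pos))
  }
  out
}
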