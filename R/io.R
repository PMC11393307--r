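## Format boundaries. Coordinates are 0-based half-open internally;
## VCF is 1-based at the file boundary. Tables travel as TSV, models and
## results as JSON; logs go to stderr, never interleaved with results.

#' Read a variant list from VCF or TSV
#'
#' VCF coordinates (1-based) are converted to the internal 0-based
#' convention; multi-allelic records are split into one entry per
#' alternate allele; alleles are uppercased. A TSV must carry columns
#' `chrom`, `pos`, `ref`, `alt` (already 0-based).
#'
#' @param path Path to a `.vcf` (optionally gzipped) or tab-separated file.
#' @return `data.table` with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt` and any extra TSV columns.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L)
      return(data.table(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0)))
    alt_split <- strsplit(toupper(fix$ALT), ",", fixed = TRUE)
    nrep <- lengths(alt_split)
    out <- data.table(chrom = rep(fix$CHROM, nrep),
                      pos = rep(as.integer(fix$POS), nrep) - 1L,
                      ref = rep(toupper(fix$REF), nrep),
                      alt = unlist(alt_split))
    bad <- is.na(out$pos) | out$ref == "" | out$alt == ""
    if (any(bad)) stop("malformed VCF record(s) at data line(s): ",
                       paste(which(bad), collapse = ", "))
    return(out[])
  }
  x <- fread(path)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x)))
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  x[, `:=`(ref = toupper(ref), alt = toupper(alt), pos = as.integer(pos))]
  x[]
}

#' Write a variant list as a minimal VCF
#'
#' Internal 0-based positions are written 1-based.
#'
#' @param variants Table with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  v <- as.data.table(variants)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       v$chrom, v$pos + 1L, v$ref, v$alt), con)
  invisible(path)
}

#' Read / write a pileup table as TSV
#' @param pileup A pileup `data.table` (see [build_pileup()]).
#' @param path File path.
#' @return `read_pileup()` returns the pileup `data.table`.
#' @export
write_pileup <- function(pileup, path) {
  fwrite(as.data.table(pileup), path, sep = "\t")
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  x <- fread(path, sep = "\t",
             colClasses = list(character = c("chrom", "ref", "context")))
  x[]
}

#' Write an MRD result as JSON
#'
#' @param result An `mrd_result` (see [lr_test()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrd_result <- function(result, path) {
  jsonlite::write_json(
    list(call = result$call, cvaf_hat = result$cvaf_hat,
         ci_low = result$ci_low, ci_high = result$ci_high,
         lr_statistic = result$lr_statistic,
         chi2_cdf_value = result$chi2_cdf_value,
         p_value = result$p_value,
         nominal_specificity = result$nominal_specificity,
         high_burden_flag = result$high_burden_flag,
         c_v = as.list(result$obs$c_v), d_v = as.list(result$obs$d_v),
         n_excluded_multimolecule = result$obs$n_excluded_multimolecule,
         n_markers_used = result$obs$n_markers_used),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the full pipeline on synthetic or provided inputs
#'
#' Chains the stages end to end: generate (or load) concatemer
#' alignments, consensus-call and deduplicate molecules, build the
#' pileup, estimate the error model, select markers and make the MRD
#' call. All stage outputs are written under `out_dir`; reruns with the
#' same seed produce identical TSV/JSON artifacts.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed driving every stage.
#' @param n_molecules Number of synthetic template molecules.
#' @param reference_length Synthetic reference length.
#' @param tumor_cvaf cVAF at which the synthetic tumor markers circulate.
#' @param n_markers Number of synthetic tumor markers.
#' @param depth Plasma molecule depth for the marker pileup.
#' @param min_qual,min_support Consensus thresholds (see
#'   [call_molecule()]).
#' @return The `mrd_result`, invisibly; artifacts on disk:
#'   `reference.fasta`, `reads.sam`, `molecules.tsv`, `pileup.tsv`,
#'   `error_model.json`, `markers.tsv`, `plasma_pileup.tsv`,
#'   `mrd_result.json`, `provenance.json`.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_molecules = 400,
                         reference_length = 20000, tumor_cvaf = 5e-4,
                         n_markers = 5000, depth = 60,
                         min_qual = 24, min_support = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("stage 1/5: synthetic reference and concatemer reads")
  ref <- generate_reference(reference_length, seed = seed)
  write_reference_fasta(ref, file.path(out_dir, "reference.fasta"))
  fx <- fixture_config(ref, n_molecules = n_molecules, seed = seed + 1)
  reads <- generate_concatemer_reads(fx)
  write_sam(reads$alignments, ref, file.path(out_dir, "reads.sam"))

  message("stage 2/5: consensus calling and deduplication")
  cons <- consensus_call(reads$alignments, ref, min_qual = min_qual,
                         min_support = min_support)
  fwrite(cons$molecule_table, file.path(out_dir, "molecules.tsv"), sep = "\t")
  write_pileup(cons$pileup, file.path(out_dir, "pileup.tsv"))

  message("stage 3/5: error model")
  em_true <- error_model(4.2e-7)
  bg <- generate_background_pileup(200000, depth, em_true, seed = seed + 2)
  em <- estimate_error_rates(bg)
  ## undefined (zero-count) classes fall back to the overall rate so the
  ## caller has a finite background for every class
  em$rates[is.na(em$rates) | em$rates == 0] <- em$overall_rate
  write_error_model(em, file.path(out_dir, "error_model.json"))

  message("stage 4/5: synthetic tumor markers and plasma pileup")
  set.seed(seed + 3)
  prof <- synthetic_tumor_profile()
  ty <- sample(names(prof), n_markers, replace = TRUE, prob = prof)
  sites <- .make_variant_sites(n_markers, ty)
  sites[, `:=`(chrom = "chrM", pos = seq_len(n_markers) - 1L)]
  markers <- finalize_marker_set(sites, provenance = "wbc_paired")
  fwrite(markers, file.path(out_dir, "markers.tsv"), sep = "\t")
  plasma <- generate_plasma_pileup(markers, depth, tumor_cvaf, em_true,
                                   seed = seed + 4)
  write_pileup(plasma, file.path(out_dir, "plasma_pileup.tsv"))

  message("stage 5/5: MRD call")
  obs <- collect_marker_observations(plasma, markers)
  res <- lr_test(obs, em)
  write_mrd_result(res, file.path(out_dir, "mrd_result.json"))
  jsonlite::write_json(
    list(package = "concatMRD",
         version = as.character(utils::packageVersion("concatMRD")),
         seed = seed, n_molecules = n_molecules,
         reference_length = reference_length, tumor_cvaf = tumor_cvaf,
         n_markers = n_markers, depth = depth,
         min_qual = min_qual, min_support = min_support),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
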