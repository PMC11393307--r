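#' The six collapsed substitution classes
#'
#' Substitutions are collapsed onto a pyrimidine reference base: a change
#' observed on a purine reference (G or T) is reported as its reverse
#' complement, so `G>A` is the same class as `C-T`, `T>C` the same as `A-G`,
#' and so on. Exactly six classes remain.
#'
#' @return Character vector of the six class labels, in canonical order.
#' @export
#' @examples
#' variant_types()
variant_types <- function() {
  c("C-T", "C-G", "C-A", "A-T", "A-G", "A-C")
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a base vector
#' @noRd
.revcomp_base <- function(b) unname(.COMPLEMENT[b])

#' Classify a substitution into the collapsed six-class scheme
#'
#' Purine-reference substitutions are mapped to their reverse complement so
#' that every substitution falls into one of the six classes returned by
#' [variant_types()]. A C>T change with a 3' G neighbour (or equivalently a
#' G>A change with a 5' C neighbour) is additionally flagged as a CpG C>T;
#' these are excluded from error-rate estimation and from MRD marker sets
#' because of their elevated deamination background.
#'
#' @param ref,alt Reference and alternate bases (vectors of single
#'   characters in `A`, `C`, `G`, `T`; `ref != alt` elementwise).
#' @param context Trinucleotide context centred on the reference base
#'   (e.g. `"ACA"`); used only to decide the CpG flag. May be `NA`, in
#'   which case `cpg_ct` is `FALSE`.
#' @return A `data.frame` with columns `type` (one of [variant_types()])
#'   and `cpg_ct` (logical).
#' @export
#' @examples
#' classify_substitution("C", "T", "ACG")   # CpG C>T
#' classify_substitution("G", "A", "TGC")   # reverse-complement CpG C>T
#' classify_substitution("T", "G", "ATT")   # A-C class
classify_substitution <- function(ref, alt, context = NA_character_) {
  ref <- toupper(ref); alt <- toupper(alt)
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  context <- toupper(rep_len(context, n))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("ambiguous or invalid base in substitution: ",
         paste(unique(paste0(ref[!ok], ">", alt[!ok])), collapse = ", "))
  }
  if (any(ref == alt)) stop("ref and alt must differ")

  flip <- ref %in% c("G", "T")
  cref <- ifelse(flip, .revcomp_base(ref), ref)
  calt <- ifelse(flip, .revcomp_base(alt), alt)
  type <- paste0(cref, "-", calt)
  if (!all(type %in% variant_types())) stop("internal: bad collapsed type")

  next3 <- ifelse(is.na(context) | nchar(context) < 3, NA, substr(context, 3, 3))
  prev5 <- ifelse(is.na(context) | nchar(context) < 3, NA, substr(context, 1, 1))
  cpg <- (ref == "C" & alt == "T" & !is.na(next3) & next3 == "G") |
         (ref == "G" & alt == "A" & !is.na(prev5) & prev5 == "C")
  data.frame(type = type, cpg_ct = cpg, stringsAsFactors = FALSE)
}

#' Which collapsed classes does a reference base contribute depth to?
#'
#' A confirmed molecule at a C or G reference position is interrogated for
#' the three pyrimidine-collapsed classes C-T, C-G, C-A; at an A or T
#' position for A-T, A-G, A-C.
#' @noRd
.types_for_ref <- function(ref) {
  pyr <- ifelse(ref %in% c("G", "T"), .revcomp_base(ref), ref)
  lapply(pyr, function(b) paste0(b, "-", setdiff(c("A", "C", "G", "T"), b)))
}

#' Is a site a CpG site for the C>T channel?
#'
#' TRUE when the reference base is C with a 3' G neighbour, or G with a 5'
#' C neighbour (the reverse-complement reading of the same dinucleotide).
#' @noRd
.is_cpg_site <- function(ref, context) {
  (ref == "C" & !is.na(context) & nchar(context) >= 3 & substr(context, 3, 3) == "G") |
  (ref == "G" & !is.na(context) & nchar(context) >= 3 & substr(context, 1, 1) == "C")
}
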