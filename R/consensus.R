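## Consensus calling from concatemer alignments.
##
## A rolling-circle concatemer read pair contains several tandem copies of
## one template cfDNA fragment. After alignment each copy appears as a
## separate (split/supplementary) alignment record over the same reference
## span. Copies are grouped by reciprocal overlap, compared base by base,
## and only calls supported identically by >= 2 high-quality copies are
## kept ("repeat confirmation"); discordant calls are treated as PCR or
## sequencing errors and discarded.

#' Read concatemer alignment records from SAM/BAM
#'
#' Loads mapped records with their CIGAR, sequence and base qualities into
#' the flat alignment table used by [segment_tandem_copies()]. A `.sam`
#' file is converted on the fly. Secondary/supplementary records are kept:
#' each mapped record is one candidate tandem copy.
#'
#' @param path Path to a SAM or BAM file.
#' @return A `data.table` with columns `qname`, `mate` (1 or 2), `chrom`,
#'   `pos` (1-based leftmost reference position), `strand`, `cigar`,
#'   `seq`, `qual` (Phred+33 string).
#' @export
read_concatemer_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.table(
    qname  = x$qname,
    mate   = ifelse(bitwAnd(x$flag, 128L) > 0L, 2L, 1L),
    chrom  = as.character(x$rname),
    pos    = x$pos,
    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
    cigar  = x$cigar,
    seq    = as.character(x$seq),
    qual   = as.character(x$qual)
  )
}

#' Expand one alignment record to per-reference-position base calls
#'
#' @param pos 1-based leftmost reference position.
#' @return An `aligned_copy`: reference span (0-based half-open) plus
#'   parallel vectors of covered reference positions, called bases and
#'   Phred qualities. Insertions and clipped bases are skipped; deletions
#'   advance the reference without emitting calls (indels are out of scope
#'   for confirmation).
#' @noRd
.expand_alignment <- function(qname, mate, chrom, pos, strand, cigar, seq, qual) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != cigar)
    stop("unparseable CIGAR: ", cigar)
  ops  <- substr(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  bases <- strsplit(seq, "")[[1]]
  quals <- utf8ToInt(qual) - 33L
  rp <- pos - 1L  # 0-based reference cursor
  qp <- 1L        # 1-based query cursor
  ref_pos <- integer(0); b <- character(0); q <- integer(0)
  for (i in seq_along(ops)) {
    L <- lens[i]
    op <- ops[i]
    if (op %in% c("M", "=", "X")) {
      idx <- qp:(qp + L - 1L)
      ref_pos <- c(ref_pos, rp:(rp + L - 1L))
      b <- c(b, bases[idx]); q <- c(q, quals[idx])
      rp <- rp + L; qp <- qp + L
    } else if (op %in% c("I", "S")) {
      qp <- qp + L
    } else if (op %in% c("D", "N")) {
      rp <- rp + L
    } # H, P: no-op
  }
  structure(list(read_pair_id = qname, mate = mate, copy_index = NA_integer_,
                 chrom = chrom, ref_start = pos - 1L, ref_end = rp,
                 strand = strand, ref_pos = ref_pos, base = b, qual = q),
            class = "aligned_copy")
}

#' Group the alignments of one read pair into tandem-copy groups
#'
#' Copies of the same template map to (nearly) the same reference span, so
#' records whose spans reciprocally overlap by at least
#' `min_reciprocal_overlap` on the same chromosome are grouped as repeats
#' of one template molecule. Records on different chromosomes, or with
#' insufficient overlap, start separate groups (a group of one copy can
#' never be confirmed). Grouping is invariant to input record order.
#'
#' @param records Alignment table for a single read pair (see
#'   [read_concatemer_alignments()]), or a list of `aligned_copy` objects.
#' @param min_reciprocal_overlap Minimum reciprocal span overlap for two
#'   records to be considered copies of the same template (default 0.9).
#' @return A list of copy groups; each group is a list of `aligned_copy`
#'   objects with `copy_index` assigned. An unmapped-only/empty input
#'   yields an empty list.
#' @export
segment_tandem_copies <- function(records, min_reciprocal_overlap = 0.9) {
  copies <- if (is.list(records) && !is.data.frame(records)) {
    records
  } else {
    records <- as.data.table(records)
    if (nrow(records) == 0L) return(list())
    if (length(unique(records$qname)) > 1L)
      stop("segment_tandem_copies() expects records of a single read pair")
    lapply(seq_len(nrow(records)), function(i)
      .expand_alignment(records$qname[i], records$mate[i], records$chrom[i],
                        records$pos[i], records$strand[i], records$cigar[i],
                        records$seq[i], records$qual[i]))
  }
  if (length(copies) == 0L) return(list())
  ## deterministic processing order regardless of input order
  ord <- order(vapply(copies, function(x) x$chrom, ""),
               vapply(copies, function(x) as.numeric(x$ref_start), 0),
               vapply(copies, function(x) as.numeric(x$ref_end), 0),
               vapply(copies, function(x) as.numeric(x$mate), 0))
  copies <- copies[ord]
  groups <- list()
  for (cp in copies) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      rep_cp <- groups[[g]][[1]]
      if (!identical(rep_cp$chrom, cp$chrom)) next
      ov <- min(rep_cp$ref_end, cp$ref_end) - max(rep_cp$ref_start, cp$ref_start)
      if (ov <= 0) next
      rec <- min(ov / (rep_cp$ref_end - rep_cp$ref_start),
                 ov / (cp$ref_end - cp$ref_start))
      if (rec >= min_reciprocal_overlap) {
        cp$copy_index <- length(groups[[g]])
        groups[[g]] <- c(groups[[g]], list(cp))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cp$copy_index <- 0L
      groups[[length(groups) + 1L]] <- list(cp)
    }
  }
  groups
}

#' Repeat-confirm a single reference position within a copy group
#'
#' Only base calls with Phred quality strictly greater than `min_qual` are
#' considered. The position is confirmed when at least `min_support`
#' remaining copies cover it and all of them agree; any disagreement, or
#' insufficient usable copies, leaves the position unconfirmed (and
#' discarded as a presumed PCR/sequencing error).
#'
#' @param copies A copy group (list of `aligned_copy`).
#' @param pos 0-based reference position.
#' @param min_qual Phred threshold; comparison is strict (`qual > min_qual`).
#' @param min_support Minimum number of agreeing covering copies (default 2).
#' @param ref_base Optional reference base; when supplied the status
#'   distinguishes `CONFIRMED_REF` from `CONFIRMED_ALT`.
#' @param strict_single_mate When `TRUE`, the supporting copies must
#'   include at least `min_support` from a single mate. Under paired-end
#'   sequencing of a short template, read 1 and read 2 can cover the same
#'   single copy and be mistaken for two independent repeats; this mode
#'   emulates long single-end reads where confirmation always comes from
#'   true tandem repeats.
#' @return A list with `status` (`"CONFIRMED_REF"`, `"CONFIRMED_ALT"` or
#'   `"UNCONFIRMED"`), `base` (consensus base or `NA`) and `support`.
#' @export
repeat_confirm <- function(copies, pos, min_qual = 24, min_support = 2,
                           ref_base = NULL, strict_single_mate = FALSE) {
  b <- character(0); m <- integer(0)
  for (cp in copies) {
    i <- match(pos, cp$ref_pos)
    if (!is.na(i) && cp$qual[i] > min_qual) {
      b <- c(b, cp$base[i]); m <- c(m, cp$mate)
    }
  }
  unconf <- list(status = "UNCONFIRMED", base = NA_character_, support = length(b))
  if (length(b) < min_support) return(unconf)
  if (length(unique(b)) != 1L) return(unconf)
  if (strict_single_mate && max(tabulate(m, nbins = 2L)) < min_support)
    return(unconf)
  status <- if (is.null(ref_base)) "CONFIRMED_ALT"
            else if (b[1] == ref_base) "CONFIRMED_REF" else "CONFIRMED_ALT"
  list(status = status, base = b[1], support = length(b))
}

#' Call a consensus molecule from a tandem-copy group
#'
#' The template span is taken as the modal (most frequent) copy span; every
#' position in it is labelled by repeat confirmation. The result carries
#' the molecule's unique identifier (chrom, start, end) used downstream for
#' deduplication.
#'
#' @inheritParams repeat_confirm
#' @param reference Named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences, used to split confirmed calls into
#'   reference-agreeing and variant calls.
#' @return A `molecule_call`: chrom/start/end (0-based half-open),
#'   `n_copies`, and a `data.table` `calls` with columns `pos`, `status`,
#'   `base`, `support`.
#' @export
call_molecule <- function(copies, reference, min_qual = 24, min_support = 2,
                          strict_single_mate = FALSE) {
  if (length(copies) == 0L) stop("empty copy group")
  reference <- .as_ref_vector(reference)
  chrom <- copies[[1]]$chrom
  spans <- vapply(copies, function(cp) paste(cp$ref_start, cp$ref_end), "")
  modal <- names(sort(table(spans), decreasing = TRUE))[1]
  se <- as.integer(strsplit(modal, " ")[[1]])
  start <- se[1]; end <- se[2]
  positions <- if (end > start) start:(end - 1L) else integer(0)
  L <- length(positions)
  k <- length(copies)
  bm <- matrix(NA_character_, nrow = k, ncol = L)
  qm <- matrix(NA_integer_, nrow = k, ncol = L)
  mates <- vapply(copies, `[[`, 0L, "mate")
  for (i in seq_len(k)) {
    cp <- copies[[i]]
    j <- match(cp$ref_pos, positions)
    keep <- !is.na(j)
    bm[i, j[keep]] <- cp$base[keep]
    qm[i, j[keep]] <- cp$qual[keep]
  }
  bm[is.na(qm) | qm <= min_qual] <- NA_character_
  support <- colSums(!is.na(bm))
  ## consensus base = first non-NA per column; confirmed iff no disagreement
  cons <- rep(NA_character_, L)
  for (i in seq_len(k)) {
    take <- is.na(cons) & !is.na(bm[i, ])
    cons[take] <- bm[i, take]
  }
  disagree <- colSums(bm != matrix(cons, nrow = k, ncol = L, byrow = TRUE),
                      na.rm = TRUE) > 0
  confirmed <- support >= min_support & !disagree
  if (strict_single_mate && any(confirmed)) {
    per_mate <- vapply(1:2, function(mm) {
      rows <- mates == mm
      if (!any(rows)) rep(0L, L) else colSums(!is.na(bm[rows, , drop = FALSE]))
    }, integer(L))
    confirmed <- confirmed & apply(per_mate, 1, max) >= min_support
  }
  refseq <- .ref_bases(reference, chrom, positions)
  status <- ifelse(!confirmed, "UNCONFIRMED",
                   ifelse(cons == refseq, "CONFIRMED_REF", "CONFIRMED_ALT"))
  calls <- data.table(pos = positions, status = status,
                      base = ifelse(confirmed, cons, NA_character_),
                      support = as.integer(support))
  structure(list(chrom = chrom, start = start, end = end,
                 n_copies = k, calls = calls),
            class = "molecule_call")
}

.as_ref_vector <- function(reference) {
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  reference
}

.ref_bases <- function(reference, chrom, positions) {
  if (length(positions) == 0L) return(character(0))
  substring(reference[[chrom]], positions + 1L, positions + 1L)
}

#' Deduplicate molecule calls by fragment endpoints
#'
#' Molecules sharing (chrom, start, end) — the unique molecule identifier —
#' collapse to one. The collapsed molecule keeps the union of confirmed
#' calls; when two duplicates disagree on a confirmed call at the same
#' position, the position is conservatively demoted to unconfirmed.
#'
#' @param molecules List of `molecule_call` objects.
#' @return List of unique `molecule_call` objects (its `length()` is the
#'   unique molecule count).
#' @export
dedup_molecules <- function(molecules) {
  if (length(molecules) == 0L) return(list())
  keys <- vapply(molecules, function(m) paste(m$chrom, m$start, m$end), "")
  out <- list()
  for (k in unique(keys)) {
    grp <- molecules[keys == k]
    if (length(grp) == 1L) { out[[length(out) + 1L]] <- grp[[1]]; next }
    calls <- rbindlist(lapply(grp, `[[`, "calls"))
    merged <- calls[, {
      conf <- status != "UNCONFIRMED"
      if (!any(conf)) {
        list(status = "UNCONFIRMED", base = NA_character_,
             support = max(support))
      } else {
        cb <- unique(base[conf])
        cs <- unique(status[conf])
        if (length(cb) == 1L && length(cs) == 1L) {
          list(status = cs, base = cb, support = max(support[conf]))
        } else {
          list(status = "UNCONFIRMED", base = NA_character_,
               support = max(support))
        }
      }
    }, by = pos]
    setorder(merged, pos)
    m <- grp[[1]]
    m$n_copies <- max(vapply(grp, `[[`, 0L, "n_copies"))
    m$calls <- merged
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Build a molecule-level pileup from unique molecules
#'
#' Molecule depth at a position counts unique molecules with a confirmed
#' call there (reference-agreeing or variant); unconfirmed calls contribute
#' to neither depth nor variant counts. Variant molecule counts are kept
#' per alternate base.
#'
#' @param molecules Deduplicated list of `molecule_call` objects.
#' @param reference Optional reference (as in [call_molecule()]) used to
#'   annotate the reference base and trinucleotide context.
#' @param regions Optional `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open) restricting the output.
#' @return A pileup `data.table` with columns `chrom`, `pos` (0-based),
#'   `ref`, `context`, `depth`, `n_A`, `n_C`, `n_G`, `n_T` (unique variant
#'   molecules per alternate base).
#' @export
build_pileup <- function(molecules, reference = NULL, regions = NULL) {
  if (length(molecules) == 0L) return(empty_pileup())
  calls <- rbindlist(lapply(molecules, function(m) {
    cc <- m$calls[status != "UNCONFIRMED"]
    if (nrow(cc) == 0L) return(NULL)
    data.table(chrom = m$chrom, pos = cc$pos, status = cc$status, base = cc$base)
  }))
  if (is.null(calls) || nrow(calls) == 0L) return(empty_pileup())
  pile <- calls[, {
    alt <- base[status == "CONFIRMED_ALT"]
    list(depth = .N,
         n_A = sum(alt == "A"), n_C = sum(alt == "C"),
         n_G = sum(alt == "G"), n_T = sum(alt == "T"),
         refcall = {
           rb <- unique(base[status == "CONFIRMED_REF"])
           if (length(rb) == 1L) rb else NA_character_
         })
  }, by = .(chrom, pos)]
  if (!is.null(reference)) {
    reference <- .as_ref_vector(reference)
    pile[, ref := substr(reference[chrom], pos + 1L, pos + 1L)]
    pile[, context := .trinuc(reference, chrom, pos)]
  } else {
    pile[, ref := refcall]
    pile[, context := NA_character_]
  }
  pile[, refcall := NULL]
  setcolorder(pile, c("chrom", "pos", "ref", "context", "depth",
                      "n_A", "n_C", "n_G", "n_T"))
  if (!is.null(regions)) {
    regions <- as.data.table(regions)
    keep <- rep(FALSE, nrow(pile))
    for (i in seq_len(nrow(regions))) {
      keep <- keep | (pile$chrom == regions$chrom[i] &
                      pile$pos >= regions$start[i] & pile$pos < regions$end[i])
    }
    pile <- pile[keep]
  }
  setorder(pile, chrom, pos)
  pile[]
}

.trinuc <- function(reference, chrom, pos) {
  seqs <- reference[chrom]
  lens <- nchar(seqs)
  ifelse(pos >= 1L & pos + 2L <= lens,
         substr(seqs, pos, pos + 2L), NA_character_)
}

#' An empty pileup table
#' @return Zero-row pileup `data.table` with the standard columns.
#' @export
empty_pileup <- function() {
  data.table(chrom = character(0), pos = integer(0), ref = character(0),
             context = character(0), depth = integer(0),
             n_A = integer(0), n_C = integer(0), n_G = integer(0),
             n_T = integer(0))
}

#' Run the full consensus stage: group, confirm, deduplicate, pile up
#'
#' @param alignments Alignment table over any number of read pairs (see
#'   [read_concatemer_alignments()]).
#' @inheritParams call_molecule
#' @param min_reciprocal_overlap Passed to [segment_tandem_copies()].
#' @return A list with `molecules` (unique `molecule_call`s), `molecule_table`
#'   (`data.table`: chrom, start, end, n_copies) and `pileup`.
#' @export
consensus_call <- function(alignments, reference, min_qual = 24,
                           min_support = 2, strict_single_mate = FALSE,
                           min_reciprocal_overlap = 0.9) {
  alignments <- as.data.table(alignments)
  reference <- .as_ref_vector(reference)
  mols <- list()
  if (nrow(alignments) > 0L) {
    for (rp in split(alignments, by = "qname")) {
      groups <- segment_tandem_copies(rp, min_reciprocal_overlap)
      for (g in groups) {
        mols[[length(mols) + 1L]] <-
          call_molecule(g, reference, min_qual, min_support, strict_single_mate)
      }
    }
  }
  uniq <- dedup_molecules(mols)
  tab <- if (length(uniq)) rbindlist(lapply(uniq, function(m)
    data.table(chrom = m$chrom, start = m$start, end = m$end,
               n_copies = m$n_copies))) else
    data.table(chrom = character(0), start = integer(0), end = integer(0),
               n_copies = integer(0))
  setorder(tab, chrom, start, end)
  list(molecules = uniq, molecule_table = tab,
       pileup = build_pileup(uniq, reference))
}
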