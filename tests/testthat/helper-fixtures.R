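# Shared fixture builders (all deterministic given the seed they take).

# a tiny aligned_copy built by hand: full-span match, constant quality
make_copy <- function(chrom, start, bases, qual = 37, mate = 1L,
                      qname = "rp1") {
  n <- length(bases)
  structure(list(read_pair_id = qname, mate = mate, copy_index = NA_integer_,
                 chrom = chrom, ref_start = start, ref_end = start + n,
                 strand = "+", ref_pos = start:(start + n - 1L),
                 base = bases, qual = rep(qual, length.out = n)),
            class = "aligned_copy")
}

# wide pileup row builder
pileup_row <- function(chrom = "chr1", pos, ref, context = NA_character_,
                       depth, A = 0L, C = 0L, G = 0L, T = 0L) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos), ref = ref,
                         context = context, depth = as.integer(depth),
                         n_A = as.integer(A), n_C = as.integer(C),
                         n_G = as.integer(G), n_T = as.integer(T))
}

# an alignment-table record with a plain match CIGAR
aln_record <- function(qname, mate, chrom, start0, seq, qual = 37,
                       strand = "+") {
  data.table::data.table(
    qname = qname, mate = as.integer(mate), chrom = chrom,
    pos = start0 + 1L, strand = strand,
    cigar = paste0(nchar(seq), "M"), seq = seq,
    qual = intToUtf8(rep(qual + 33L, nchar(seq))))
}
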