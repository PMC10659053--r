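#' Build a filtered per-position base pileup
#'
#' Converts ungapped aligned reads into per-position, per-strand base
#' counts after the read-level filters of the editome workflow: the first
#' and last `trim_bases` bases of every aligned read are discarded, bases
#' must reach the Phred floor `min_base_quality`, and (optionally) only
#' uniquely aligned reads contribute (mapping quality > 0 and neither
#' secondary nor supplementary). For RNA, each base is assigned to the
#' transcript strand decoded from the strandedness protocol and is recorded
#' in transcript orientation, so a genome-strand T/C pileup under a
#' minus-strand transcript appears as A/G.
#'
#' @param reads a read table as produced by [simulate_reads()] or
#'   [read_sam()]; only ungapped (`<n>M`) alignments are supported.
#' @param ref a `reference_bundle` (used for chromosome bookkeeping).
#' @param min_base_quality Phred floor for a base to count.
#' @param trim_bases number of bases ignored at each read end.
#' @param unique_only drop non-unique alignments.
#' @param source `"RNA"` (stranded, transcript-oriented counts) or `"DNA"`
#'   (unstranded, genome-forward counts with strand `"*"`).
#' @param protocol strandedness protocol, see [read_sim_params()].
#' @return a `site_pileup` data.table with columns `chrom`, `pos`,
#'   `strand`, `A`, `C`, `G`, `T`, `depth`; attribute `"rejected"` counts
#'   reads excluded per reason, attribute `"mapped_bases"` the number of
#'   filtered bases that contributed.
#' @export
build_pileup <- function(reads, ref, min_base_quality = 30L, trim_bases = 6L,
                         unique_only = TRUE, source = c("RNA", "DNA"),
                         protocol = c("forward", "reverse")) {
  source <- match.arg(source)
  protocol <- match.arg(protocol)
  reads <- as.data.table(reads)
  rejected <- c(unmapped = 0L, nonunique = 0L, no_quality = 0L,
                gapped = 0L)

  keep <- bitwAnd(reads$flag, 4L) == 0L
  rejected["unmapped"] <- sum(!keep)
  if (unique_only) {
    uq <- reads$mapq > 0L & bitwAnd(reads$flag, 256L) == 0L &
      bitwAnd(reads$flag, 2048L) == 0L
    rejected["nonunique"] <- sum(keep & !uq)
    keep <- keep & uq
  }
  noq <- is.na(reads$qual) | reads$qual == "*"
  rejected["no_quality"] <- sum(keep & noq)
  keep <- keep & !noq
  gap <- !grepl("^[0-9]+M$", reads$cigar)
  rejected["gapped"] <- sum(keep & gap)
  keep <- keep & !gap
  reads <- reads[keep]

  empty <- data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), depth = integer(0))
  if (!nrow(reads)) {
    setattr(empty, "rejected", rejected)
    setattr(empty, "mapped_bases", 0)
    setattr(empty, "class", c("site_pileup", class(empty)))
    return(empty[])
  }

  L <- nchar(reads$seq)
  align_strand <- fifelse(bitwAnd(reads$flag, 16L) != 0L, "-", "+")
  tx_strand <- if (source == "RNA") {
    if (protocol == "forward") align_strand else
      fifelse(align_strand == "+", "-", "+")
  } else rep("*", nrow(reads))

  idx <- rep(seq_len(nrow(reads)), L)
  offset <- sequence(L)
  gpos <- reads$pos[idx] + offset - 1L
  base_raw <- charToRaw(paste(reads$seq, collapse = ""))
  qual_int <- as.integer(charToRaw(paste(reads$qual, collapse = ""))) - 33L
  bidx <- .base_lut[as.integer(base_raw) + 1L]

  ok <- offset > trim_bases & offset <= L[idx] - trim_bases &
    qual_int >= min_base_quality & !is.na(bidx)
  dt <- data.table(chrom = reads$chrom[idx][ok], pos = gpos[ok],
                   strand = tx_strand[idx][ok], b = bidx[ok])
  # transcript orientation: complement bases under minus-strand transcripts
  if (source == "RNA") dt[strand == "-", b := .comp_idx[b]]
  counts <- dt[, .N, by = .(chrom, pos, strand, b)]
  wide <- dcast(counts, chrom + pos + strand ~ b, value.var = "N", fill = 0L)
  for (j in as.character(1:4)) if (!j %in% names(wide)) wide[, (j) := 0L]
  setnames(wide, as.character(1:4), BASES)
  wide[, depth := A + C + G + T]
  setorder(wide, chrom, pos, strand)
  setattr(wide, "rejected", rejected)
  setattr(wide, "mapped_bases", nrow(dt))
  setattr(wide, "class", c("site_pileup", class(wide)))
  wide[]
}

#' Derive the SNP mask and callable set from a DNA pileup
#'
#' A position is masked as a genomic variant when its filtered DNA depth
#' reaches `min_dna_depth` and any non-reference base is supported by at
#' least `min_alt_reads` reads. Positions whose DNA depth is below
#' `min_dna_depth` are uncallable: editing cannot be distinguished from an
#' unobserved genomic variant there, so they are excluded from calling
#' altogether.
#'
#' @param dna_pileup a DNA `site_pileup` built with the same filters as the
#'   RNA pileup.
#' @param ref a `reference_bundle` (for reference bases).
#' @param min_dna_depth minimum DNA depth for a position to be callable.
#' @param min_alt_reads alternate reads required to mask a position.
#' @return an object of class `snp_mask`: a list with data.tables `masked`
#'   and `callable` (columns `chrom`, `pos`) and the parameters used.
#' @export
mask_dna_variants <- function(dna_pileup, ref, min_dna_depth = 10L,
                              min_alt_reads = 2L) {
  dp <- as.data.table(dna_pileup)
  if (!nrow(dp)) {
    return(structure(list(masked = data.table(chrom = character(0),
                                              pos = integer(0)),
                          callable = data.table(chrom = character(0),
                                                pos = integer(0)),
                          min_dna_depth = min_dna_depth,
                          min_alt_reads = min_alt_reads),
                     class = "snp_mask"))
  }
  dp[, ref_fwd := ref_base_at(ref, chrom, pos)]
  cm <- as.matrix(dp[, .(A, C, G, T)])
  cm_alt <- replace(cm, cbind(seq_len(nrow(cm)), match(dp$ref_fwd, BASES)), 0L)
  max_alt <- pmax(cm_alt[, 1], cm_alt[, 2], cm_alt[, 3], cm_alt[, 4])
  callable <- dp$depth >= min_dna_depth
  masked <- callable & max_alt >= min_alt_reads
  structure(list(masked = dp[masked, .(chrom, pos)],
                 callable = dp[callable, .(chrom, pos)],
                 min_dna_depth = min_dna_depth,
                 min_alt_reads = min_alt_reads),
            class = "snp_mask")
}
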