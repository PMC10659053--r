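# Internal exact-seed / ungapped-extension aligner.
#
# Seeds of width k are taken from the start, middle and end of each query
# and matched exactly against the target with Biostrings::matchPDict; every
# seed hit proposes a candidate alignment start, and each candidate is
# scored ungapped as the number of matching bases over the full query.
# Small genomes make exact seeding tractable; this backs both the
# uniqueness re-check of called sites and the transformed realignment of
# hyper-edited reads.

seed_offsets <- function(L, k) {
  o <- unique(c(1L, pmax(1L, (L - k) %/% 2L + 1L), pmax(1L, L - k + 1L)))
  o[o + k - 1L <= L]
}

# qseqs: character queries; targets: named character vector (chrom -> seq).
# Returns data.table(read, chrom, start, score, L).
seed_extend_align <- function(qseqs, targets, k = 16L) {
  n <- length(qseqs)
  if (!n) return(data.table(read = integer(0), chrom = character(0),
                            start = integer(0), score = integer(0),
                            L = integer(0)))
  qlen <- nchar(qseqs)
  seed_dt <- rbindlist(lapply(seq_len(n), function(i) {
    o <- seed_offsets(qlen[i], k)
    data.table(read = i, offset = o,
               seed = substring(qseqs[i], o, o + k - 1L))
  }))
  if (!nrow(seed_dt)) return(data.table(read = integer(0),
                                        chrom = character(0),
                                        start = integer(0),
                                        score = integer(0), L = integer(0)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_dt$seed))
  cand <- vector("list", length(targets))
  for (ci in seq_along(targets)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(targets[[ci]]))
    nh <- S4Vectors::elementNROWS(m)
    if (!sum(nh)) next
    hit_seed <- rep(seq_along(nh), nh)
    starts <- unlist(Biostrings::startIndex(m), use.names = FALSE)
    cand[[ci]] <- data.table(read = seed_dt$read[hit_seed],
                             chrom = names(targets)[ci],
                             start = starts - seed_dt$offset[hit_seed] + 1L)
  }
  cand <- rbindlist(cand)
  if (!nrow(cand)) return(data.table(read = integer(0),
                                     chrom = character(0),
                                     start = integer(0), score = integer(0),
                                     L = integer(0)))
  cand[, L := qlen[read]]
  tlen <- setNames(nchar(targets), names(targets))
  cand <- cand[start >= 1L & start + L - 1L <= tlen[chrom]]
  cand <- unique(cand, by = c("read", "chrom", "start"))
  if (!nrow(cand)) return(cand[, .(read, chrom, start,
                                   score = integer(0), L)])
  tseq <- substring(targets[cand$chrom], cand$start, cand$start + cand$L - 1L)
  cand[, score := match_count(qseqs[read], tseq)]
  cand[]
}

match_count <- function(a, b) {
  vapply(seq_along(a),
         function(i) sum(charToRaw(a[i]) == charToRaw(b[i])), integer(1))
}

#' Realignment uniqueness check for called sites
#'
#' Re-examines the reads supporting each called site with the internal
#' exact-seed / ungapped-extension aligner: a supporting read is ambiguous
#' when a second genomic locus (either strand) scores at least
#' `margin * best`. Sites with any ambiguous supporting read are dropped,
#' mirroring the conventional BLAT-style re-check of edit-supporting reads.
#' With `margin = Inf` the filter is disabled and no site is ever dropped.
#'
#' @param sites an edit-site table (needs `chrom`, `pos`, `strand`,
#'   `alt_fwd` columns; [call_sites()] output qualifies).
#' @param reads the aligned read table the sites were called from.
#' @param ref a `reference_bundle`.
#' @param k seed length.
#' @param margin score fraction at which a secondary locus makes a read
#'   ambiguous.
#' @param max_reads_per_site supporting reads examined per site.
#' @return the site table with a logical column `realign_keep`; dropped
#'   sites have `realign_keep == FALSE`.
#' @export
realignment_check <- function(sites, reads, ref, k = 16L, margin = 0.95,
                              max_reads_per_site = 3L) {
  sites <- as.data.table(sites)
  sites[, realign_keep := TRUE]
  if (!nrow(sites)) return(sites[])
  reads <- as.data.table(reads)[bitwAnd(flag, 4L) == 0L &
                                  grepl("^[0-9]+M$", cigar)]
  if (!nrow(reads)) return(sites[])
  widths <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  offs <- setNames(cumsum(c(0, widths[-length(widths)])), names(widths))
  rl <- nchar(reads$seq)
  rq <- IRanges::IRanges(offs[reads$chrom] + reads$pos, width = rl)
  sq <- IRanges::IRanges(offs[sites$chrom] + sites$pos, width = 1L)
  hits <- IRanges::findOverlaps(sq, rq)
  if (!length(hits)) return(sites[])
  pr <- data.table(s = S4Vectors::queryHits(hits),
                   r = S4Vectors::subjectHits(hits))
  pr[, offset := sites$pos[s] - reads$pos[r] + 1L]
  pr <- pr[substring(reads$seq[r], offset, offset) == sites$alt_fwd[s]]
  if (!nrow(pr)) return(sites[])
  pr <- pr[, head(.SD, max_reads_per_site), by = s]
  uread <- unique(pr$r)
  aln_f <- seed_extend_align(reads$seq[uread], ref$genome_chr, k = k)
  aln_r <- seed_extend_align(revcomp_chr(reads$seq[uread]), ref$genome_chr,
                             k = k)
  aln <- rbind(aln_f[, .(read, chrom, start, score, strand = "+")],
               aln_r[, .(read, chrom, start, score, strand = "-")])
  if (!nrow(aln)) return(sites[])
  setorder(aln, read, -score)
  summ <- aln[, .(best = as.double(score[1]),
                  second = if (.N > 1L) as.double(score[2]) else -Inf),
              by = read]
  ambiguous <- uread[summ$read[summ$second >= margin * summ$best]]
  bad_sites <- unique(pr$s[pr$r %in% ambiguous])
  sites[bad_sites, realign_keep := FALSE]
  sites[]
}
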