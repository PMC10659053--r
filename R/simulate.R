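#' Read-simulation parameters
#'
#' @param read_length read length in bp.
#' @param coverage_rna,coverage_dna mean fold coverage of the RNA library
#'   (per simulated library) and the DNA library.
#' @param base_error_rate per-base substitution error probability in
#'   `[0, 0.05]`.
#' @param protocol strandedness protocol: `"forward"` (read orientation
#'   equals transcript strand) or `"reverse"` (opposite).
#' @param aligner_mismatch_cap reads with more than this many mismatches are
#'   emitted as unaligned records, emulating aligner failure on
#'   hyper-edited reads.
#' @param reads_per_cluster hyper-edited transcript reads generated over
#'   each planted cluster.
#' @param mapq mapping quality written for aligned reads.
#' @param seed integer seed; run-specific seeds are derived from it together
#'   with the condition and replicate labels.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 150L, coverage_rna = 50,
                            coverage_dna = 30, base_error_rate = 0.001,
                            protocol = c("forward", "reverse"),
                            aligner_mismatch_cap = 4L,
                            reads_per_cluster = 20L, mapq = 60L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (base_error_rate < 0 || base_error_rate > 0.05)
    stop("base_error_rate must lie in [0, 0.05]", call. = FALSE)
  if (coverage_rna <= 0 || coverage_dna <= 0)
    stop("coverage must be > 0", call. = FALSE)
  structure(list(read_length = as.integer(read_length),
                 coverage_rna = coverage_rna, coverage_dna = coverage_dna,
                 base_error_rate = base_error_rate, protocol = protocol,
                 aligner_mismatch_cap = as.integer(aligner_mismatch_cap),
                 reads_per_cluster = as.integer(reads_per_cluster),
                 mapq = as.integer(mapq), seed = as.integer(seed)),
            class = "read_sim_params")
}

phred_char <- function(error_rate) {
  q <- if (error_rate > 0) round(-10 * log10(error_rate)) else 40L
  rawToChar(as.raw(33L + max(2L, min(40L, q))))
}

#' Simulate aligned DNA and stranded RNA reads for one library
#'
#' Draws RNA reads uniformly within the reference's transcription units
#' (preserving strand through the library protocol), plants the truth
#' table's SNP alleles (DNA and RNA) and editing events (RNA only) into the
#' reads, applies uniform per-base sequencing errors with matching Phred
#' qualities, and emits hyper-edited transcript reads over each planted
#' cluster. Any read whose mismatch count against the reference exceeds
#' `aligner_mismatch_cap` becomes an unaligned record (flag 4), emulating
#' the aligner failure that motivates transformed realignment; all other
#' reads are emitted pre-aligned at their true coordinates with ungapped
#' CIGARs.
#'
#' @param ref a `reference_bundle`.
#' @param truth a `scenario_truth` from [plant_truth()].
#' @param params a [read_sim_params()].
#' @param condition condition label (must appear in the truth table's
#'   `level_*` columns).
#' @param replicate replicate number.
#' @param what which libraries to simulate, subset of `c("rna", "dna")`.
#' @return a list with `rna` and/or `dna` read tables (columns `qname`,
#'   `flag`, `chrom`, `pos`, `mapq`, `cigar`, `seq`, `qual`; unmapped reads
#'   have flag 4, `chrom` `"*"`, `pos` 0 and as-sequenced orientation) and
#'   `counts`, the per-library read accounting.
#' @export
simulate_reads <- function(ref, truth, params, condition, replicate = 1L,
                           what = c("rna", "dna")) {
  stopifnot(inherits(ref, "reference_bundle"),
            inherits(params, "read_sim_params"))
  lc <- paste0("level_", condition)
  if (!lc %in% names(truth))
    stop("condition ", condition, " not present in truth table",
         call. = FALSE)
  truth <- as.data.table(truth)
  rl <- params$read_length
  qual1 <- strrep(phred_char(params$base_error_rate), rl)
  out <- list()

  widths <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  offs <- setNames(cumsum(c(0, widths[-length(widths)])), names(widths))

  if ("rna" %in% what) {
    set.seed(derive_seed(params$seed, condition, replicate, 1L))
    units <- ref$tx_units[end - start + 1L >= rl]
    n_u <- pmax(0L, as.integer(round(params$coverage_rna *
                                       (units$end - units$start + 1L) / rl)))
    ridx <- rep(seq_len(nrow(units)), n_u)
    pos <- units$start[ridx] +
      floor(runif(length(ridx)) *
              (units$end[ridx] - units$start[ridx] - rl + 2L))
    reads <- data.table(chrom = units$chrom[ridx], pos = as.integer(pos),
                        tx_strand = units$strand[ridx],
                        cluster_id = NA_character_)
    # hyper-edited transcript reads over each planted cluster
    hy <- truth[kind == "hyper"]
    if (nrow(hy)) {
      cl <- hy[, .(chrom = chrom[1], strand = strand[1], minp = min(pos),
                   maxp = max(pos)), by = cluster_id]
      m <- params$reads_per_cluster
      cridx <- rep(seq_len(nrow(cl)), each = m)
      lo <- cl$maxp[cridx] - rl + 1L
      hi <- cl$minp[cridx]
      cpos <- lo + floor(runif(length(cridx)) * (hi - lo + 1L))
      reads <- rbind(reads,
                     data.table(chrom = cl$chrom[cridx],
                                pos = as.integer(cpos),
                                tx_strand = cl$strand[cridx],
                                cluster_id = cl$cluster_id[cridx]))
    }
    reads[, seq := extract_seq(ref, chrom, pos, rl)]
    vars <- rbind(
      truth[kind == "snp",
            .(chrom, pos, alt = alt_fwd,
              prob = fifelse(genotype == "hom", 1, 0.5),
              cluster_id = NA_character_)],
      truth[kind == "edit",
            .(chrom, pos, alt = alt_fwd, prob = get(lc),
              cluster_id = NA_character_)],
      truth[kind == "hyper",
            .(chrom, pos, alt = alt_fwd, prob = get(lc), cluster_id)])
    nmm <- apply_variants(reads, vars, offs, rl, match_cluster = TRUE)
    nmm <- nmm + apply_errors(reads, rl, params$base_error_rate)
    unmapped <- nmm > params$aligner_mismatch_cap
    reads[, flag := fifelse(tx_strand == "-", 16L, 0L)]
    if (params$protocol == "reverse")
      reads[, flag := fifelse(flag == 16L, 0L, 16L)]
    # unaligned records carry the as-sequenced orientation
    if (any(unmapped)) {
      rc <- unmapped & reads$flag == 16L
      reads[rc, seq := revcomp_chr(seq)]
      reads[unmapped, `:=`(flag = 4L, chrom = "*", pos = 0L)]
    }
    reads[, `:=`(qname = sprintf("rna_%s_r%d_%07d", condition, replicate,
                                 seq_len(.N)),
                 mapq = fifelse(flag == 4L, 0L, params$mapq),
                 cigar = fifelse(flag == 4L, "*", paste0(rl, "M")),
                 qual = qual1)]
    out$rna <- reads[, .(qname, flag, chrom, pos, mapq, cigar, seq, qual,
                         tx_strand, cluster_id)]
    out$counts <- list(rna_total = nrow(reads),
                       rna_unmapped = sum(unmapped))
  }

  if ("dna" %in% what) {
    set.seed(derive_seed(params$seed, condition, replicate, 2L))
    n_d <- as.integer(round(params$coverage_dna * widths / rl))
    ridx <- rep(seq_along(widths), n_d)
    pos <- 1L + floor(runif(length(ridx)) * (widths[ridx] - rl + 1L))
    dna <- data.table(chrom = names(widths)[ridx], pos = as.integer(pos),
                      tx_strand = "*", cluster_id = NA_character_)
    dna[, seq := extract_seq(ref, chrom, pos, rl)]
    vars <- truth[kind == "snp",
                  .(chrom, pos, alt = alt_fwd,
                    prob = fifelse(genotype == "hom", 1, 0.5),
                    cluster_id = NA_character_)]
    apply_variants(dna, vars, offs, rl, match_cluster = FALSE)
    apply_errors(dna, rl, params$base_error_rate)
    dna[, flag := sample(c(0L, 16L), .N, replace = TRUE)]
    dna[, `:=`(qname = sprintf("dna_%s_r%d_%07d", condition, replicate,
                               seq_len(.N)),
               mapq = params$mapq, cigar = paste0(rl, "M"), qual = qual1)]
    out$dna <- dna[, .(qname, flag, chrom, pos, mapq, cigar, seq, qual)]
    out$counts <- c(out$counts, list(dna_total = nrow(dna)))
  }
  out
}

extract_seq <- function(ref, chrom, pos, rl) {
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    out[i] <- substring(ref$genome_chr[[cn]], pos[i], pos[i] + rl - 1L)
  }
  out
}

# plant variant alleles into reads (in place); returns per-read count of
# introduced mismatches
apply_variants <- function(reads, vars, offs, rl, match_cluster) {
  nmm <- integer(nrow(reads))
  if (!nrow(vars) || !nrow(reads)) return(nmm)
  mapped <- which(reads$chrom != "*")
  rq <- IRanges::IRanges(offs[reads$chrom[mapped]] + reads$pos[mapped],
                         width = rl)
  vq <- IRanges::IRanges(offs[vars$chrom] + vars$pos, width = 1L)
  hits <- IRanges::findOverlaps(vq, rq)
  if (!length(hits)) return(nmm)
  pr <- data.table(v = S4Vectors::queryHits(hits),
                   r = mapped[S4Vectors::subjectHits(hits)])
  if (match_cluster) {
    vcl <- vars$cluster_id[pr$v]
    pr <- pr[is.na(vcl) | (!is.na(reads$cluster_id[pr$r]) &
                             vcl == reads$cluster_id[pr$r])]
  }
  if (!nrow(pr)) return(nmm)
  pr <- pr[runif(nrow(pr)) < vars$prob[pr$v]]
  if (!nrow(pr)) return(nmm)
  pr[, offset := vars$pos[v] - reads$pos[r] + 1L]
  pr[, rnd := seq_len(.N), by = r]
  for (k in seq_len(max(pr$rnd))) {
    sub <- pr[rnd == k]
    s <- reads$seq[sub$r]
    substr(s, sub$offset, sub$offset) <- vars$alt[sub$v]
    reads[sub$r, seq := s]
  }
  tab <- pr[, .N, by = r]
  nmm[tab$r] <- tab$N
  nmm
}

# uniform per-base substitution errors (in place); returns per-read count
apply_errors <- function(reads, rl, error_rate) {
  ne <- integer(nrow(reads))
  if (error_rate <= 0 || !nrow(reads)) return(ne)
  ne <- rbinom(nrow(reads), rl, error_rate)
  hit <- which(ne > 0L)
  if (!length(hit)) return(ne)
  pr <- data.table(r = rep(hit, ne[hit]))
  pr[, offset := 1L + floor(runif(.N) * rl)]
  pr <- unique(pr, by = c("r", "offset"))
  cur <- substring(reads$seq[pr$r], pr$offset, pr$offset)
  shift <- 1L + floor(runif(nrow(pr)) * 3L)
  new <- BASES[((match(cur, BASES) - 1L + shift) %% 4L) + 1L]
  pr[, rnd := seq_len(.N), by = r]
  for (k in seq_len(max(pr$rnd))) {
    i <- pr$rnd == k
    s <- reads$seq[pr$r[i]]
    substr(s, pr$offset[i], pr$offset[i]) <- new[i]
    reads[pr$r[i], seq := s]
  }
  ne
}
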