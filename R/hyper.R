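#' Realign unmapped reads in A-to-G transformed space
#'
#' Recovers hyper-edited reads that fail normal alignment: every A in the
#' read and in the reference is rewritten to G, erasing A-to-G mismatches,
#' and the transformed read is realigned by exact k-mer seeding with
#' ungapped extension. Reads from minus-strand transcripts are handled by
#' reverse-complementing the read and matching in T-to-C transformed
#' genome space, so strandedness is preserved through the transform. A hit
#' is reported only when it is unique across both transformed strands and
#' carries at most `max_other_mm` non-A-to-G mismatches; recovered edit
#' positions are the reference-A (transcript strand) positions where the
#' original read shows the edited base.
#'
#' @param reads a read table; only unmapped records (flag 4, as-sequenced
#'   orientation) are used.
#' @param ref a `reference_bundle`.
#' @param k seed length for exact k-mer seeding.
#' @param max_other_mm maximum allowed non-A-to-G mismatches.
#' @return a `hyper_read_hits` list: `hits`, a data.table with one row per
#'   realigned read (`read_id`, `chrom`, `pos`, `strand`, `n_AtoG`,
#'   `n_other`, `n_A_span`, `L`) with recovered genomic edit positions in
#'   the list column `edit_pos`; and `n_unplaced`, the count of reads
#'   without a unique transformed alignment.
#' @export
transform_and_realign <- function(reads, ref, k = 16L, max_other_mm = 1L) {
  reads <- as.data.table(reads)
  um <- reads[bitwAnd(flag, 4L) != 0L]
  empty <- data.table(read_id = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      n_AtoG = integer(0), n_other = integer(0),
                      n_A_span = integer(0), L = integer(0),
                      edit_pos = list())
  if (!nrow(um)) return(list(hits = empty, n_unplaced = 0L))

  genome_ag <- vapply(ref$genome_chr, chartr, character(1),
                      old = "A", new = "G")
  genome_tc <- vapply(ref$genome_chr, chartr, character(1),
                      old = "T", new = "C")

  # plus-strand transcripts: transformed read vs A->G genome
  q_plus <- chartr("A", "G", um$seq)
  # minus-strand transcripts: reverse complement matches the forward
  # genome, with edits appearing as T->C; transform both with T->C
  rc <- revcomp_chr(um$seq)
  q_minus <- chartr("T", "C", rc)

  aln_p <- seed_extend_align(q_plus, genome_ag, k = k)
  aln_m <- seed_extend_align(q_minus, genome_tc, k = k)
  aln <- rbind(aln_p[, .(read, chrom, start, score, L, strand = "+")],
               aln_m[, .(read, chrom, start, score, L, strand = "-")])
  if (!nrow(aln)) return(list(hits = empty, n_unplaced = nrow(um)))
  aln[, n_other := L - score]
  aln <- aln[n_other <= max_other_mm]
  # unique-hit requirement across both transformed strands
  aln[, n_hits := .N, by = read]
  aln <- aln[n_hits == 1L]
  if (!nrow(aln)) return(list(hits = empty, n_unplaced = nrow(um)))

  hits <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    a <- aln[i]
    gsub_raw <- charToRaw(substring(ref$genome_chr[[a$chrom]], a$start,
                                    a$start + a$L - 1L))
    qraw <- if (a$strand == "+") charToRaw(um$seq[a$read]) else
      charToRaw(rc[a$read])
    if (a$strand == "+") {
      is_ref_a <- gsub_raw == charToRaw("A")
      is_edit <- is_ref_a & qraw == charToRaw("G")
    } else {
      is_ref_a <- gsub_raw == charToRaw("T")
      is_edit <- is_ref_a & qraw == charToRaw("C")
    }
    hits[[i]] <- data.table(
      read_id = um$qname[a$read], chrom = a$chrom, pos = a$start,
      strand = a$strand, n_AtoG = sum(is_edit), n_other = a$n_other,
      n_A_span = sum(is_ref_a), L = a$L,
      edit_pos = list(a$start - 1L + which(is_edit)))
  }
  list(hits = rbindlist(hits), n_unplaced = nrow(um) - nrow(aln))
}

#' Cluster filter and aggregation of hyper-edited reads
#'
#' Retains realigned reads with at least `min_edits_per_read` recovered
#' A-to-G edits whose edit fraction over the adenosines in the aligned
#' span reaches `min_edit_fraction`, then aggregates the surviving reads
#' into per-position hyper-edited sites (mode `"hyper"`). The edited count
#' G at a position is the number of retained reads edited there and A the
#' number of retained reads covering it unedited.
#'
#' @param hyper_hits output of [transform_and_realign()].
#' @param ref a `reference_bundle`.
#' @param min_edits_per_read minimum recovered edits per read.
#' @param min_edit_fraction minimum `n_AtoG / adenosines-in-span`.
#' @return an `edit_site` data.table with `mode = "hyper"`.
#' @export
cluster_filter <- function(hyper_hits, ref, min_edits_per_read = 5L,
                           min_edit_fraction = 0.05) {
  hits <- as.data.table(hyper_hits$hits)
  empty <- data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), ref_tx = character(0),
                      alt_tx = character(0), ref_fwd = character(0),
                      alt_fwd = character(0), edit_type = character(0),
                      G = integer(0), A = integer(0), depth = integer(0),
                      level = numeric(0), mode = character(0))
  if (!nrow(hits)) return(empty[])
  keep <- hits[n_AtoG >= min_edits_per_read &
                 n_AtoG / pmax(n_A_span, 1L) >= min_edit_fraction]
  if (!nrow(keep)) return(empty[])
  keep[, rid := .I]
  edited <- keep[, .(pos = edit_pos[[1]]), by = .(rid, chrom, strand)]
  ecnt <- edited[, .(G = .N), by = .(chrom, pos, strand)]
  # coverage: retained reads whose span includes the position, at
  # transcript-strand adenosines recovered in any read
  cov <- keep[, .(chrom, strand, start = pos, end = pos + L - 1L)]
  ov <- point_overlaps(ecnt$chrom, ecnt$pos,
                       cov[, .(chrom, start, end)])
  ov <- ov[ecnt$strand[from] == cov$strand[to]]
  tot <- ov[, .N, by = from]
  ecnt[tot$from, depth := tot$N]
  ecnt[, `:=`(A = depth - G, level = G / depth,
              ref_tx = "A", alt_tx = "G",
              ref_fwd = fifelse(strand == "-", "T", "A"),
              alt_fwd = fifelse(strand == "-", "C", "G"),
              edit_type = "A-to-G", mode = "hyper")]
  setorder(ecnt, chrom, pos)
  ecnt[, .(chrom, pos, strand, ref_tx, alt_tx, ref_fwd, alt_fwd, edit_type,
           G, A, depth, level, mode)]
}

#' Merge normal and hyper edit-site tables
#'
#' Sites detected by both routes become `mode = "common"` and are counted
#' once (normal-route counts are kept for the level). Sites whose alternate
#' base conflicts between the two routes are excluded and reported. The
#' returned overlap counts satisfy inclusion-exclusion exactly:
#' `union = normal_only + hyper_only + common`.
#'
#' @param res normal-mode edit-site table ([call_sites()]).
#' @param rhes hyper-mode edit-site table ([cluster_filter()]).
#' @return a list with `sites` (unified table), `overlap` (named counts
#'   `normal_only`, `hyper_only`, `common`, `union`) and `n_conflicting`.
#' @export
merge_modes <- function(res, rhes) {
  res <- as.data.table(res)
  rhes <- as.data.table(rhes)
  res[, key := site_key(chrom, pos, strand)]
  rhes[, key := site_key(chrom, pos, strand)]
  shared <- intersect(res$key, rhes$key)
  conflict <- res[key %in% shared][rhes[key %in% shared, .(key, alt_tx)],
                                   on = "key"][alt_tx != i.alt_tx, key]
  shared_ok <- setdiff(shared, conflict)
  out <- rbind(
    res[!key %in% conflict][, mode := fifelse(key %in% shared_ok, "common",
                                              "normal")],
    rhes[!key %in% c(shared, conflict)],
    fill = TRUE)
  setorder(out, chrom, pos)
  overlap <- c(normal_only = sum(out$mode == "normal"),
               hyper_only = sum(out$mode == "hyper"),
               common = sum(out$mode == "common"))
  overlap["union"] <- sum(overlap)
  out[, key := NULL]
  list(sites = out[], overlap = overlap,
       n_conflicting = length(conflict))
}
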