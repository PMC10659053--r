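#' Classify a mismatch into one of the 12 edit types
#'
#' Edit types are reported in transcript orientation: a genome-strand T-to-C
#' mismatch under a minus-strand transcript is the canonical A-to-G (A-to-I)
#' type, while the same genomic change under a plus-strand transcript is
#' T-to-C.
#'
#' @param ref_base,alt_base genome-forward reference and alternate bases.
#' @param strand transcript strand (`"+"`, `"-"`); `"*"` routes the site to
#'   an unstranded bucket (`NA` type) excluded from motif analyses.
#' @return character vector of types such as `"A-to-G"`.
#' @export
classify_type <- function(ref_base, alt_base, strand) {
  r <- ifelse(strand == "-", comp_base(ref_base), ref_base)
  a <- ifelse(strand == "-", comp_base(alt_base), alt_base)
  ifelse(strand %in% c("+", "-"), paste0(r, "-to-", a), NA_character_)
}

#' Call candidate normal editing sites from an RNA pileup
#'
#' A site is called when it is callable in DNA and not in the SNP mask, its
#' filtered RNA depth reaches `min_rna_depth`, exactly one alternate base
#' is observed (a second alternate counts as observed at
#' `multi_allele_min` reads or more), the alternate is supported by at
#' least `min_edited_reads` reads, and the one-sided binomial tail
#' probability of the alternate count against the sequencing error rate
#' survives Benjamini-Hochberg correction at `fdr` across all candidates.
#' Counts and types are reported in transcript orientation; the editing
#' level is `G/(G+A)` with G the alternate and A the reference read count.
#'
#' @param rna_pileup an RNA `site_pileup` (transcript-oriented counts).
#' @param ref a `reference_bundle`.
#' @param snp_mask a `snp_mask` from [mask_dna_variants()], or `NULL` to
#'   skip DNA-based filtering (all positions treated as callable).
#' @param min_rna_depth minimum filtered RNA depth.
#' @param min_edited_reads minimum alternate-read support.
#' @param error_rate per-base error rate for the binomial test (> 0).
#' @param fdr BH threshold over candidate sites.
#' @param multi_allele_min read support at which a second alternate base
#'   triggers the multi-allele exclusion.
#' @return an `edit_site` data.table sorted by (chrom, pos): columns
#'   `chrom`, `pos`, `strand`, `ref_tx`, `alt_tx`, `ref_fwd`, `alt_fwd`,
#'   `edit_type`, `G`, `A`, `depth`, `level`, `p.value`, `q.value`,
#'   `mode = "normal"`.
#' @export
call_sites <- function(rna_pileup, ref, snp_mask = NULL, min_rna_depth = 10L,
                       min_edited_reads = 3L, error_rate = 0.001,
                       fdr = 0.05, multi_allele_min = 2L) {
  if (error_rate <= 0) stop("error_rate must be > 0", call. = FALSE)
  pp <- as.data.table(rna_pileup)
  empty <- data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), ref_tx = character(0),
                      alt_tx = character(0), ref_fwd = character(0),
                      alt_fwd = character(0), edit_type = character(0),
                      G = integer(0), A = integer(0), depth = integer(0),
                      level = numeric(0), p.value = numeric(0),
                      q.value = numeric(0), mode = character(0))
  if (!nrow(pp)) return(empty[])
  pp <- pp[depth >= min_rna_depth]
  if (!is.null(snp_mask)) {
    pp <- pp[site_key(chrom, pos, "*") %in%
               site_key(snp_mask$callable$chrom, snp_mask$callable$pos, "*")]
    pp <- pp[!site_key(chrom, pos, "*") %in%
               site_key(snp_mask$masked$chrom, snp_mask$masked$pos, "*")]
  }
  if (!nrow(pp)) return(empty[])
  # transcript-strand reference base; counts are already transcript-oriented
  pp[, ref_tx := ref_base_at(ref, chrom, pos, strand)]
  cm <- as.matrix(pp[, .(A, C, G, T)])
  ii <- seq_len(nrow(cm))
  ridx <- match(pp$ref_tx, BASES)
  cm_alt <- replace(cm, cbind(ii, ridx), 0L)
  i1 <- max.col(cm_alt, ties.method = "first")
  alt1 <- cm_alt[cbind(ii, i1)]
  cm2 <- replace(cm_alt, cbind(ii, i1), -1L)
  alt2 <- pmax(cm2[cbind(ii, max.col(cm2, ties.method = "first"))], 0L)
  pp[, `:=`(ref_count = cm[cbind(ii, ridx)],
            alt_count = alt1,
            alt_tx = BASES[i1],
            second_alt = alt2)]
  cand <- pp[alt_count >= min_edited_reads & second_alt < multi_allele_min]
  if (!nrow(cand)) return(empty[])
  cand[, p.value := pbinom(alt_count - 1L, depth, error_rate,
                           lower.tail = FALSE)]
  cand[, q.value := bh_fdr(p.value)]
  cand <- cand[q.value <= fdr]
  if (!nrow(cand)) return(empty[])
  cand[, `:=`(
    ref_fwd = fifelse(strand == "-", comp_base(ref_tx), ref_tx),
    alt_fwd = fifelse(strand == "-", comp_base(alt_tx), alt_tx),
    edit_type = paste0(ref_tx, "-to-", alt_tx),
    G = alt_count, A = ref_count,
    level = alt_count / (alt_count + ref_count),
    mode = "normal")]
  setorder(cand, chrom, pos)
  cand[, .(chrom, pos, strand, ref_tx, alt_tx, ref_fwd, alt_fwd, edit_type,
           G, A, depth, level, p.value, q.value, mode)]
}

#' Write an edit-site table as TSV or VCF
#'
#' The VCF export writes genome-forward REF/ALT with the transcript strand,
#' edit type, counts, level and detection mode in INFO.
#'
#' @param sites an edit-site table.
#' @param path output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return invisibly, `path`.
#' @export
write_sites <- function(sites, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  sites <- as.data.table(sites)
  if (format == "tsv") {
    fwrite(sites, path, sep = "\t", quote = FALSE, na = "NA")
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcript strand\">",
             "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Edit type (transcript orientation)\">",
             "##INFO=<ID=EDITED,Number=1,Type=Integer,Description=\"Edited (G) read count\">",
             "##INFO=<ID=REFCNT,Number=1,Type=Integer,Description=\"Reference (A) read count\">",
             "##INFO=<ID=LEVEL,Number=1,Type=Float,Description=\"Editing level G/(G+A)\">",
             "##INFO=<ID=MODE,Number=1,Type=String,Description=\"Detection mode\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tSTRAND=%s;TYPE=%s;EDITED=%d;REFCNT=%d;LEVEL=%.6g;MODE=%s",
      sites$chrom, sites$pos, sites$ref_fwd, sites$alt_fwd, sites$strand,
      sites$edit_type, sites$G, sites$A, sites$level, sites$mode)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
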