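.FEATURE_RANK <- c(CDS = 1L, five_prime_utr = 2L, three_prime_utr = 2L,
                   intron = 3L)

# winning feature row index per point under CDS > UTR > intron precedence,
# requiring strand agreement for genic features ("*" matches any strand)
winning_feature <- function(ref, chrom, pos, strand) {
  n <- length(pos)
  ans <- rep(NA_integer_, n)
  if (!nrow(ref$features)) return(ans)
  ov <- point_overlaps(chrom, pos, ref$features)
  if (!nrow(ov)) return(ans)
  ov[, `:=`(fs = ref$features$strand[to],
            rank = .FEATURE_RANK[ref$features$type[to]])]
  ov <- ov[strand[from] == "*" | fs == strand[from]]
  if (!nrow(ov)) return(ans)
  setorder(ov, from, rank)
  best <- ov[!duplicated(from)]
  ans[best$from] <- best$to
  ans
}

#' Genomic feature class at positions
#'
#' Assigns each (position, transcript strand) to exactly one of
#' `CDS`, `five_prime_utr`, `three_prime_utr`, `intron` or `intergenic`,
#' resolving overlapping transcripts by the precedence
#' CDS > UTR > intron > intergenic. Genic classes require the feature to lie
#' on the site's transcript strand; strand `"*"` matches either.
#'
#' @param ref a `reference_bundle`.
#' @param chrom,pos,strand vectors describing the sites.
#' @return character vector of feature classes.
#' @export
feature_at <- function(ref, chrom, pos, strand) {
  idx <- winning_feature(ref, chrom, pos, strand)
  out <- rep("intergenic", length(pos))
  hit <- !is.na(idx)
  out[hit] <- ref$features$type[idx[hit]]
  out
}

#' Annotate edit sites with feature class, repeat/TE overlap and CDS effect
#'
#' Each site receives one feature class (precedence CDS > UTR > intron >
#' intergenic); CDS sites are subdivided into synonymous and non-synonymous
#' via the codon-consequence annotator, using the transcript that supplied
#' the winning CDS feature. Repeat and TE flags record overlap with the
#' repeat interval set and its TE subset.
#'
#' @param sites an edit-site table with `chrom`, `pos`, `strand` columns.
#' @param ref a `reference_bundle`.
#' @return a list with `sites` (the annotated table, extra columns
#'   `feature`, `tx_id`, `consequence`, `repeat_flag`, `te_flag`) and
#'   `fractions`, the named per-class site fractions over
#'   `five_prime_utr`, `CDS-syn`, `CDS-nonsyn`, `intron`, `intergenic`,
#'   `three_prime_utr` (summing to 1).
#' @export
annotate_features <- function(sites, ref) {
  sites <- as.data.table(sites)
  widths <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  if (any(sites$pos < 1L | sites$pos > widths[sites$chrom]))
    stop("site beyond chromosome bounds", call. = FALSE)
  idx <- winning_feature(ref, sites$chrom, sites$pos, sites$strand)
  sites[, feature := fifelse(is.na(idx), "intergenic",
                             ref$features$type[idx])]
  sites[, tx_id := fifelse(is.na(idx), NA_character_,
                           ref$features$tx_id[idx])]
  sites[, consequence := NA_character_]
  cds <- which(sites$feature == "CDS")
  if (length(cds)) {
    ev <- codon_consequence(sites[cds], ref)
    cons <- ev$consequence[match(site_key(sites$chrom[cds], sites$pos[cds],
                                          sites$strand[cds]),
                                 site_key(ev$chrom, ev$pos, ev$strand))]
    sites[cds, consequence := cons]
    sites[cds, feature := fifelse(cons == "synonymous", "CDS-syn",
                                  "CDS-nonsyn")]
  }
  sites[, `:=`(repeat_flag = FALSE, te_flag = FALSE)]
  if (nrow(ref$repeats)) {
    ov <- point_overlaps(sites$chrom, sites$pos, ref$repeats)
    sites[unique(ov$from), repeat_flag := TRUE]
    sites[unique(ov$from[ref$repeats$te[ov$to]]), te_flag := TRUE]
  }
  classes <- c("five_prime_utr", "CDS-syn", "CDS-nonsyn", "intron",
               "intergenic", "three_prime_utr")
  fr <- prop.table(table(factor(sites$feature, levels = classes)))
  list(sites = sites[], fractions = setNames(as.numeric(fr), classes))
}
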