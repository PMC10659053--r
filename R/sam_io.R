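#' Write a read table as SAM
#'
#' Emits a plain-text SAM file (1-based POS, ungapped CIGARs as produced by
#' the simulator) with a header derived from the reference. Unmapped reads
#' (flag 4) are written with `RNAME *` and `POS 0`.
#'
#' @param reads a read table (`qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`).
#' @param ref a `reference_bundle` supplying the `@SQ` header lines.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(reads, ref, path) {
  reads <- as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
                   Biostrings::width(ref$genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag,
                  ifelse(reads$chrom == "*" | is.na(reads$chrom), "*",
                         reads$chrom),
                  ifelse(is.na(reads$pos), 0L, reads$pos),
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM/BAM file into a read table
#'
#' Uses [Rsamtools] to parse the file (SAM input is converted to BAM in a
#' temporary location first). Unmapped records are retained with
#' `chrom = "*"` and `pos = 0`.
#'
#' @param path a SAM or BAM file.
#' @return a data.table with columns `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`.
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq", "qual"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.table(
    qname = x$qname,
    flag = as.integer(x$flag),
    chrom = fifelse(is.na(as.character(x$rname)), "*",
                    as.character(x$rname)),
    pos = fifelse(is.na(x$pos), 0L, x$pos),
    mapq = fifelse(is.na(x$mapq), 0L, as.integer(x$mapq)),
    cigar = fifelse(is.na(x$cigar), "*", x$cigar),
    seq = as.character(x$seq),
    qual = as.character(x$qual)
  )
}
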