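#' Specify a synthetic genome
#'
#' Defines the layout of a small synthetic genome used to exercise the
#' editome pipeline: random sequence with a given GC content, a set of
#' non-overlapping protein-coding gene models (5'UTR, multi-exon CDS,
#' introns, 3'UTR) on both strands, and repeat/TE intervals covering a
#' chosen fraction of the intergenic space.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gc_content genomic GC fraction in `[0, 1]`.
#' @param n_genes total number of genes across chromosomes.
#' @param exons_per_gene number of CDS exons per gene.
#' @param utr5_length,cds_length,intron_length,utr3_length feature lengths in
#'   bp; `cds_length` must be divisible by 3.
#' @param te_fraction fraction of intergenic bp annotated as repeat.
#' @param te_subfraction fraction of repeat intervals flagged as TE (the
#'   remainder are non-TE repeats, e.g. simple repeats).
#' @param min_intergenic minimum intergenic gap between genes in bp.
#' @param seed integer seed; identical specs yield byte-identical references.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chroms = 1L, chrom_length = 200000L,
                        gc_content = 0.42, n_genes = 20L,
                        exons_per_gene = 3L, utr5_length = 200L,
                        cds_length = 1200L, intron_length = 400L,
                        utr3_length = 500L, te_fraction = 0.35,
                        te_subfraction = 0.7, min_intergenic = 1000L,
                        seed = 7L) {
  spec <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    gc_content = gc_content, n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    utr5_length = as.integer(utr5_length), cds_length = as.integer(cds_length),
    intron_length = as.integer(intron_length),
    utr3_length = as.integer(utr3_length), te_fraction = te_fraction,
    te_subfraction = te_subfraction, min_intergenic = as.integer(min_intergenic),
    seed = as.integer(seed)
  )
  lens <- c(spec$chrom_length, spec$utr5_length, spec$cds_length,
            spec$intron_length, spec$utr3_length)
  if (any(lens <= 0L)) stop("all lengths must be > 0", call. = FALSE)
  if (spec$n_chroms < 1L || spec$n_genes < 1L || spec$exons_per_gene < 1L)
    stop("n_chroms, n_genes and exons_per_gene must be >= 1", call. = FALSE)
  if (spec$cds_length %% 3L != 0L)
    stop("cds_length must be divisible by 3 (got ", spec$cds_length, ")",
         call. = FALSE)
  if (spec$gc_content < 0 || spec$gc_content > 1 ||
      spec$te_fraction < 0 || spec$te_fraction > 1)
    stop("gc_content and te_fraction must lie in [0, 1]", call. = FALSE)
  structure(spec, class = "genome_spec")
}

gene_span_length <- function(spec) {
  spec$utr5_length + spec$cds_length +
    (spec$exons_per_gene - 1L) * spec$intron_length + spec$utr3_length
}

#' Build a synthetic reference bundle
#'
#' Generates the genome sequence, gene models, repeat intervals and the
#' transcription-unit map from a [genome_spec()]. The transcription units
#' (gene pre-mRNAs plus strand-assigned intergenic units, e.g. lincRNA-like
#' transcription) tile each chromosome and define where stranded RNA-seq
#' reads are drawn from, so that intronic and intergenic positions receive
#' strand-resolved RNA coverage as they do in a real total editome.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `reference_bundle`: a list with elements
#'   `genome` ([Biostrings::DNAStringSet]), `genome_chr` (character vector per
#'   chromosome), `genes`, `features`, `repeats`, `tx_units` (data.tables)
#'   and `spec`.
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  gc <- spec$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  span <- gene_span_length(spec)
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  genes_per_chrom <- tabulate(rep_len(seq_len(spec$n_chroms), spec$n_genes),
                              nbins = spec$n_chroms)

  genome_chr <- character(spec$n_chroms)
  genes <- vector("list", spec$n_chroms)
  features <- vector("list", spec$n_chroms)
  repeats <- vector("list", spec$n_chroms)
  units <- vector("list", spec$n_chroms)
  gene_counter <- 0L

  for (ci in seq_len(spec$n_chroms)) {
    k <- genes_per_chrom[ci]
    need <- k * span + (k + 1L) * spec$min_intergenic
    if (need > spec$chrom_length)
      stop("features exceed chromosome length: need ", need, " bp but ",
           "chrom_length is ", spec$chrom_length, call. = FALSE)
    genome_chr[ci] <- paste(sample(BASES, spec$chrom_length, replace = TRUE,
                                   prob = base_prob), collapse = "")

    extra <- spec$chrom_length - k * span - (k + 1L) * spec$min_intergenic
    gaps <- rep(spec$min_intergenic, k + 1L)
    if (extra > 0L)
      gaps <- gaps + as.vector(rmultinom(1L, extra, rep(1, k + 1L)))

    # gene i starts after the first i gaps and i-1 gene spans
    gstart <- cumsum(gaps)[seq_len(k)] + (seq_len(k) - 1L) * span + 1L
    strands <- if (k) sample(c("+", "-"), k, replace = TRUE) else character(0)

    feat_list <- vector("list", k)
    gene_rows <- vector("list", k)
    for (gi in seq_len(k)) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("gene%03d", gene_counter)
      tid <- paste0(gid, "_t1")
      st <- gstart[gi]
      feat_list[[gi]] <- build_gene_features(spec, chroms[ci], gid, tid,
                                             st, strands[gi])
      gene_rows[[gi]] <- data.table(
        gene_id = gid, tx_id = tid, chrom = chroms[ci], strand = strands[gi],
        start = st, end = st + span - 1L
      )
    }
    genes[[ci]] <- rbindlist(gene_rows)
    features[[ci]] <- rbindlist(feat_list)

    # intergenic gaps (including chromosome ends) become repeat space and
    # strand-assigned intergenic transcription units
    gap_start <- c(1L, genes[[ci]]$end + 1L)
    gap_end <- c(genes[[ci]]$start - 1L, spec$chrom_length)
    gap_dt <- data.table(start = gap_start, end = gap_end)[end >= start]
    repeats[[ci]] <- place_repeats(gap_dt, chroms[ci], spec)
    ig_units <- gap_dt[, .(chrom = chroms[ci], start, end,
                           strand = sample(c("+", "-"), .N, replace = TRUE),
                           kind = "intergenic")]
    g_units <- genes[[ci]][, .(chrom, start, end, strand, kind = "gene",
                               unit_id = gene_id)]
    ig_units[, unit_id := sprintf("%s_ig%02d", chroms[ci], seq_len(.N))]
    units[[ci]] <- rbind(g_units, ig_units, use.names = TRUE)
  }

  genome <- Biostrings::DNAStringSet(genome_chr)
  names(genome) <- chroms
  bundle <- structure(list(
    genome = genome,
    genome_chr = setNames(genome_chr, chroms),
    genes = rbindlist(genes),
    features = rbindlist(features),
    repeats = rbindlist(repeats),
    tx_units = setorder(rbindlist(units, fill = TRUE), chrom, start),
    spec = spec
  ), class = "reference_bundle")
  bundle
}

# genomic feature rows for a single gene model; coordinates 1-based closed
build_gene_features <- function(spec, chrom, gid, tid, start, strand) {
  e <- spec$exons_per_gene
  cds_sizes <- rep(spec$cds_length %/% e, e)
  cds_sizes[e] <- cds_sizes[e] + spec$cds_length %% e
  # transcript-order block types and sizes (5' -> 3')
  types <- c("five_prime_utr",
             as.vector(rbind(rep("CDS", e), rep("intron", e)))[seq_len(2L * e - 1L)],
             "three_prime_utr")
  sizes <- c(spec$utr5_length,
             as.vector(rbind(cds_sizes, rep(spec$intron_length, e)))[seq_len(2L * e - 1L)],
             spec$utr3_length)
  if (strand == "-") { types <- rev(types); sizes <- rev(sizes) }
  ends <- start - 1L + cumsum(sizes)
  starts <- ends - sizes + 1L
  dt <- data.table(gene_id = gid, tx_id = tid, chrom = chrom, strand = strand,
                   type = types, start = starts, end = ends)
  # exon_rank in transcript order for CDS blocks
  cds_idx <- which(dt$type == "CDS")
  if (strand == "-") cds_idx <- rev(cds_idx)
  dt[, exon_rank := NA_integer_]
  dt[cds_idx, exon_rank := seq_along(cds_idx)]
  dt
}

# distribute non-overlapping repeat intervals over intergenic gaps so that
# repeat bp / intergenic bp ~= te_fraction
place_repeats <- function(gap_dt, chrom, spec, unit_len = 300L) {
  if (!nrow(gap_dt) || spec$te_fraction <= 0)
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), te = logical(0)))
  out <- vector("list", nrow(gap_dt))
  for (i in seq_len(nrow(gap_dt))) {
    glen <- gap_dt$end[i] - gap_dt$start[i] + 1L
    target <- round(glen * spec$te_fraction)
    m <- target %/% unit_len
    last <- target - m * unit_len
    lens <- c(rep(unit_len, m), if (last >= 30L) last)
    if (!length(lens)) { out[[i]] <- NULL; next }
    m <- length(lens)
    slack <- glen - sum(lens)
    spacers <- as.vector(rmultinom(1L, slack, rep(1, m + 1L)))
    starts <- gap_dt$start[i] + cumsum(spacers[seq_len(m)]) +
      cumsum(c(0L, lens[-m]))
    out[[i]] <- data.table(chrom = chrom, start = as.integer(starts),
                           end = as.integer(starts + lens - 1L))
  }
  rep_dt <- rbindlist(out)
  if (!nrow(rep_dt)) rep_dt[, te := logical(0)] else
    rep_dt[, te := runif(.N) < spec$te_subfraction]
  rep_dt[]
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("reference_bundle:", length(x$genome), "chromosome(s),",
      sum(Biostrings::width(x$genome)), "bp\n")
  cat("  genes:", nrow(x$genes), " repeat intervals:", nrow(x$repeats),
      " transcription units:", nrow(x$tx_units), "\n")
  invisible(x)
}

#' Write reference files (FASTA, GTF, BED)
#'
#' Writes the genome as FASTA, the gene models as a 1-based GTF (gene,
#' transcript, 5'UTR/CDS/intron/3'UTR rows) and the repeat intervals as a
#' 0-based half-open BED file whose name field distinguishes TE from other
#' repeats.
#'
#' @param ref a `reference_bundle`.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of file paths.
#' @export
write_reference_files <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  bed <- file.path(dir, "repeats.bed")
  Biostrings::writeXStringSet(ref$genome, fa)

  feat <- copy(ref$features)
  # GTF frame for CDS blocks: bases to skip to reach the next codon start
  feat[, phase := NA_integer_]
  feat[type == "CDS", phase := {
    ord <- order(exon_rank)
    w <- (end - start + 1L)[ord]
    prev <- integer(.N)
    prev[ord] <- cumsum(c(0L, w[-.N]))
    as.integer((3L - prev %% 3L) %% 3L)
  }, by = tx_id]
  gr <- GenomicRanges::GRanges(feat$chrom,
                               IRanges::IRanges(feat$start, feat$end),
                               strand = feat$strand)
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$gene_id <- feat$gene_id
  S4Vectors::mcols(gr)$transcript_id <- feat$tx_id
  S4Vectors::mcols(gr)$phase <- feat$phase
  gg <- GenomicRanges::GRanges(ref$genes$chrom,
                               IRanges::IRanges(ref$genes$start, ref$genes$end),
                               strand = ref$genes$strand)
  S4Vectors::mcols(gg)$type <- "transcript"
  S4Vectors::mcols(gg)$gene_id <- ref$genes$gene_id
  S4Vectors::mcols(gg)$transcript_id <- ref$genes$tx_id
  S4Vectors::mcols(gg)$phase <- NA_integer_
  all_gr <- c(gg, gr)
  all_gr <- all_gr[order(as.character(GenomicRanges::seqnames(all_gr)),
                         GenomicRanges::start(all_gr))]
  rtracklayer::export(all_gr, gtf, format = "gtf")

  if (nrow(ref$repeats)) {
    rb <- GenomicRanges::GRanges(ref$repeats$chrom,
                                 IRanges::IRanges(ref$repeats$start,
                                                  ref$repeats$end))
    S4Vectors::mcols(rb)$name <- ifelse(ref$repeats$te, "TE", "repeat")
    rtracklayer::export(rb, bed, format = "bed")
  } else {
    file.create(bed)
  }
  invisible(c(fasta = fa, gtf = gtf, bed = bed))
}

#' Read a reference bundle back from FASTA/GTF/BED files
#'
#' Rebuilds a `reference_bundle` from files written by
#' [write_reference_files()] (or any annotation using the same feature
#' types). The transcription-unit map is reconstructed as gene spans plus
#' intergenic gaps; intergenic unit strands default to `+` because external
#' annotation carries no unit strand.
#'
#' @param fasta,gtf,bed file paths; `bed` may be `NULL`.
#' @return a `reference_bundle`.
#' @export
read_reference_files <- function(fasta, gtf, bed = NULL) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- rtracklayer::import(gtf, format = "gtf")
  ann_dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(ann)),
    start = GenomicRanges::start(ann), end = GenomicRanges::end(ann),
    strand = as.character(GenomicRanges::strand(ann)),
    type = as.character(S4Vectors::mcols(ann)$type),
    gene_id = as.character(S4Vectors::mcols(ann)$gene_id),
    tx_id = as.character(S4Vectors::mcols(ann)$transcript_id)
  )
  feats <- ann_dt[type %in% c("five_prime_utr", "CDS", "intron",
                              "three_prime_utr")]
  setorder(feats, chrom, start)
  feats[, exon_rank := NA_integer_]
  for (t in unique(feats[type == "CDS", tx_id])) {
    idx <- feats[, which(type == "CDS" & tx_id == t)]
    if (length(idx) && feats$strand[idx[1]] == "-") idx <- rev(idx)
    feats[idx, exon_rank := seq_along(idx)]
  }
  genes <- feats[, .(chrom = chrom[1], strand = strand[1],
                     start = min(start), end = max(end)),
                 by = .(gene_id, tx_id)]
  reps <- data.table(chrom = character(0), start = integer(0),
                     end = integer(0), te = logical(0))
  if (!is.null(bed) && file.exists(bed) && file.size(bed) > 0) {
    b <- rtracklayer::import(bed, format = "bed")
    reps <- data.table(chrom = as.character(GenomicRanges::seqnames(b)),
                       start = GenomicRanges::start(b),
                       end = GenomicRanges::end(b),
                       te = (S4Vectors::mcols(b)$name %||%
                               rep("TE", length(b))) == "TE")
  }
  units <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    cn <- names(genome)[ci]
    g <- genes[chrom == cn][order(start)]
    gap_start <- c(1L, g$end + 1L)
    gap_end <- c(g$start - 1L, Biostrings::width(genome)[ci])
    ig <- data.table(start = gap_start, end = gap_end)[end >= start]
    units[[ci]] <- rbind(
      g[, .(chrom, start, end, strand, kind = "gene", unit_id = gene_id)],
      ig[, .(chrom = cn, start, end, strand = "+", kind = "intergenic",
             unit_id = sprintf("%s_ig%02d", cn, seq_len(.N)))],
      use.names = TRUE)
  }
  structure(list(
    genome = genome, genome_chr = setNames(as.character(genome), names(genome)),
    genes = genes[, .(gene_id, tx_id, chrom, strand, start, end)],
    features = feats[, .(gene_id, tx_id, chrom, strand, type, start, end,
                         exon_rank)],
    repeats = reps,
    tx_units = setorder(rbindlist(units), chrom, start),
    spec = NULL
  ), class = "reference_bundle")
}

# transcript-strand reference base at genomic positions
ref_base_at <- function(ref, chrom, pos, strand = NULL) {
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    raw <- charToRaw(ref$genome_chr[[cn]])
    out[idx] <- strsplit(rawToChar(raw[pos[idx]]), "", fixed = TRUE)[[1]]
  }
  if (!is.null(strand)) {
    neg <- strand == "-"
    out[neg] <- comp_base(out[neg])
  }
  out
}
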