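library(data.table)

# A reference bundle built directly from given sequences, with the whole of
# each chromosome as one transcription unit unless units are supplied.
mini_ref <- function(seqs, units = NULL, features = NULL, repeats = NULL) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("chr%d", seq_along(seqs))
  genome <- Biostrings::DNAStringSet(seqs)
  if (is.null(units)) {
    units <- data.table(chrom = names(seqs), start = 1L,
                        end = nchar(seqs), strand = "+",
                        kind = "intergenic",
                        unit_id = paste0(names(seqs), "_u1"))
  }
  if (is.null(features)) {
    features <- data.table(gene_id = character(0), tx_id = character(0),
                           chrom = character(0), strand = character(0),
                           type = character(0), start = integer(0),
                           end = integer(0), exon_rank = integer(0))
  }
  genes <- if (nrow(features)) {
    features[, .(chrom = chrom[1], strand = strand[1], start = min(start),
                 end = max(end)), by = .(gene_id, tx_id)]
  } else {
    data.table(gene_id = character(0), tx_id = character(0),
               chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  }
  if (is.null(repeats)) {
    repeats <- data.table(chrom = character(0), start = integer(0),
                          end = integer(0), te = logical(0))
  }
  structure(list(genome = genome, genome_chr = setNames(seqs, names(seqs)),
                 genes = genes, features = features, repeats = repeats,
                 tx_units = units, spec = NULL),
            class = "reference_bundle")
}

# one aligned read row; seq is genome-forward orientation
make_read <- function(chrom, pos, seq, strand = "+", qual = NULL,
                      mapq = 60L, flag = NULL, qname = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq)) # Phred 40
  if (is.null(flag)) flag <- if (strand == "-") 16L else 0L
  data.table(qname = qname %||% sprintf("read_%s_%d", chrom, pos),
             flag = flag, chrom = chrom, pos = as.integer(pos),
             mapq = as.integer(mapq), cigar = paste0(nchar(seq), "M"),
             seq = seq, qual = qual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small structured genome used across tests
small_spec <- function(...) {
  genome_spec(chrom_length = 30000L, n_genes = 4L, utr5_length = 100L,
              cds_length = 600L, intron_length = 150L, utr3_length = 200L,
              min_intergenic = 800L, seed = 42L, ...)
}
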