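.AA_LEVELS <- c(sort(setdiff(unique(Biostrings::GENETIC_CODE), "*")), "*")

# CDS model for a transcript: ordered genomic CDS blocks plus the spliced
# CDS sequence in transcript orientation
cds_model <- function(ref, tx) {
  blocks <- ref$features[tx_id == tx & type == "CDS"]
  if (!nrow(blocks)) return(NULL)
  setorder(blocks, exon_rank)
  seqs <- substring(ref$genome_chr[[blocks$chrom[1]]], blocks$start,
                    blocks$end)
  strand <- blocks$strand[1]
  cds_seq <- if (strand == "-")
    paste(revcomp_chr(seqs), collapse = "") else paste(seqs, collapse = "")
  list(blocks = blocks, strand = strand, cds_seq = cds_seq,
       len = nchar(cds_seq))
}

# CDS-relative (1-based, transcript orientation) position of genomic pos
cds_position <- function(model, gpos) {
  b <- model$blocks
  widths <- b$end - b$start + 1L
  cum <- cumsum(c(0L, widths))
  for (i in seq_len(nrow(b))) {
    if (gpos >= b$start[i] && gpos <= b$end[i]) {
      within <- if (model$strand == "+") gpos - b$start[i] + 1L else
        b$end[i] - gpos + 1L
      return(cum[i] + within)
    }
  }
  NA_integer_
}

#' Codon consequence of A-to-G editing at CDS sites
#'
#' Reconstructs the codon containing each CDS site in transcript
#' orientation (reverse-complemented for minus-strand transcripts),
#' substitutes G for the edited A, and reports the amino-acid change under
#' the standard genetic code. Stop-codon gains and losses are labelled
#' distinctly rather than collapsed into the non-synonymous class. When no
#' transcript is supplied, the transcript whose CDS contains the site is
#' used (the reference's single isoform per gene).
#'
#' @param sites a site table (`chrom`, `pos`, `strand`; optional `tx_id`).
#' @param ref a `reference_bundle`.
#' @return a `recoding_event` data.table: `chrom`, `pos`, `strand`,
#'   `tx_id`, `cds_pos`, `codon_index`, `codon_pos` (1-3), `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `synonymous`,
#'   `consequence` (`synonymous`/`nonsynonymous`/`stop_gain`/`stop_loss`).
#'   Sites outside any CDS are dropped.
#' @export
codon_consequence <- function(sites, ref) {
  sites <- as.data.table(sites)
  if (!"tx_id" %in% names(sites) || anyNA(sites$tx_id)) {
    idx <- winning_feature(ref, sites$chrom, sites$pos, sites$strand)
    intx <- !is.na(idx) & ref$features$type[idx] == "CDS"
    sites[, tx_id := fifelse(intx, ref$features$tx_id[idx], NA_character_)]
  }
  sites <- sites[!is.na(tx_id)]
  out <- vector("list", nrow(sites))
  gc_tab <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    model <- cds_model(ref, s$tx_id)
    if (is.null(model)) next
    if (s$strand != model$strand)
      stop("site strand disagrees with its transcript strand", call. = FALSE)
    cp <- cds_position(model, s$pos)
    if (is.na(cp)) next
    ref_tx <- substring(model$cds_seq, cp, cp)
    if (ref_tx != "A")
      stop("A-to-G consequence requested at a non-A CDS base", call. = FALSE)
    ci <- (cp - 1L) %/% 3L + 1L
    cpos <- (cp - 1L) %% 3L + 1L
    ref_codon <- substring(model$cds_seq, 3L * ci - 2L, 3L * ci)
    alt_codon <- ref_codon
    substr(alt_codon, cpos, cpos) <- "G"
    ref_aa <- unname(gc_tab[ref_codon])
    alt_aa <- unname(gc_tab[alt_codon])
    cons <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "nonsynonymous"
    out[[i]] <- data.table(chrom = s$chrom, pos = s$pos, strand = s$strand,
                           tx_id = s$tx_id, cds_pos = cp, codon_index = ci,
                           codon_pos = cpos, ref_codon = ref_codon,
                           alt_codon = alt_codon, ref_aa = ref_aa,
                           alt_aa = alt_aa,
                           synonymous = ref_aa == alt_aa,
                           consequence = cons)
  }
  ev <- rbindlist(out)
  if (!nrow(ev))
    ev <- data.table(chrom = character(0), pos = integer(0),
                     strand = character(0), tx_id = character(0),
                     cds_pos = integer(0), codon_index = integer(0),
                     codon_pos = integer(0), ref_codon = character(0),
                     alt_codon = character(0), ref_aa = character(0),
                     alt_aa = character(0), synonymous = logical(0),
                     consequence = character(0))
  ev[]
}

#' Amino-acid substitution matrix of recoding events
#'
#' Counts each (reference amino acid, edited amino acid) pair over
#' deduplicated recoding events. Diagonal entries are synonymous events;
#' the off-diagonal sum equals the non-synonymous (plus stop-affecting)
#' event count, and the matrix total equals the number of events.
#'
#' @param events a `recoding_event` table from [codon_consequence()].
#' @return an amino-acid by amino-acid integer count matrix (single-letter
#'   rows = reference, columns = edited; `*` is the stop codon).
#' @export
substitution_matrix <- function(events) {
  events <- as.data.table(events)
  m <- matrix(0L, nrow = length(.AA_LEVELS), ncol = length(.AA_LEVELS),
              dimnames = list(ref = .AA_LEVELS, alt = .AA_LEVELS))
  if (!nrow(events)) return(m)
  events <- unique(events, by = c("chrom", "pos", "strand", "tx_id"))
  tb <- events[, .N, by = .(ref_aa, alt_aa)]
  m[cbind(match(tb$ref_aa, .AA_LEVELS), match(tb$alt_aa, .AA_LEVELS))] <-
    tb$N
  m
}

#' All amino-acid pairs reachable by a single A-to-G codon change
#'
#' Exhaustive enumeration over the 64 codons and the codon positions
#' carrying A: the attainable (reference aa, edited aa) set under the
#' standard genetic code. Used as the oracle for recoding outputs.
#'
#' @return a data.table of distinct `ref_aa`/`alt_aa` pairs.
#' @export
atog_reachable_pairs <- function() {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  out <- list()
  for (cod in codons) {
    for (p in 1:3) {
      if (substring(cod, p, p) != "A") next
      alt <- cod
      substr(alt, p, p) <- "G"
      out[[length(out) + 1L]] <- data.table(ref_aa = unname(gc_tab[cod]),
                                            alt_aa = unname(gc_tab[alt]))
    }
  }
  unique(rbindlist(out))
}
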