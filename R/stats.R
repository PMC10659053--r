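#' Per-site editing level
#'
#' The editing level of a site is `G/(G+A)`: the edited (G) read count over
#' the sum of edited and reference (A) read counts.
#'
#' @param G edited read count(s).
#' @param A reference read count(s).
#' @return numeric vector of levels in `[0, 1]`.
#' @export
editing_level <- function(G, A) {
  if (any(G + A <= 0)) stop("editing level undefined: G + A must be > 0",
                            call. = FALSE)
  G / (G + A)
}

#' Overall editing level of a site set
#'
#' The pooled level `sum(G) / sum(G + A)` over all sites, equal to the
#' coverage-weighted mean of per-site levels. Sites below `min_coverage`
#' total reads are excluded, matching the minimum-coverage rule used for
#' all level statistics.
#'
#' @param sites an edit-site table with `G` and `A` columns.
#' @param min_coverage minimum `G + A` for a site to enter the pool.
#' @return a single level in `[0, 1]`.
#' @export
overall_editing_level <- function(sites, min_coverage = 10L) {
  sites <- as.data.table(sites)
  sites <- sites[G + A >= min_coverage]
  if (!nrow(sites)) stop("overall editing level undefined: no site meets ",
                         "the coverage threshold", call. = FALSE)
  sum(sites$G) / sum(sites$G + sites$A)
}

#' Edited sites per megabase of mapped sequence
#'
#' @param n_sites number of edited sites.
#' @param mapped_bases total mapped bases of the library.
#' @return sites per Mb.
#' @export
sites_per_mb <- function(n_sites, mapped_bases) {
  if (any(mapped_bases <= 0)) stop("sites_per_mb undefined: mapped_bases ",
                                   "must be > 0", call. = FALSE)
  n_sites / (mapped_bases / 1e6)
}

#' Repeat editing index
#'
#' A site-list-free global editing measure: over every transcript-strand
#' reference-adenosine position inside the repeat (or TE) intervals, the
#' ratio of G reads to A+G reads. With `denominator = "total"` the full
#' filtered depth at those positions is used instead of A+G.
#'
#' @param rna_pileup an RNA `site_pileup`.
#' @param ref a `reference_bundle`.
#' @param intervals interval table (`chrom`, `start`, `end`), e.g.
#'   `ref$repeats` or its TE subset; defaults to the TE subset.
#' @param denominator `"ag"` (A+G reads, consistent with the editing-level
#'   definition) or `"total"` (all filtered reads).
#' @return the editing index, a fraction.
#' @export
editing_index <- function(rna_pileup, ref, intervals = NULL,
                          denominator = c("ag", "total")) {
  denominator <- match.arg(denominator)
  pp <- as.data.table(rna_pileup)
  if (is.null(intervals)) intervals <- ref$repeats[te == TRUE]
  intervals <- as.data.table(intervals)
  if (!nrow(pp) || !nrow(intervals))
    stop("editing index undefined: empty pileup or interval set",
         call. = FALSE)
  ov <- point_overlaps(pp$chrom, pp$pos, intervals)
  pp <- pp[unique(ov$from)]
  pp <- pp[ref_base_at(ref, chrom, pos, strand) == "A"]
  denom <- if (denominator == "ag") sum(pp$A + pp$G) else sum(pp$depth)
  if (denom <= 0) stop("editing index undefined: zero denominator",
                       call. = FALSE)
  sum(pp$G) / denom
}

#' Exclusive intersection counts of per-tissue site sets
#'
#' Assigns every distinct site to exactly one of the `2^k - 1` membership
#' classes over `k` tissues (UpSet-style exclusive intersections), so the
#' class counts sum to the size of the union.
#'
#' @param site_sets named list (length >= 2) of site tables or site-key
#'   vectors.
#' @return a data.table with one row per non-empty membership class:
#'   `members` (comma-joined tissue names), `degree` and `count`.
#' @export
intersection_sets <- function(site_sets) {
  if (length(site_sets) < 2L) stop("need at least two site sets",
                                   call. = FALSE)
  keys <- lapply(site_sets, function(s) {
    if (is.character(s)) unique(s) else {
      s <- as.data.table(s)
      unique(site_key(s$chrom, s$pos, s$strand))
    }
  })
  all_keys <- unique(unlist(keys))
  memb <- vapply(keys, function(k) all_keys %in% k,
                 logical(length(all_keys)))
  if (length(all_keys) == 1L) memb <- matrix(memb, nrow = 1L)
  pattern <- apply(memb, 1L, function(r)
    paste(names(site_sets)[r], collapse = ","))
  out <- as.data.table(table(pattern))
  setnames(out, c("members", "count"))
  out[, degree := lengths(strsplit(members, ",", fixed = TRUE))]
  setorder(out, -degree, members)
  out[, .(members, degree, count = as.integer(count))]
}

#' Neighbour-base motif matrix around edit sites
#'
#' Extracts the -1 and +1 neighbours of each site in transcript
#' orientation (reverse-complemented for minus-strand sites) and returns
#' per-position base frequencies. Position 0 is the edited adenosine and is
#' always 100% A by construction; sites at a sequence boundary have the
#' missing neighbour skipped and counted.
#'
#' @param sites a stranded edit-site table (`chrom`, `pos`, `strand`).
#' @param ref a `reference_bundle`.
#' @return a `motif_matrix` list: `freq`, a 3 x 4 matrix (rows `-1`, `0`,
#'   `+1`; columns A, C, G, T) with rows summing to 1; `counts`, the raw
#'   base counts; `n_skipped_boundary`.
#' @export
motif_matrix <- function(sites, ref) {
  sites <- as.data.table(sites)
  if (!nrow(sites)) stop("no sites", call. = FALSE)
  if (any(!sites$strand %in% c("+", "-")))
    stop("all sites must be stranded for motif analysis", call. = FALSE)
  counts <- matrix(0L, nrow = 3L, ncol = 4L,
                   dimnames = list(c("-1", "0", "+1"), BASES))
  skipped <- 0L
  for (ri in c(-1L, 0L, 1L)) {
    b <- if (ri == 0L) ref_base_at(ref, sites$chrom, sites$pos, sites$strand)
    else neighbour_base(ref, sites$chrom, sites$pos, sites$strand, ri)
    skipped <- skipped + sum(is.na(b))
    tb <- table(factor(b[!is.na(b)], levels = BASES))
    row <- c("-1", "0", "+1")[ri + 2L]
    counts[row, ] <- counts[row, ] + as.integer(tb)
  }
  freq <- counts / rowSums(counts)
  structure(list(freq = freq, counts = counts,
                 n_skipped_boundary = skipped), class = "motif_matrix")
}
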