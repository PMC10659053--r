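#' Describe an editing scenario to plant into a synthetic genome
#'
#' Collects the parameters of the planted truth: number of edit sites and
#' their true editing levels, the genomic-feature mix, neighbour-base motif
#' bias, hyper-edited clusters, SNPs, and the condition/replicate design.
#' Defaults emulate a temperature-acclimation design with three conditions
#' (27, 18 and 13 degrees C), three replicates each, levels spread over
#' 0.1-0.9, a strong upstream-adenosine motif preference and a feature mix
#' dominated by intergenic, intronic and 3'UTR sites.
#'
#' @param n_sites number of normal edit sites to plant.
#' @param level_range range of true editing levels (uniform draw).
#' @param class_mix named fractions over feature classes
#'   (`intergenic`, `intron`, `three_prime_utr`, `CDS`, `five_prime_utr`);
#'   normalised internally.
#' @param upstream_A_bias fraction of planted sites whose transcript-strand
#'   upstream (-1) neighbour is A.
#' @param downstream_G_bias fraction of planted sites whose downstream (+1)
#'   neighbour is G.
#' @param conditions condition labels, warmest first.
#' @param replicates_per_condition replicates per condition.
#' @param diff_fraction fraction of sites with condition-dependent levels.
#' @param diff_delta level difference between the two extreme conditions at
#'   differential sites.
#' @param cold_up_fraction fraction of differential sites whose level rises
#'   in the colder conditions.
#' @param n_snps number of planted genomic SNPs.
#' @param het_fraction fraction of SNPs that are heterozygous.
#' @param n_hyper_clusters,sites_per_cluster,cluster_span hyper-edited
#'   clusters: count, edited adenosines per cluster (>= 5) and window span.
#' @param per_read_edit_prob per-read probability that a cluster adenosine is
#'   edited on a hyper-edited transcript.
#' @param sites optional explicit edit table (`chrom`, `pos`, `strand`, and
#'   either `level` or `level_<condition>` columns); replaces random
#'   placement.
#' @param snps optional explicit SNP table (`chrom`, `pos`, `genotype`,
#'   optional `alt`).
#' @param seed integer seed for placement.
#' @return an object of class `edit_scenario`.
#' @export
edit_scenario <- function(n_sites = 1000L, level_range = c(0.1, 0.9),
                          class_mix = c(intergenic = 0.51, intron = 0.27,
                                        three_prime_utr = 0.19, CDS = 0.02,
                                        five_prime_utr = 0.01),
                          upstream_A_bias = 0.9, downstream_G_bias = 0.5,
                          conditions = c("T27", "T18", "T13"),
                          replicates_per_condition = 3L,
                          diff_fraction = 0.15, diff_delta = 0.2,
                          cold_up_fraction = 0.8,
                          n_snps = 200L, het_fraction = 0.5,
                          n_hyper_clusters = 12L, sites_per_cluster = 8L,
                          cluster_span = 60L, per_read_edit_prob = 0.9,
                          sites = NULL, snps = NULL, seed = 7L) {
  if (sites_per_cluster < 5L && n_hyper_clusters > 0L)
    stop("sites_per_cluster must be >= 5", call. = FALSE)
  if (any(level_range < 0) || any(level_range > 1))
    stop("level_range must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), level_range = level_range,
    class_mix = class_mix / sum(class_mix),
    upstream_A_bias = upstream_A_bias, downstream_G_bias = downstream_G_bias,
    conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    diff_fraction = diff_fraction, diff_delta = diff_delta,
    cold_up_fraction = cold_up_fraction,
    n_snps = as.integer(n_snps), het_fraction = het_fraction,
    n_hyper_clusters = as.integer(n_hyper_clusters),
    sites_per_cluster = as.integer(sites_per_cluster),
    cluster_span = as.integer(cluster_span),
    per_read_edit_prob = per_read_edit_prob,
    sites = sites, snps = snps, seed = as.integer(seed)
  ), class = "edit_scenario")
}

level_cols <- function(conditions) paste0("level_", conditions)

# transcript-strand adenosine candidates across all transcription units
tx_adenosine_candidates <- function(ref) {
  out <- vector("list", nrow(ref$tx_units))
  for (i in seq_len(nrow(ref$tx_units))) {
    u <- ref$tx_units[i]
    raw <- charToRaw(ref$genome_chr[[u$chrom]])
    span <- u$start:u$end
    want <- if (u$strand == "+") charToRaw("A") else charToRaw("T")
    pos <- span[raw[span] == want]
    # keep one-off ends out so every site has both neighbours
    pos <- pos[pos > 1L & pos < length(raw)]
    if (length(pos))
      out[[i]] <- data.table(chrom = u$chrom, pos = pos, strand = u$strand,
                             unit_id = u$unit_id, unit_kind = u$kind,
                             unit_start = u$start, unit_end = u$end)
  }
  rbindlist(out)
}

#' Plant edits, hyper-edited clusters and SNPs into a reference
#'
#' Samples (or validates, for explicit scenarios) edit-site positions on
#' transcript-strand adenosines, hyper-edited clusters, and genomic SNPs,
#' and records the full truth table used as the evaluation oracle for the
#' pipeline. Edits are never co-located with SNPs, and every edit position
#' carries the reference base A on its transcript strand (genome-strand T
#' for minus-strand units).
#'
#' @param ref a `reference_bundle`.
#' @param scenario an [edit_scenario()].
#' @return an object of class `scenario_truth`: a data.table with columns
#'   `chrom`, `pos`, `strand`, `kind` (`edit`/`hyper`/`snp`), `feature`,
#'   `te`, `repeat_flag`, `ref_fwd`, `alt_fwd`, `genotype`, `cluster_id`,
#'   `upstream`, `downstream` (transcript orientation) and one
#'   `level_<condition>` column per condition. The scenario is attached as
#'   attribute `"scenario"`.
#' @export
plant_truth <- function(ref, scenario) {
  stopifnot(inherits(ref, "reference_bundle"),
            inherits(scenario, "edit_scenario"))
  set.seed(derive_seed(scenario$seed, "plant"))
  lc <- level_cols(scenario$conditions)
  cand <- tx_adenosine_candidates(ref)

  # ---- hyper clusters -------------------------------------------------
  hyper <- data.table()
  blocked <- data.table(chrom = character(0), start = integer(0),
                        end = integer(0))
  if (is.null(scenario$sites) && scenario$n_hyper_clusters > 0L) {
    margin <- 170L # keep full-length reads over the cluster inside the unit
    ig <- cand[unit_kind == "intergenic" &
                 pos >= unit_start + margin & pos <= unit_end - margin]
    picked <- 0L
    rows <- list()
    tries <- 0L
    while (picked < scenario$n_hyper_clusters && tries < 2000L && nrow(ig)) {
      tries <- tries + 1L
      anchor <- ig[sample.int(nrow(ig), 1L)]
      win <- ig[chrom == anchor$chrom & strand == anchor$strand &
                  pos >= anchor$pos &
                  pos <= anchor$pos + scenario$cluster_span - 1L]
      if (nrow(win) < scenario$sites_per_cluster) next
      picked <- picked + 1L
      sel <- win[seq_len(scenario$sites_per_cluster)]
      sel[, cluster_id := sprintf("cluster%02d", picked)]
      rows[[picked]] <- sel
      blocked <- rbind(blocked,
                       data.table(chrom = anchor$chrom,
                                  start = min(sel$pos) - 1L,
                                  end = max(sel$pos) + 1L))
      ig <- ig[!(chrom == anchor$chrom &
                   pos >= anchor$pos - scenario$cluster_span &
                   pos <= anchor$pos + 2L * scenario$cluster_span)]
    }
    if (picked < scenario$n_hyper_clusters)
      warning("placed only ", picked, " of ", scenario$n_hyper_clusters,
              " hyper clusters")
    hyper <- rbindlist(rows)
  }

  # ---- SNPs -----------------------------------------------------------
  snps <- data.table()
  if (!is.null(scenario$snps)) {
    snps <- as.data.table(scenario$snps)
    snps[, ref_fwd := ref_base_at(ref, chrom, pos)]
    if (!"alt" %in% names(snps))
      snps[, alt := vapply(ref_fwd, function(r)
        sample(setdiff(BASES, r), 1L), character(1))]
  } else if (scenario$n_snps > 0L) {
    widths <- Biostrings::width(ref$genome)
    cn <- sample(names(ref$genome), scenario$n_snps, replace = TRUE,
                 prob = widths / sum(widths))
    ps <- integer(scenario$n_snps)
    for (nm in unique(cn)) {
      i <- which(cn == nm)
      ps[i] <- sample.int(widths[names(ref$genome) == nm], length(i))
    }
    snps <- unique(data.table(chrom = cn, pos = ps))
    if (nrow(blocked)) {
      bad <- rep(FALSE, nrow(snps))
      for (j in seq_len(nrow(blocked)))
        bad <- bad | (snps$chrom == blocked$chrom[j] &
                        snps$pos >= blocked$start[j] - scenario$cluster_span &
                        snps$pos <= blocked$end[j] + scenario$cluster_span)
      snps <- snps[!bad]
    }
    snps[, ref_fwd := ref_base_at(ref, chrom, pos)]
    snps[, alt := vapply(ref_fwd, function(r)
      sample(setdiff(BASES, r), 1L), character(1))]
    snps[, genotype := sample(c("het", "hom"), .N, replace = TRUE,
                              prob = c(scenario$het_fraction,
                                       1 - scenario$het_fraction))]
  }
  if (nrow(snps) && !"genotype" %in% names(snps))
    snps[, genotype := "het"]

  # ---- normal edit sites ---------------------------------------------
  if (!is.null(scenario$sites)) {
    edits <- as.data.table(scenario$sites)
    ref_tx <- ref_base_at(ref, edits$chrom, edits$pos, edits$strand)
    if (any(ref_tx != "A"))
      stop("edit placement error: position(s) ",
           paste(head(edits$pos[ref_tx != "A"], 3), collapse = ", "),
           " are not reference A on the requested transcript strand",
           call. = FALSE)
    if (nrow(snps) && any(site_key(edits$chrom, edits$pos, "*") %in%
                            site_key(snps$chrom, snps$pos, "*")))
      stop("edit/SNP collision error: an edit was requested at a SNP position",
           call. = FALSE)
    if (!any(lc %in% names(edits))) {
      if (!"level" %in% names(edits))
        stop("explicit sites need a 'level' or per-condition level columns",
             call. = FALSE)
      for (cc in lc) edits[, (cc) := edits$level]
    }
    for (cc in setdiff(lc, names(edits))) edits[, (cc) := edits[[lc[1]]]]
  } else {
    pool <- cand
    if (nrow(snps))
      pool <- pool[!site_key(chrom, pos, "*") %in%
                     site_key(snps$chrom, snps$pos, "*")]
    if (nrow(hyper))
      pool <- pool[!site_key(chrom, pos, strand) %in%
                     site_key(hyper$chrom, hyper$pos, hyper$strand)]
    pool[, feature := feature_at(ref, chrom, pos, strand)]
    pool[, upstream := neighbour_base(ref, chrom, pos, strand, -1L)]
    pool[, downstream := neighbour_base(ref, chrom, pos, strand, +1L)]

    mix <- scenario$class_mix
    targets <- round(scenario$n_sites * mix)
    # adjust rounding drift on the largest class
    targets[which.max(targets)] <- targets[which.max(targets)] +
      scenario$n_sites - sum(targets)
    picked <- vector("list", length(targets))
    for (ki in seq_along(targets)) {
      klass <- names(targets)[ki]
      sub <- pool[feature == klass]
      picked[[ki]] <- sample_with_motif_bias(
        sub, targets[[ki]], scenario$upstream_A_bias,
        scenario$downstream_G_bias)
    }
    edits <- rbindlist(picked)
    if (nrow(edits) < scenario$n_sites)
      warning("placed only ", nrow(edits), " of ", scenario$n_sites,
              " requested edit sites (candidate pool exhausted)")
    # true levels: shared across conditions except the differential subset
    base <- runif(nrow(edits), scenario$level_range[1], scenario$level_range[2])
    lvl <- matrix(base, nrow = nrow(edits), ncol = length(lc))
    n_diff <- floor(nrow(edits) * scenario$diff_fraction)
    if (n_diff > 0L && length(lc) > 1L) {
      di <- sample.int(nrow(edits), n_diff)
      dir <- ifelse(runif(n_diff) < scenario$cold_up_fraction, 1, -1)
      steps <- seq(0, scenario$diff_delta, length.out = length(lc))
      for (j in seq_along(lc)[-1])
        lvl[di, j] <- pmin(0.98, pmax(0.02, base[di] + dir * steps[j]))
    }
    for (j in seq_along(lc)) edits[, (lc[j]) := lvl[, j]]
  }

  # ---- assemble truth table ------------------------------------------
  fill_site_cols <- function(dt, kind) {
    dt <- copy(dt)
    dt[, kind := kind]
    if (!"feature" %in% names(dt))
      dt[, feature := feature_at(ref, chrom, pos, strand)]
    if (!"upstream" %in% names(dt))
      dt[, upstream := neighbour_base(ref, chrom, pos, strand, -1L)]
    if (!"downstream" %in% names(dt))
      dt[, downstream := neighbour_base(ref, chrom, pos, strand, +1L)]
    dt[, ref_fwd := ref_base_at(ref, chrom, pos)]
    dt[, alt_fwd := ifelse(strand == "+", "G", "C")]
    dt
  }
  keep_cols <- c("chrom", "pos", "strand", "kind", "feature", "ref_fwd",
                 "alt_fwd", "genotype", "cluster_id", "upstream",
                 "downstream", lc)
  edits <- fill_site_cols(edits, "edit")
  edits[, `:=`(genotype = NA_character_, cluster_id = NA_character_)]
  parts <- list(edits[, intersect(keep_cols, names(edits)), with = FALSE])
  if (nrow(hyper)) {
    hyper <- fill_site_cols(hyper, "hyper")
    hyper[, genotype := NA_character_]
    for (cc in lc) hyper[, (cc) := scenario$per_read_edit_prob]
    parts <- c(parts, list(hyper[, intersect(keep_cols, names(hyper)),
                                 with = FALSE]))
  }
  if (nrow(snps)) {
    sn <- copy(snps)
    sn[, `:=`(strand = "*", kind = "snp", cluster_id = NA_character_)]
    sn[, feature := feature_at(ref, chrom, pos, "*")]
    sn[, `:=`(upstream = NA_character_, downstream = NA_character_)]
    sn[, alt_fwd := alt]
    for (cc in lc) sn[, (cc) := NA_real_]
    parts <- c(parts, list(sn[, intersect(keep_cols, names(sn)),
                              with = FALSE]))
  }
  truth <- rbindlist(parts, fill = TRUE)
  # repeat / TE flags
  truth[, `:=`(te = FALSE, repeat_flag = FALSE)]
  if (nrow(ref$repeats)) {
    ov <- point_overlaps(truth$chrom, truth$pos, ref$repeats)
    truth[ov$from, repeat_flag := TRUE]
    truth[ov$from[ref$repeats$te[ov$to]], te := TRUE]
  }
  setorder(truth, chrom, pos)
  setattr(truth, "class", c("scenario_truth", class(truth)))
  setattr(truth, "scenario", scenario)
  truth[]
}

# transcript-orientation neighbour base at signed offset from pos
neighbour_base <- function(ref, chrom, pos, strand, offset) {
  gpos <- ifelse(strand == "-", pos - offset, pos + offset)
  widths <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  ok <- gpos >= 1L & gpos <= widths[chrom]
  out <- rep(NA_character_, length(pos))
  out[ok] <- ref_base_at(ref, chrom[ok], gpos[ok], strand[ok])
  out
}

# stratified sampling honouring upstream-A and downstream-G motif bias
sample_with_motif_bias <- function(pool, n, up_bias, down_bias) {
  if (!n || !nrow(pool)) return(pool[0])
  pool <- copy(pool)
  pool[, `:=`(up_a = upstream == "A", down_g = downstream == "G")]
  cells <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))
  want <- c(up_bias * down_bias, up_bias * (1 - down_bias),
            (1 - up_bias) * down_bias, (1 - up_bias) * (1 - down_bias))
  counts <- round(n * want)
  counts[1] <- counts[1] + n - sum(counts)
  out <- vector("list", 4L)
  short <- 0L
  for (i in seq_along(cells)) {
    sub <- pool[up_a == cells[[i]][1] & down_g == cells[[i]][2]]
    take <- min(counts[i] + short, nrow(sub))
    short <- counts[i] + short - take
    if (take > 0L) out[[i]] <- sub[sample.int(nrow(sub), take)]
  }
  res <- rbindlist(out)
  res[, c("up_a", "down_g") := NULL]
  res
}

# overlaps of points with an interval table; returns data.table(from, to)
point_overlaps <- function(chrom, pos, intervals) {
  if (!length(pos) || !nrow(intervals))
    return(data.table(from = integer(0), to = integer(0)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start, intervals$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  data.table(from = S4Vectors::queryHits(hits),
             to = S4Vectors::subjectHits(hits))
}

#' Write a scenario truth table to TSV
#' @param truth a `scenario_truth`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  fwrite(as.data.table(truth), path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
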