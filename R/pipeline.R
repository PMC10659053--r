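#' Default pipeline configuration
#'
#' Returns the full parameter set of the synthetic end-to-end run as a
#' nested list: genome layout, planted scenario, read simulation, pileup
#' filters, SNP-mask and calling thresholds, hyper-editing parameters and
#' the differential-editing design. Every effective parameter is echoed
#' into the run manifest; there are no hidden defaults. The default RNA
#' coverage is per library (17x per replicate, pooled over 3 conditions x
#' 3 replicates for site calling, emulating a design where detection pools
#' all RNA while differential testing uses per-replicate counts).
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    genome = list(),                       # genome_spec() defaults
    scenario = list(),                     # edit_scenario() defaults
    reads = list(coverage_rna = 17),       # per-replicate RNA coverage
    pileup = list(min_base_quality = 30L, trim_bases = 6L,
                  unique_only = TRUE, protocol = "forward"),
    mask = list(min_dna_depth = 10L, min_alt_reads = 2L),
    call = list(min_rna_depth = 10L, min_edited_reads = 3L,
                error_rate = 0.001, fdr = 0.05, multi_allele_min = 2L,
                realign = TRUE, realign_k = 16L, realign_margin = 0.95),
    hyper = list(k = 16L, max_other_mm = 1L, min_edits_per_read = 5L,
                 min_edit_fraction = 0.05),
    diff = list(fdr = 0.05, diffs = c(0.10, 0.20), min_coverage = 10L,
                delta_mode = "pooled"),
    seed = 7L
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and fills unspecified entries from
#' [default_config()].
#'
#' @param path YAML file.
#' @return a configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  cfg
}

#' Pool per-library pileups
#'
#' Sums base counts over identical (chrom, pos, strand) rows; pileups are
#' additive, so pooled calling over many libraries reduces to summing
#' their filtered pileups.
#'
#' @param pileups a list of `site_pileup` tables built with identical
#'   filters.
#' @return a pooled `site_pileup`.
#' @export
pool_pileups <- function(pileups) {
  all_p <- rbindlist(lapply(pileups, as.data.table))
  out <- all_p[, .(A = sum(A), C = sum(C), G = sum(G), T = sum(T),
                   depth = sum(depth)), by = .(chrom, pos, strand)]
  setorder(out, chrom, pos, strand)
  setattr(out, "mapped_bases",
          sum(vapply(pileups, function(p)
            as.double(attr(p, "mapped_bases") %||% 0), double(1))))
  setattr(out, "class", c("site_pileup", class(out)))
  out[]
}

#' Compare called sites against the planted truth
#'
#' Matches calls to planted sites by (chrom, pos, strand) and reports
#' precision/recall plus editing-level agreement. Planted SNPs are never
#' legitimate calls; their overlap with the call set is reported as
#' `snp_calls`.
#'
#' @param calls an edit-site table.
#' @param truth a `scenario_truth`.
#' @param kinds truth kinds counted as positives (default `"edit"`).
#' @param level_cols truth level columns averaged into the expected level
#'   (defaults to all `level_*` columns).
#' @return a list with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `snp_calls`, `mean_abs_level_error` (over true positives) and
#'   `n_called`.
#' @export
evaluate_calls <- function(calls, truth, kinds = "edit", level_cols = NULL) {
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  pos_truth <- truth[kind %in% kinds]
  tkey <- site_key(pos_truth$chrom, pos_truth$pos, pos_truth$strand)
  ckey <- site_key(calls$chrom, calls$pos, calls$strand)
  tp_keys <- intersect(ckey, tkey)
  tp <- length(tp_keys)
  fp <- length(setdiff(ckey, tkey))
  fn <- length(setdiff(tkey, ckey))
  snp_truth <- truth[kind == "snp"]
  snp_calls <- length(intersect(ckey, site_key(snp_truth$chrom,
                                               snp_truth$pos, "+"))) +
    length(intersect(ckey, site_key(snp_truth$chrom, snp_truth$pos, "-")))
  if (is.null(level_cols))
    level_cols <- grep("^level_", names(truth), value = TRUE)
  mae <- NA_real_
  if (tp > 0 && length(level_cols) && "level" %in% names(calls)) {
    pos_truth[, true_level := rowMeans(.SD), .SDcols = level_cols]
    m <- calls[match(tp_keys, ckey)]
    t2 <- pos_truth[match(tp_keys, tkey)]
    mae <- mean(abs(m$level - t2$true_level))
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       snp_calls = snp_calls, mean_abs_level_error = mae,
       n_called = length(ckey))
}

#' Run the full synthetic editome pipeline
#'
#' Orchestrates simulate -> pileup -> SNP mask -> normal calling ->
#' hyper-editing recovery -> merge -> annotation/statistics ->
#' differential editing -> recoding, and assembles a machine-readable run
#' manifest with every effective parameter and per-stage filter
#' accounting. With an output directory, stage outputs are written as
#' FASTA/GTF/BED/SAM/TSV/JSON files with md5 checksums recorded in the
#' manifest.
#'
#' @param config a configuration list, see [default_config()].
#' @param outdir optional output directory.
#' @param write_sam_files also write the (large) per-library SAM files.
#' @param quiet suppress progress messages (written to stderr).
#' @return a list of class `editome_run`: `ref`, `truth`, `res` (normal
#'   sites), `rhes` (hyper sites), `merged`, `annotated`, `stats`,
#'   `differential`, `recoding`, `evaluation` and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         write_sam_files = FALSE, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[editome] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- modifyList(default_config(), config)
  if (!is.null(cfg$seed)) {
    cfg$genome$seed <- cfg$genome$seed %||% cfg$seed
    cfg$scenario$seed <- cfg$scenario$seed %||% cfg$seed
    cfg$reads$seed <- cfg$reads$seed %||% cfg$seed
  }

  say("building reference")
  ref <- stage("reference", build_reference(do.call(genome_spec, cfg$genome)))
  scenario <- stage("scenario", do.call(edit_scenario, cfg$scenario))
  truth <- stage("truth", plant_truth(ref, scenario))
  params <- stage("params", do.call(read_sim_params, cfg$reads))
  conds <- scenario$conditions
  reps <- seq_len(scenario$replicates_per_condition)

  say("simulating reads (", length(conds), " conditions x ", length(reps),
      " replicates)")
  rna_pileups <- list()
  rna_reads <- list()
  n_unmapped <- 0L
  counts <- list()
  for (cond in conds) for (rp in reps) {
    sim <- stage("simulate",
                 simulate_reads(ref, truth, params, cond, rp, what = "rna"))
    key <- paste(cond, rp, sep = ".")
    rna_reads[[key]] <- sim$rna
    n_unmapped <- n_unmapped + sim$counts$rna_unmapped
    rna_pileups[[key]] <- stage("pileup", do.call(build_pileup,
      c(list(sim$rna, ref, source = "RNA"), cfg$pileup)))
  }
  dna_sim <- stage("simulate",
                   simulate_reads(ref, truth, params, conds[1], 0L,
                                  what = "dna"))
  dna_pileup <- stage("pileup", do.call(build_pileup,
    c(list(dna_sim$dna, ref, source = "DNA"),
      cfg$pileup[setdiff(names(cfg$pileup), "protocol")])))

  say("masking DNA variants")
  mask <- stage("mask", do.call(mask_dna_variants,
                                c(list(dna_pileup, ref), cfg$mask)))

  say("calling normal editing sites")
  pooled <- pool_pileups(rna_pileups)
  call_args <- cfg$call[setdiff(names(cfg$call),
                                c("realign", "realign_k", "realign_margin"))]
  res <- stage("call", do.call(call_sites,
                               c(list(pooled, ref, mask), call_args)))
  all_reads <- rbindlist(rna_reads)
  if (isTRUE(cfg$call$realign) && nrow(res)) {
    res <- stage("realign", realignment_check(
      res, all_reads, ref, k = cfg$call$realign_k,
      margin = cfg$call$realign_margin))
    n_realign_dropped <- sum(!res$realign_keep)
    res <- res[realign_keep == TRUE][, realign_keep := NULL]
  } else n_realign_dropped <- 0L

  say("recovering hyper-edited sites")
  hh <- stage("hyper", transform_and_realign(
    all_reads, ref, k = cfg$hyper$k, max_other_mm = cfg$hyper$max_other_mm))
  rhes <- stage("hyper", cluster_filter(
    hh, ref, min_edits_per_read = cfg$hyper$min_edits_per_read,
    min_edit_fraction = cfg$hyper$min_edit_fraction))
  merged <- stage("merge", merge_modes(res, rhes))

  say("computing editome statistics")
  ann <- stage("annotate", annotate_features(merged$sites, ref))
  atog <- merged$sites[edit_type == "A-to-G"]
  mapped_bases <- attr(pooled, "mapped_bases")
  stats <- list(
    n_sites = nrow(merged$sites),
    n_atog = nrow(atog),
    atog_fraction = if (nrow(merged$sites))
      nrow(atog) / nrow(merged$sites) else NA_real_,
    overlap = as.list(merged$overlap),
    overall_editing_level = if (nrow(atog))
      overall_editing_level(atog) else NA_real_,
    sites_per_mb = sites_per_mb(nrow(atog), mapped_bases),
    editing_index_te = tryCatch(
      editing_index(pooled, ref), error = function(e) NA_real_),
    region_fractions = as.list(ann$fractions),
    motif = if (nrow(atog)) motif_matrix(atog, ref)$freq else NULL
  )

  say("differential editing")
  norm_atog <- res[edit_type == "A-to-G"]
  diffs <- list()
  if (length(conds) >= 2L && nrow(norm_atog)) {
    cnt <- site_replicate_counts(rna_pileups, norm_atog)
    pairs <- utils::combn(conds, 2L, simplify = FALSE)
    for (pr in pairs) {
      lab <- paste0(pr[1], "_vs_", pr[2])
      diffs[[lab]] <- stage("differential", differential_editing(
        cnt, group_a = pr[1], group_b = pr[2], fdr = cfg$diff$fdr,
        diffs = cfg$diff$diffs, min_coverage = cfg$diff$min_coverage,
        delta_mode = cfg$diff$delta_mode))
    }
  }

  say("recoding consequences")
  cds_sites <- ann$sites[feature %in% c("CDS-syn", "CDS-nonsyn") &
                           edit_type == "A-to-G"]
  recod <- stage("recoding", codon_consequence(cds_sites, ref))
  aa_matrix <- substitution_matrix(recod)

  evaluation <- list(
    normal = evaluate_calls(res, truth, kinds = "edit"),
    merged = evaluate_calls(merged$sites, truth, kinds = c("edit", "hyper")),
    hyper_cluster_recall = {
      hy <- truth[kind == "hyper"]
      if (nrow(hy)) {
        hk <- site_key(hy$chrom, hy$pos, hy$strand)
        rk <- site_key(rhes$chrom, rhes$pos, rhes$strand)
        length(intersect(hk, rk)) / length(hk)
      } else NA_real_
    })

  manifest <- list(
    package_version = as.character(utils::packageVersion("editome")),
    parameters = cfg,
    counts = c(counts, list(
      rna_libraries = length(rna_reads),
      rna_reads = nrow(all_reads),
      rna_unmapped = n_unmapped,
      dna_reads = nrow(dna_sim$dna),
      pileup_rejected = as.list(attr(rna_pileups[[1]], "rejected")),
      masked_positions = nrow(mask$masked),
      callable_positions = nrow(mask$callable),
      sites_normal = nrow(res),
      realign_dropped = n_realign_dropped,
      hyper_reads_placed = nrow(hh$hits),
      hyper_reads_unplaced = hh$n_unplaced,
      sites_hyper = nrow(rhes),
      overlap = as.list(merged$overlap),
      differential = lapply(diffs, function(d)
        as.list(d$summary[, .(diff, up, down)])),
      recoding_events = nrow(recod))),
    evaluation = evaluation)

  out <- structure(list(ref = ref, truth = truth, res = res, rhes = rhes,
                        merged = merged, annotated = ann, stats = stats,
                        differential = diffs, recoding = recod,
                        aa_matrix = aa_matrix, evaluation = evaluation,
                        manifest = manifest,
                        pileups = list(rna = rna_pileups, dna = dna_pileup,
                                       pooled = pooled)),
                   class = "editome_run")

  if (!is.null(outdir)) {
    say("writing outputs to ", outdir)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- write_reference_files(ref, outdir)
    files["truth"] <- write_truth(truth, file.path(outdir, "truth.tsv"))
    files["sites_tsv"] <- write_sites(merged$sites,
                                      file.path(outdir, "sites.tsv"))
    files["sites_vcf"] <- write_sites(merged$sites,
                                      file.path(outdir, "sites.vcf"),
                                      format = "vcf")
    jsonlite::write_json(stats[setdiff(names(stats), "motif")],
                         file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    files["stats"] <- file.path(outdir, "stats.json")
    if (!is.null(stats$motif)) {
      fwrite(as.data.table(stats$motif, keep.rownames = "position"),
             file.path(outdir, "motif.tsv"), sep = "\t")
      files["motif"] <- file.path(outdir, "motif.tsv")
    }
    for (lab in names(diffs)) {
      fp <- file.path(outdir, sprintf("differential_%s.tsv", lab))
      fwrite(diffs[[lab]]$results, fp, sep = "\t")
      files[paste0("diff_", lab)] <- fp
    }
    fwrite(recod, file.path(outdir, "recoding_events.tsv"), sep = "\t")
    files["recoding"] <- file.path(outdir, "recoding_events.tsv")
    fwrite(as.data.table(aa_matrix, keep.rownames = "ref_aa"),
           file.path(outdir, "aa_substitution_matrix.tsv"), sep = "\t")
    files["aa_matrix"] <- file.path(outdir, "aa_substitution_matrix.tsv")
    if (write_sam_files) {
      for (key in names(rna_reads)) {
        fp <- file.path(outdir, sprintf("rna_%s.sam", key))
        write_sam(rna_reads[[key]], ref, fp)
        files[paste0("sam_", key)] <- fp
      }
      fp <- file.path(outdir, "dna.sam")
      write_sam(dna_sim$dna, ref, fp)
      files["sam_dna"] <- fp
    }
    manifest$files <- as.list(tools::md5sum(unname(files)))
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  out
}

#' @export
print.editome_run <- function(x, ...) {
  cat("editome_run\n")
  cat("  normal sites:", nrow(x$res), " hyper sites:", nrow(x$rhes),
      " common:", x$merged$overlap[["common"]], "\n")
  cat("  A-to-G fraction:", round(x$stats$atog_fraction, 4), "\n")
  ev <- x$evaluation$normal
  cat("  planted-site precision:", round(ev$precision, 4),
      " recall:", round(ev$recall, 4), "\n")
  invisible(x)
}
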