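unmapped_read <- function(seq, qname = "um1") {
  data.table(qname = qname, flag = 4L, chrom = "*", pos = 0L, mapq = 0L,
             cigar = "*", seq = seq, qual = strrep("I", nchar(seq)))
}

test_that("A-to-G transformed realignment recovers exactly the edited As", {
  set.seed(91)
  g <- random_dna(500)
  ref <- mini_ref(c(chr1 = g))
  start <- 101L
  seg <- substring(g, start, start + 59L)
  apos <- which(strsplit(seg, "")[[1]] == "A")
  edited <- chartr("A", "G", seg) # every A edited
  hh <- transform_and_realign(unmapped_read(edited), ref, k = 10L)
  expect_identical(nrow(hh$hits), 1L)
  expect_identical(hh$hits$pos, start)
  expect_identical(hh$hits$strand, "+")
  expect_identical(hh$hits$n_AtoG, length(apos))
  expect_identical(sort(hh$hits$edit_pos[[1]]), start - 1L + apos)
  expect_identical(hh$hits$n_other, 0L)
})

test_that("non-A-to-G mismatches are capped by max_other_mm", {
  set.seed(92)
  g <- random_dna(500)
  ref <- mini_ref(c(chr1 = g))
  seg <- substring(g, 101, 160)
  edited <- chartr("A", "G", seg)
  cpos <- which(strsplit(seg, "")[[1]] == "C")
  one_mm <- edited
  substr(one_mm, cpos[1], cpos[1]) <- "T"
  two_mm <- one_mm
  substr(two_mm, cpos[2], cpos[2]) <- "T"
  h1 <- transform_and_realign(unmapped_read(one_mm), ref, k = 10L,
                              max_other_mm = 1L)
  h2 <- transform_and_realign(unmapped_read(two_mm), ref, k = 10L,
                              max_other_mm = 1L)
  expect_identical(nrow(h1$hits), 1L)
  expect_identical(h1$hits$n_other, 1L)
  expect_identical(nrow(h2$hits), 0L)
})

test_that("minus-strand hyper-edits come back as transcript-space A-to-G", {
  set.seed(93)
  g <- random_dna(500)
  units <- data.table(chrom = "chr1", start = 1L, end = 500L, strand = "-",
                      kind = "intergenic", unit_id = "u1")
  ref <- mini_ref(c(chr1 = g), units = units)
  start <- 201L
  seg <- substring(g, start, start + 59L) # genome forward
  tpos <- which(strsplit(seg, "")[[1]] == "T")
  # transcript = revcomp(segment); editing its As = genome Ts -> Cs
  read_seq <- editome:::revcomp_chr(chartr("T", "C", seg))
  hh <- transform_and_realign(unmapped_read(read_seq), ref, k = 10L)
  expect_identical(nrow(hh$hits), 1L)
  expect_identical(hh$hits$strand, "-")
  expect_identical(hh$hits$pos, start)
  expect_identical(sort(hh$hits$edit_pos[[1]]), start - 1L + tpos)
})

test_that("cluster filtering applies the per-read thresholds", {
  hits <- data.table(
    read_id = c("a", "b"), chrom = "chr1", pos = c(10L, 10L),
    strand = "+", n_AtoG = c(6L, 2L), n_other = 0L, n_A_span = c(40L, 40L),
    L = 60L, edit_pos = list(10L + 1:6, 10L + 1:2))
  out <- cluster_filter(list(hits = hits), NULL,
                        min_edits_per_read = 5L, min_edit_fraction = 0.05)
  # read a kept (6 >= 5, 0.15 >= 0.05); read b dropped
  expect_identical(nrow(out), 6L)
  expect_true(all(out$mode == "hyper"))
  low_frac <- copy(hits)[1, n_A_span := 200L] # 6/200 < 0.05
  expect_identical(nrow(cluster_filter(list(hits = low_frac), NULL)), 0L)
})

test_that("planted hyper clusters are recovered exactly", {
  ref <- build_reference(small_spec())
  sc <- edit_scenario(n_sites = 0L, n_snps = 0L, n_hyper_clusters = 2L,
                      sites_per_cluster = 8L, per_read_edit_prob = 0.9,
                      seed = 17L)
  truth <- suppressWarnings(plant_truth(ref, sc))
  params <- read_sim_params(coverage_rna = 10, base_error_rate = 0,
                            reads_per_cluster = 20L, seed = 18L)
  sim <- simulate_reads(ref, truth, params, "T27", 1L, what = "rna")
  hh <- transform_and_realign(sim$rna, ref)
  rhes <- cluster_filter(hh, ref)
  planted <- truth[truth$kind == "hyper", ]
  expect_identical(nrow(planted), 16L)
  pk <- paste(planted$chrom, planted$pos, planted$strand)
  rk <- paste(rhes$chrom, rhes$pos, rhes$strand)
  expect_identical(sort(intersect(pk, rk)), sort(pk)) # 100% recovery
  expect_identical(sort(rk), sort(pk))                # and nothing else
})

test_that("merging modes obeys set algebra and inclusion-exclusion", {
  mk <- function(pos, mode) {
    data.table(chrom = "chr1", pos = pos, strand = "+", ref_tx = "A",
               alt_tx = "G", ref_fwd = "A", alt_fwd = "G",
               edit_type = "A-to-G", G = 5L, A = 5L, depth = 10L,
               level = 0.5, mode = mode)
  }
  m <- merge_modes(mk(c(1L, 2L), "normal"), mk(c(2L, 3L), "hyper"))
  expect_identical(unname(m$overlap["common"]), 1L)
  expect_identical(unname(m$overlap["union"]), 3L)
  expect_identical(m$sites[pos == 2L, mode], "common")

  d <- merge_modes(mk(1:2, "normal"), mk(3:4, "hyper"))
  expect_identical(unname(d$overlap["common"]), 0L)

  big <- merge_modes(mk(1:100, "normal"), mk(91:120, "hyper"))
  expect_identical(unname(big$overlap["normal_only"]), 90L)
  expect_identical(unname(big$overlap["hyper_only"]), 20L)
  expect_identical(unname(big$overlap["common"]), 10L)
  expect_identical(unname(big$overlap["union"]),
                   unname(big$overlap["normal_only"] +
                            big$overlap["hyper_only"] +
                            big$overlap["common"]))
  # conflicting alternate bases are excluded and reported
  conf_h <- mk(1L, "hyper")[, `:=`(alt_tx = "C", alt_fwd = "C")]
  cm <- merge_modes(mk(1L, "normal"), conf_h)
  expect_identical(cm$n_conflicting, 1L)
  expect_identical(nrow(cm$sites), 0L)
})

test_that("reads with only A-to-G mismatches always realign when unique", {
  set.seed(95)
  g <- random_dna(20000)
  ref <- mini_ref(c(chr1 = g))
  n_ok <- 0L
  for (i in 1:200) {
    start <- sample.int(20000L - 80L, 1L)
    seg <- substring(g, start, start + 79L)
    apos <- which(strsplit(seg, "")[[1]] == "A")
    if (length(apos) < 2L) next
    pick <- sample(apos, max(2L, rbinom(1L, length(apos), 0.5)))
    s <- seg
    for (p in pick) substr(s, p, p) <- "G"
    hh <- transform_and_realign(unmapped_read(s), ref, k = 16L,
                                max_other_mm = 0L)
    expect_identical(nrow(hh$hits), 1L)
    expect_identical(hh$hits$pos, start)
    expect_identical(sort(hh$hits$edit_pos[[1]]),
                     sort(start - 1L + pick))
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 150L)
})
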