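test_that("editing level and overall level follow their definitions", {
  expect_equal(editing_level(5, 5), 0.5)
  expect_equal(editing_level(0, 10), 0)
  expect_equal(editing_level(10, 0), 1)
  expect_error(editing_level(0, 0), "undefined")

  sites <- data.table(G = c(1L, 9L), A = c(9L, 1L))
  expect_equal(overall_editing_level(sites), 0.5)
  expect_equal(overall_editing_level(data.table(G = 3L, A = 7L)), 0.3)
  expect_error(overall_editing_level(data.table(G = 1L, A = 2L)),
               "undefined")
})

test_that("overall level equals the coverage-weighted mean level exactly", {
  set.seed(41)
  sites <- data.table(G = rbinom(500, 80, 0.3), A = 0L)
  sites[, A := rbinom(.N, 40, 0.8) + 10L]
  w <- (sites$G + sites$A)
  weighted <- sum(w * sites$G / w) / sum(w)
  expect_equal(overall_editing_level(sites, min_coverage = 0L), weighted,
               tolerance = 1e-12)
  # equal-depth sites: overall equals the arithmetic mean of levels
  eq <- data.table(G = c(2L, 4L, 6L), A = c(18L, 16L, 14L))
  expect_equal(overall_editing_level(eq),
               mean(eq$G / (eq$G + eq$A)), tolerance = 1e-12)
})

test_that("per-Mb density is a simple homogeneous ratio", {
  expect_equal(sites_per_mb(100, 5e7), 2)
  expect_equal(sites_per_mb(0, 123), 0)
  expect_equal(sites_per_mb(100, 2 * 5e7), 1)
  expect_error(sites_per_mb(1, 0), "undefined")
})

test_that("the editing index pools regions by adenosine coverage", {
  g <- paste(rep("A", 200), collapse = "")
  ref <- mini_ref(c(chr1 = g),
                  repeats = data.table(chrom = "chr1",
                                       start = c(1L, 101L),
                                       end = c(100L, 200L),
                                       te = c(TRUE, TRUE)))
  pp <- data.table(chrom = "chr1", pos = 1:200, strand = "+",
                   A = rep(c(98L, 92L), each = 100),
                   C = 0L, G = rep(c(2L, 8L), each = 100), T = 0L,
                   depth = 100L)
  # indices 0.02 and 0.08 at equal A+G coverage pool to 0.05
  expect_equal(editing_index(pp, ref), 0.05)
  zero <- copy(pp)[, `:=`(G = 0L, A = 100L)]
  expect_equal(editing_index(zero, ref), 0)
})

test_that("the editing index converges to the planted uniform TE level", {
  ref <- build_reference(small_spec(te_fraction = 0.4))
  te <- ref$repeats[te == TRUE]
  # plant every transcript-strand A inside TE intervals at level 0.05
  cand <- editome:::tx_adenosine_candidates(ref)
  ov <- editome:::point_overlaps(cand$chrom, cand$pos, te)
  sites <- cand[unique(ov$from), .(chrom, pos, strand)]
  sites$level <- 0.05
  truth <- plant_truth(ref, edit_scenario(sites = sites, n_snps = 0L,
                                          n_hyper_clusters = 0L, seed = 1L))
  # a large mismatch cap keeps even densely edited reads aligned, so the
  # index oracle sees every edited observation
  params <- read_sim_params(coverage_rna = 100, base_error_rate = 0,
                            aligner_mismatch_cap = 1000L, seed = 2L)
  sim <- simulate_reads(ref, truth, params, "T27", 1L, what = "rna")
  pp <- build_pileup(sim$rna, ref, source = "RNA")
  idx <- editing_index(pp, ref, intervals = te)
  n_ag <- 0
  ov2 <- editome:::point_overlaps(pp$chrom, pp$pos, te)
  sub <- pp[unique(ov2$from)]
  sub <- sub[editome:::ref_base_at(ref, sub$chrom, sub$pos, sub$strand) == "A"]
  se <- sqrt(0.05 * 0.95 / sum(sub$A + sub$G))
  expect_lt(abs(idx - 0.05), 3 * se)
})

test_that("exclusive intersections partition the union", {
  a <- data.table(chrom = "chr1", pos = 1:3, strand = "+")
  b <- data.table(chrom = "chr1", pos = 2:4, strand = "+")
  out <- intersection_sets(list(A = a, B = b))
  expect_identical(out[members == "A", count], 1L)
  expect_identical(out[members == "B", count], 1L)
  expect_identical(out[members == "A,B", count], 2L)
  # identical tables: only the full intersection class
  tri <- intersection_sets(list(x = a, y = a, z = a))
  expect_identical(nrow(tri), 1L)
  expect_identical(tri$count, 3L)
  expect_identical(tri$degree, 3L)
})

test_that("intersection class counts sum to the brute-force union size", {
  set.seed(43)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i)
      data.table(chrom = "chr1",
                 pos = sample.int(60L, sample(10:40, 1L)), strand = "+"))
    names(sets) <- LETTERS[1:4]
    out <- intersection_sets(sets)
    union_size <- length(unique(unlist(lapply(sets, function(s) s$pos))))
    expect_identical(sum(out$count), union_size)
  }
})

test_that("motif matrices are transcript-oriented and sum to one", {
  # genome: C A T, site at the A on the minus strand
  ref <- mini_ref(c(chr1 = "CCCATCCC"),
                  units = data.table(chrom = "chr1", start = 1L, end = 8L,
                                     strand = "-", kind = "intergenic",
                                     unit_id = "u1"))
  # minus-strand transcript A = genome T at position 5
  sites <- data.table(chrom = "chr1", pos = 5L, strand = "-")
  m <- motif_matrix(sites, ref)
  expect_equal(unname(m$freq["0", "A"]), 1)
  # transcript upstream (-1) = complement of genome base at pos+1 (C) = G
  expect_equal(unname(m$freq["-1", "G"]), 1)
  # transcript downstream (+1) = complement of genome base at pos-1 (A) = T
  expect_equal(unname(m$freq["+1", "T"]), 1)
  expect_equal(unname(rowSums(m$freq)), rep(1, 3), tolerance = 1e-9)
  expect_error(motif_matrix(data.table(chrom = "chr1", pos = 5L,
                                       strand = "*"), ref), "stranded")
})

test_that("simulated upstream bias is recovered from called-site motifs", {
  ref <- build_reference(genome_spec(seed = 7L))
  truth <- plant_truth(ref, edit_scenario(n_sites = 2000L,
                                          upstream_A_bias = 0.9,
                                          n_snps = 0L, n_hyper_clusters = 0L,
                                          seed = 7L))
  sites <- truth[truth$kind == "edit", ]
  m <- motif_matrix(sites, ref)
  expect_lt(abs(m$freq["-1", "A"] - 0.9), 0.03)
  expect_equal(unname(m$freq["0", "A"]), 1)
})

test_that("feature precedence resolves constructed transcript overlaps", {
  g <- random_dna(2000, seed = 47)
  feats <- data.table(
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    tx_id = c("g1_t1", "g1_t1", "g2_t1", "g2_t1", "g2_t1"),
    chrom = "chr1", strand = "+",
    type = c("CDS", "three_prime_utr", "CDS", "intron", "CDS"),
    start = c(100L, 400L, 300L, 501L, 801L),
    end = c(399L, 500L, 500L, 800L, 1100L),
    exon_rank = c(1L, NA, 1L, NA, 2L))
  ref <- mini_ref(c(chr1 = g), features = feats)
  # position 450: 3'UTR of g1 but CDS of g2 -> CDS wins
  expect_identical(feature_at(ref, "chr1", 450L, "+"), "CDS")
  # position 600: intron of g2 only
  expect_identical(feature_at(ref, "chr1", 600L, "+"), "intron")
  # position 1500: intergenic
  expect_identical(feature_at(ref, "chr1", 1500L, "+"), "intergenic")
  # opposite strand sees no matching features
  expect_identical(feature_at(ref, "chr1", 450L, "-"), "intergenic")
})

test_that("annotate_features fractions sum to one and split CDS sites", {
  ref <- build_reference(small_spec())
  truth <- plant_truth(ref, edit_scenario(n_sites = 400L, seed = 13L,
                                          n_snps = 0L,
                                          n_hyper_clusters = 0L))
  sites <- truth[truth$kind == "edit", c("chrom", "pos", "strand")]
  ann <- annotate_features(sites, ref)
  expect_equal(sum(ann$fractions), 1, tolerance = 1e-12)
  expect_true(all(ann$sites$feature %in%
                    c("five_prime_utr", "CDS-syn", "CDS-nonsyn", "intron",
                      "intergenic", "three_prime_utr")))
  expect_error(annotate_features(data.table(chrom = "chr1", pos = 10^9,
                                            strand = "+"), ref),
               "bounds")
})
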