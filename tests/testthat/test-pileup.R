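gseq <- random_dna(600, seed = 21)
ref_pu <- mini_ref(c(chr1 = gseq))

read_with_mismatch <- function(pos, offset, alt = "G", qual_at = NULL,
                               strand = "+") {
  s <- substring(gseq, pos, pos + 149L)
  substr(s, offset, offset) <- alt
  q <- strrep("I", 150L)
  if (!is.null(qual_at))
    substr(q, offset, offset) <- rawToChar(as.raw(33L + qual_at))
  make_read("chr1", pos, s, strand = strand, qual = q)
}

test_that("the six-base end trim removes read-end mismatches", {
  pp <- build_pileup(read_with_mismatch(10L, 4L), ref_pu, source = "RNA")
  expect_false((10L + 3L) %in% pp$pos)
  # a mid-read mismatch at the same quality does appear
  pp2 <- build_pileup(read_with_mismatch(10L, 75L), ref_pu, source = "RNA")
  expect_true((10L + 74L) %in% pp2$pos)
})

test_that("the Phred >= 30 floor gates individual bases", {
  lo <- build_pileup(read_with_mismatch(10L, 75L, qual_at = 29L), ref_pu)
  hi <- build_pileup(read_with_mismatch(10L, 75L, qual_at = 30L), ref_pu)
  expect_false((10L + 74L) %in% lo$pos)
  expect_true((10L + 74L) %in% hi$pos)
})

test_that("base counts add up over reads", {
  apos <- which(strsplit(gseq, "")[[1]] == "A")
  apos <- apos[apos > 160 & apos < 400][1]
  start <- apos - 75L
  reads <- rbindlist(c(
    lapply(1:3, function(i) read_with_mismatch(start, 76L, "G")),
    lapply(1:7, function(i) make_read("chr1", start,
                                      substring(gseq, start, start + 149L)))))
  pp <- build_pileup(reads, ref_pu, source = "RNA")
  row <- pp[pos == apos]
  expect_identical(row$A, 7L)
  expect_identical(row$G, 3L)
  expect_identical(row$depth, 10L)
})

test_that("raising the quality floor never increases any count", {
  set.seed(31)
  reads <- rbindlist(lapply(1:30, function(i) {
    pos <- sample(1:400, 1)
    q <- rawToChar(as.raw(33L + sample(20:40, 150L, replace = TRUE)))
    make_read("chr1", pos, substring(gseq, pos, pos + 149L), qual = q)
  }))
  p30 <- build_pileup(reads, ref_pu, min_base_quality = 30L)
  p35 <- build_pileup(reads, ref_pu, min_base_quality = 35L)
  j <- merge(p30, p35, by = c("chrom", "pos", "strand"), all.x = TRUE)
  for (b in c("A", "C", "G", "T"))
    expect_true(all(fifelse(is.na(j[[paste0(b, ".y")]]), 0L,
                            j[[paste0(b, ".y")]]) <= j[[paste0(b, ".x")]]))
})

test_that("minus-strand pileups are exact complements of genome space", {
  units <- data.table(chrom = "chr1", start = 1L, end = 600L, strand = "-",
                      kind = "intergenic", unit_id = "u1")
  ref_m <- mini_ref(c(chr1 = gseq), units = units)
  # a genome-strand T->C mismatch under a minus-strand transcript
  tpos <- which(strsplit(gseq, "")[[1]] == "T")
  tpos <- tpos[tpos > 160 & tpos < 400][1]
  start <- tpos - 75L
  pp <- build_pileup(read_with_mismatch(start, 76L, "C", strand = "-"),
                     ref_m, source = "RNA")
  row <- pp[pos == tpos]
  expect_identical(row$strand, "-")
  expect_identical(row$G, 1L) # transcript-space G = genome C
  # round-trip: transcript-strand ref base is A
  expect_identical(editome:::ref_base_at(ref_m, row$chrom, row$pos, "-"), "A")
})

test_that("unique-alignment and missing-quality filters reject reads", {
  r_ok <- make_read("chr1", 10L, substring(gseq, 10, 159))
  r_mapq0 <- make_read("chr1", 10L, substring(gseq, 10, 159), mapq = 0L)
  r_sec <- make_read("chr1", 10L, substring(gseq, 10, 159), flag = 256L)
  r_noq <- make_read("chr1", 10L, substring(gseq, 10, 159))
  r_noq$qual <- "*"
  pp <- build_pileup(rbind(r_ok, r_mapq0, r_sec, r_noq), ref_pu)
  expect_identical(max(pp$depth), 1L)
  rej <- attr(pp, "rejected")
  expect_identical(unname(rej["nonunique"]), 2L)
  expect_identical(unname(rej["no_quality"]), 1L)
})

test_that("DNA variant masking follows depth and alt-support rules", {
  apos <- which(strsplit(gseq, "")[[1]] == "A")
  apos <- apos[apos > 160 & apos < 400]
  p1 <- apos[1]; p2 <- apos[2]
  mk <- function(pos, n_alt, n_ref) {
    start <- pos - 75L
    rbindlist(c(
      lapply(seq_len(n_alt), function(i) read_with_mismatch(start, 76L, "G")),
      lapply(seq_len(n_ref), function(i)
        make_read("chr1", start, substring(gseq, start, start + 149L)))))
  }
  dp <- build_pileup(rbind(mk(p1, 5L, 10L), mk(p2, 0L, 30L)), ref_pu,
                     source = "DNA")
  mask <- mask_dna_variants(dp, ref_pu, min_dna_depth = 10L,
                            min_alt_reads = 2L)
  expect_true(p1 %in% mask$masked$pos)
  expect_false(p2 %in% mask$masked$pos)
  expect_true(p2 %in% mask$callable$pos)
  # depth below min_dna_depth: uncallable, excluded downstream
  dp_low <- build_pileup(mk(p1, 0L, 4L), ref_pu, source = "DNA")
  mask_low <- mask_dna_variants(dp_low, ref_pu, min_dna_depth = 10L)
  expect_false(p1 %in% mask_low$callable$pos)
  rna <- build_pileup(mk(p1, 5L, 10L), ref_pu, source = "RNA")
  calls <- call_sites(rna, ref_pu, mask_low)
  expect_identical(nrow(calls), 0L)
})

test_that("read-end-only edits never reach the pileup", {
  apos <- which(strsplit(gseq, "")[[1]] == "A")
  apos <- apos[apos > 200 & apos < 400][1]
  # every read carries the mismatch within 6 bases of one of its ends
  reads <- rbindlist(c(
    lapply(1:6, function(o) read_with_mismatch(apos - o + 1L, o, "G")),
    lapply(145:150, function(o) read_with_mismatch(apos - o + 1L, o, "G"))))
  pp <- build_pileup(reads, ref_pu, source = "RNA")
  row <- pp[pos == apos]
  expect_identical(sum(row$G), 0L)
})
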