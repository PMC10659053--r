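---
title: "Methods: the editome detection, quantification and differential-editing models"
author: "editome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the editome detection, quantification and differential-editing models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`editome` characterises adenosine-to-inosine (A-to-I) RNA editing by
comparing stranded RNA-seq alignments against DNA-seq from the same
individual. Inosine is read as guanosine, so editing manifests as A-to-G
mismatches in transcript orientation. The package covers four linked
analyses — site detection (normal and hyper-edited), quantification,
differential editing between conditions, and CDS recoding — and ships a
synthetic-editome simulator with planted truth so that each stage can be
validated end to end against a known answer.

This vignette documents the models, the parameters that matter (with
units and defaults), the numerical choices, and what the synthetic
validation does and does not demonstrate about real data.

# Filtered pileups

All calling is driven by per-position, per-transcript-strand base counts
(`build_pileup()`). A base contributes if and only if:

* its 1-based offset within the read lies in `[trim_bases + 1,
  L - trim_bases]` (default `trim_bases = 6`), suppressing the
  alignment-artefact-prone read ends;
* its Phred quality is at least `min_base_quality` (default 30, an
  error probability of about 0.1%);
* the read is uniquely aligned (`unique_only = TRUE`): mapping quality
  above 0 and neither secondary nor supplementary. The uniqueness rule
  is the conventional operationalisation of "unique alignment"; it is a
  package decision and is configurable.

RNA bases are assigned to the transcript strand decoded from the library
protocol (`forward`: read orientation equals transcript strand;
`reverse`: opposite) and are recorded in transcript orientation, so a
genomic T→C mismatch under a minus-strand transcript is counted as an
A-strand pileup with a G alternate. The six-base trim is applied to DNA
reads as well as RNA for symmetry; a separate trim can be set per call
if asymmetric handling is wanted.

# SNP masking and callability

DNA-seq is the only SNP source (`mask_dna_variants()`). A position is
masked when its filtered DNA depth reaches `min_dna_depth` (default 10)
and any non-reference base has at least `min_alt_reads` (default 2)
supporting reads — "supported by a sufficient number of reads" made
concrete and configurable. Positions below `min_dna_depth` are
*uncallable*: there the data cannot distinguish editing from an unseen
genomic variant, so they are excluded from calling entirely rather than
treated as reference.

# Normal site calling

`call_sites()` calls a site when all of the following hold:

1. the position is callable and unmasked;
2. filtered RNA depth ≥ `min_rna_depth` (default 10);
3. exactly one alternate base is observed. Read literally, "two or more
   variants" would exclude almost every deep site because sequencing
   error eventually shows every base; a second alternate therefore only
   counts as *observed* at `multi_allele_min` reads (default 2), below
   which it is treated as noise;
4. the alternate has ≥ `min_edited_reads` supporting reads (default 3);
5. the one-sided binomial tail probability
   `P(X ≥ G | n = depth, p = error_rate)` survives Benjamini–Hochberg
   correction at `fdr = 0.05` across all candidate sites.

`error_rate` defaults to 0.001, matching the Phred-30 quality floor: a
base that passed the quality filter misreports with probability at most
about 0.1%. Using the full depth as the binomial denominator (rather
than depth/3 per specific alternate base) is deliberately conservative.

Called sites carry transcript-oriented counts: the editing level is
`G/(G + A)` with `G` the edited-base and `A` the reference-base count.
The twelve possible mismatch types are reported in transcript
orientation (`classify_type()`); unstranded sites get an `NA` type and
are excluded from motif analyses.

## Realignment uniqueness check

Reads supporting a call are re-examined with an internal exact-k-mer
seed-and-extend aligner (`realignment_check()`): seeds of length `k`
(default 16) from the start, middle and end of the read are matched
exactly against both genome strands (via `Biostrings::matchPDict`), each
seed hit proposes an ungapped candidate alignment, and candidates are
scored by matching bases. A read is ambiguous when a second locus scores
at least `margin × best` (default margin 0.95); any ambiguous supporting
read drops the site. This preserves the contract of the conventional
BLAT re-check — discard calls supported by multimapping reads — without
an external binary. `margin = Inf` disables the filter.

# Hyper-editing recovery

Heavily edited reads fail normal alignment because their mismatch count
exceeds what aligners tolerate; they occur in clusters and are missed by
pileup-based calling. `transform_and_realign()` recovers them with the
standard transformation scheme: rewrite every A to G in both the read
and the genome, erasing A-to-G mismatches, then realign by exact k-mer
seeding and ungapped extension. Reads from minus-strand transcripts are
handled by reverse-complementing the read and matching in T→C
transformed genome space, so strandedness survives the transform. A hit
is kept only if it is unique across both transformed strands and carries
at most `max_other_mm` (default 1) non-A-to-G mismatches.

`cluster_filter()` then retains reads with at least `min_edits_per_read`
(default 5) recovered edits whose edit fraction over the adenosines in
the aligned span is at least `min_edit_fraction` (default 0.05), and
aggregates surviving reads into per-position hyper-edited sites. The
thresholds were chosen once so that planted clusters are recoverable
while an error-only null yields nothing, and are configurable; the
upstream tool this mirrors does not publish its internal values.

`merge_modes()` unifies normal and hyper calls: sites found by both
routes become `common` and are counted once (keeping normal-route counts
for the level, since those passed the full statistical filter), alt-base
conflicts are excluded and reported, and the counts satisfy
`union = normal_only + hyper_only + common` exactly on every run.

# Quantification

* **Editing level**: `G/(G + A)` per site; undefined at `G + A = 0`.
* **Overall editing level**: `ΣG / Σ(G + A)` over a site set — an
  algebraic identity with the coverage-weighted mean of per-site levels,
  asserted to machine precision in the tests. All level-type statistics
  enforce a minimum site coverage of 10 reads; site *counts* do not.
* **Sites per Mb**: `n_sites / (mapped_bases / 1e6)`, with mapped bases
  counted after filtering.
* **Editing index**: `ΣG / Σ(A + G)` over every transcript-strand
  reference-adenosine inside repeat (or TE) intervals — a site-list-free
  global measure. Whether the denominator should be A+G reads or total
  depth is genuinely open; A+G is the default for consistency with the
  level definition and `denominator = "total"` is available.
* **Feature annotation**: precedence CDS > UTR > intron > intergenic
  across overlapping transcripts (the annotation itself does not say how
  to resolve overlaps); 5′ versus 3′ UTR is taken from the transcript
  that supplied the winning class, and CDS sites are split
  synonymous/non-synonymous by the recoding annotator. "Repeat" regions
  are any interval in the repeat set; "TE" is its flagged subset —
  the partition is an input, not an inference.
* **Intersections**: every distinct site goes to exactly one of the
  `2^k − 1` exclusive membership classes, so class counts sum to the
  union size.
* **Motif matrices**: −1/0/+1 neighbour-base frequencies in transcript
  orientation; position 0 is 100% A by construction; boundary sites have
  the missing neighbour skipped and counted.

# Differential editing

For each site with edited/total counts `(k, n)` per replicate in two
groups, `lrt_binomial_glm()` fits the binomial logistic regression
`logit p = b0 + b1·group` and tests `b1 = 0` by likelihood ratio against
χ²(1). Replicates within a group share the group proportion (no
overdispersion term), so the maximised likelihoods close over the pooled
group counts and the statistic equals the likelihood-ratio (G) statistic
of the pooled 2×2 table; the tests verify this against a brute-force
likelihood maximisation oracle, against `stats::glm` deviances, and
against the closed-form G-test in the single-replicate case. Boundary
configurations (all-zero or fully edited in both groups) give D = 0 and
p = 1 without NaNs.

`differential_editing()` requires every replicate in both groups to meet
the 10-read coverage rule (the level-statistic rule extended to
testing), applies BH-FDR across testable sites, and classifies at
`q < 0.05` with difference thresholds of 0.10 and 0.20 ("10p"/"20p");
calls at 20p are nested within 10p by construction. The difference Δ is
the difference of *pooled* group levels by default, mirroring the
count-based GLM; a replicate-mean variant is available
(`delta_mode = "mean"`) since either reading of "difference value" is
defensible. Comparisons between more than two conditions run pairwise.
No overdispersion correction is applied; truly overdispersed data will
be anti-conservative here, which is a known limitation shared with the
plain logistic-regression mode of the methylation tools this follows.

# Recoding

`codon_consequence()` rebuilds the codon containing each CDS site in
transcript orientation, substitutes G for the edited A, and translates
under the standard genetic code. Stop-codon changes are labelled
`stop_gain`/`stop_loss` rather than folded into non-synonymous (A→G can
destroy but never create a stop, which the exhaustive 64-codon oracle in
the tests confirms). Events are counted per site with one representative
transcript (the reference carries one isoform per gene; with multiple
isoforms the worst-case consequence is reported at site level), and
`substitution_matrix()` tallies (reference aa, edited aa) pairs.

# The synthetic editome

The simulator is first-class, tested code, and its defaults *are* the
validation conditions:

* **Genome** (`genome_spec()`): one 200 kb chromosome at GC 0.42 with 20
  non-overlapping genes (200 bp 5′UTR, 1200 bp CDS in 3 exons, 400 bp
  introns, 500 bp 3′UTR) on random strands, and repeat intervals
  covering 35% of intergenic space, 70% of them flagged TE.
* **Scenario** (`edit_scenario()`): 1,000 edit sites with true levels
  uniform on 0.1–0.9, placed on transcript-strand adenosines with a
  feature mix dominated by intergenic (51%), intron (27%) and 3′UTR
  (19%) sites; an upstream-adenosine motif bias of 0.9 (and a milder
  downstream-G preference); 200 SNPs (half heterozygous); 12
  hyper-edited clusters of 8 adenosines within 60 bp, edited per read
  with probability 0.9; three conditions labelled T27/T18/T13 with three
  replicates each, 15% of sites condition-dependent with a 0.2 level
  shift (rising in the cold for 80% of them — falling temperatures
  increasing editing is the commonly observed direction).
* **Reads** (`read_sim_params()`): 150 bp single-end reads at 50× RNA /
  30× DNA with 0.1% uniform base error and matching Phred qualities.
  RNA reads are drawn uniformly within *transcription units* — gene
  pre-mRNAs plus strand-assigned intergenic units (lincRNA-like
  transcription) that tile the chromosome — so intronic and intergenic
  sites receive strand-resolved coverage as in a total editome. Each
  read covering an edit carries G (transcript strand) with probability
  equal to the site's true level, independently per read; DNA reads
  carry SNP alleles but never edits.
* **Aligner emulation**: reads are emitted pre-aligned at their true
  coordinates with ungapped CIGARs (isolating the pipeline's own filters
  from aligner behaviour), except that any read exceeding
  `aligner_mismatch_cap` mismatches (default 4 per 150 bp) becomes an
  unaligned record — the standard hyper-editing premise. The true
  tolerance at which real aligners drop hyper-edited reads is not
  published; the cap is exposed as configuration. One knock-on effect is
  deliberate and worth knowing: dense low-level editing loses its most
  heavily edited reads to the unmapped pool, biasing pileup-based level
  estimates slightly downward there — exactly the phenomenon
  hyper-editing recovery exists to correct. The estimator-convergence
  test therefore raises the cap to isolate the estimator from this
  routing.

Determinism is a hard contract: identical (spec, scenario, parameters,
seed) yield byte-identical FASTA/GTF/BED/SAM/truth outputs, and the
pipeline manifest (including file checksums) reproduces exactly.

**What the simulator does not emulate**: indels and splice-aware
alignment (ungapped reads only — substitution detection does not depend
on them, and splice handling belongs to the upstream aligner in real
workflows), PCR duplicates, non-uniform coverage, position- or
context-dependent error models, quality-score miscalibration, paired-end
fragments, allele-specific expression, and genuine alignment errors
other than the mismatch-cap dropout. Passing the planted-truth checks
therefore demonstrates the correctness of the package's *filters,
statistics and bookkeeping*, not robustness to every artefact of real
libraries.

# Numerical choices and degenerate inputs

* Binomial tails via `pbinom(..., lower.tail = FALSE)`; BH via
  `stats::p.adjust`.
* The LRT uses the closed-form pooled-proportion likelihoods with
  `0·log 0 = 0`; the statistic is clamped at 0 against floating-point
  negatives.
* Empty candidate sets, empty site tables and zero-denominator
  statistics return empty tables or explicit "undefined" errors — never
  NaNs.
* Ties in alternate-base selection resolve to the first base in A<C<G<T
  order; a tied second alternate then triggers the multi-allele
  exclusion at the usual threshold.
* Coordinates are 1-based closed throughout (SAM/GTF convention); BED
  input/output converts at the boundary (0-based half-open).
* Sub-seeds for conditions/replicates are derived from the master seed
  with a fixed integer recurrence kept inside 32-bit range.

# Problem sizes used in validation

The shipped tests run the full detection scenario at its native size
(200 kb, 1,000 sites, 50×/30×), the hyper-editing recovery on all
planted clusters, differential calibration on 10 null simulations of
2,000 sites (3 replicates per group, depth 50), the power grid at
Δ ∈ {0.05, 0.1, 0.2, 0.3} × depth ∈ {20, 50, 100} with 400 sites per
cell, and the oracle equivalence on 50 random count configurations.
Smaller genomes (30–50 kb) back the constructed unit tests. These sizes
were chosen to give stable Monte-Carlo margins (binomial standard errors
well inside the asserted tolerances) at desk-scale runtimes.

# Known limitations

* No overdispersion/beta-binomial option in the differential test.
* No multi-factor designs (e.g. tissue × temperature interactions).
* Feature annotation assumes non-overlapping gene models on a strand
  resolve by the stated precedence; nested antisense genes are untested
  territory.
* The editing index is computed from the pileup the caller saw; it
  inherits the mismatch-cap dropout discussed above unless hyper reads
  are folded back in.
* The realignment check samples up to a fixed number of supporting
  reads per site (default 3) for tractability.
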