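# editome

Detection, quantification and differential analysis of A-to-I RNA editing
from matched DNA-seq and stranded RNA-seq data, with a fully deterministic
synthetic editome for end-to-end validation.

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA.
Because inosine base-pairs like guanosine, edited positions appear as
A-to-G mismatches between RNA-seq reads and the genomic DNA of the same
individual. Characterising an editome therefore means separating true
editing from genomic SNPs, sequencing error and misalignment — and
recovering the *hyper-edited* reads that carry so many A-to-G changes
that they fail normal alignment altogether. Once sites are called, the
questions become quantitative: how strongly is each site edited, how does
editing distribute over genomic features and repeat/TE space, which CDS
edits recode amino acids, and which sites change between conditions
(for example acclimation temperatures) across replicated libraries.

`editome` implements that workflow for R users:

* **Filtered pileups** — per-position, per-transcript-strand base counts
  after trimming the first and last 6 bases of each aligned read,
  requiring Phred ≥ 30 and unique alignment.
* **SNP masking from DNA-seq** — positions with sufficient DNA depth and
  ≥ 2 alternate reads are masked; positions with insufficient DNA depth
  are uncallable.
* **Normal site calling** — a site is called when RNA depth ≥ 10, exactly
  one alternate base is observed with ≥ 3 supporting reads, and the
  one-sided binomial tail P(X ≥ G | n, error rate) survives BH-FDR at 5%
  across candidates; supporting reads are re-checked for alignment
  uniqueness with an internal k-mer seed-and-extend realigner.
* **Hyper-editing recovery** — unmapped reads are realigned after an
  A→G transformation of read and genome (T→C genome space for
  minus-strand transcripts); reads with ≥ 5 recovered edits and edit
  fraction ≥ 5% of the adenosines in their span define hyper-edited
  sites, merged with the normal calls under exact inclusion–exclusion
  accounting.
* **Quantification** — per-site editing level `G/(G+A)`, overall level
  `ΣG/Σ(G+A)` (the coverage-weighted mean), per-Mb site density, the
  repeat *editing index* (ΣG/Σ(A+G) over all reference-A positions in
  repeat/TE intervals), feature annotation with CDS > UTR > intron >
  intergenic precedence, UpSet-style exclusive intersections and
  neighbour-base motif matrices.
* **Differential editing** — per-site binomial logistic regression
  (likelihood-ratio test against χ²(1)) over replicated edited/total
  counts, BH-FDR at 5%, and up/down classification at 10% and 20%
  difference values.
* **Recoding** — codon consequences of CDS edits under the standard
  genetic code and the amino-acid substitution matrix.
* **Synthetic truth** — a simulator that generates a genome, gene
  models, repeats, planted SNPs/edit sites/hyper clusters and stranded
  reads with known per-condition editing levels, so every stage is
  testable against planted truth without external data.

## Worked example

A small end-to-end run on synthetic data (about 20 seconds):

```r
library(editome)
cfg <- default_config()
cfg$genome   <- list(chrom_length = 50000L, n_genes = 5L)
cfg$scenario <- list(n_sites = 200L, n_snps = 40L, n_hyper_clusters = 3L,
                     conditions = c("T27", "T13"),
                     replicates_per_condition = 3L)
cfg$reads    <- list(coverage_rna = 20)
cfg$seed     <- 7L
run <- run_pipeline(cfg, quiet = TRUE)
print(run)
#> editome_run
#>   normal sites: 201  hyper sites: 42  common: 14
#>   A-to-G fraction: 1
#>   planted-site precision: 0.99  recall: 0.995
```

201 normal sites were called against 200 planted (precision 0.99,
recall 0.995 versus the truth table), 42 hyper-edited positions were
recovered from unalignable reads, and every called mismatch type is the
canonical A-to-G. The summaries carry the quantitative picture:

```r
round(unlist(run$stats$region_fractions), 3)
#>  five_prime_utr         CDS-syn      CDS-nonsyn          intron      intergenic
#>           0.009           0.000           0.017           0.240           0.563
#> three_prime_utr
#>           0.170
round(run$stats$motif, 3)
#>        A     C     G     T
#> -1 0.817 0.066 0.061 0.057
#> 0  1.000 0.000 0.000 0.000
#> +1 0.214 0.140 0.463 0.183
run$differential$T27_vs_T13$summary
#>     diff    up  down    ns
#> 1:   0.1    10     2   164
#> 2:   0.2     7     2   167
```

The feature mix mirrors the planted scenario (editing dominated by
intergenic, intron and 3'UTR sites), the motif matrix recovers the
planted upstream-adenosine preference (0.82 here at n = 201 sites; the
generator's bias is 0.9), and the temperature comparison classifies
differential sites at the 10%/20% difference thresholds under 5% FDR.
With an `outdir`, the same call writes FASTA/GTF/BED/TSV/VCF/JSON
outputs plus a manifest with parameters, per-stage filter accounting and
file checksums.

## Command-line interface

A thin wrapper over the same functions lives in `inst/scripts/editome.R`
(installed under `system.file("scripts", "editome.R", package = "editome")`):

```sh
Rscript inst/scripts/editome.R all --config run.yaml --outdir out/
Rscript inst/scripts/editome.R simulate --outdir sim/ --seed 7
```

See the methods vignette (`vignettes/editome-methods.Rmd`) for the
models, parameter choices and limitations.
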