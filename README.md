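# gwaspect

Genome-wide association analysis of seed shape for diversity panels of
inbreeding crops, built around the seed **aspect ratio** (major axis /
minor axis of the seed outline, a dimensionless number ≥ 1). The package
covers the whole path from raw inputs to candidate genes:

1. **Morphometrics** — seed aspect ratios measured from binary scan images
   by equivalent-ellipse moments, averaged per accession, with a
   Shapiro–Wilk/QQ normality check.
2. **Marker QC** — per-SNP missingness, heterozygosity and minor allele
   frequency; the standard filter drops markers with missingness > 20%,
   heterozygosity > 20% or MAF < 0.01, plus a sensitivity sweep over the
   heterozygosity threshold.
3. **Population structure** — allele-sharing genetic distances and
   principal coordinate analysis (PCoA) with per-axis variance fractions.
4. **Association** — a kinship mixed linear model per marker,
   `y = μ + xβ + u + e` with `u ~ N(0, σ²_g K)` (VanRaden kinship K,
   EMMA-style spectral REML, P3D by default), Wald tests, and
   Benjamini–Hochberg FDR control.
5. **Linkage disequilibrium** — D, D′ and r² for unphased genotypes via a
   two-locus EM, Hill–Weir decay-curve fitting with a decay distance at
   r² = 0.1, strong-LD windows (D′ ≥ 0.80) around peak SNPs, and
   candidate-gene extraction from GFF3 annotation within ±150 kb.
6. **Stability selection** — LASSO/elastic-net marker selection under the
   penalty `λα‖β‖₁ + λ(1−α)‖β‖₂²` with bootstrap selection probabilities
   (B = 100), the theoretical threshold `π_θ = q²_Λ/(2θp) + ½` and a
   permutation-based empirical threshold `π*_θ`.

A first-class synthetic-data module simulates structured genotype panels
(Balding–Nichols subpopulations, blockwise LD with a controllable decay
scale, array-style missingness/heterozygosity contamination), aspect-ratio
phenotypes and seed images, with ground-truth records for
parameter-recovery tests — so the entire pipeline is testable without any
proprietary array data.

## Worked example

```r
library(gwaspect)

panel <- simulate_panel(n_accessions = 384, n_snps = 2000,
                        n_chromosomes = 4, seed = 7)
flt <- filter_snps(panel$genotypes)
Gf  <- flt$genotypes

causal <- snp_stats(Gf)$snp_id[200]   # "S01_38893484"
phen <- simulate_phenotype(Gf,
                           causal = data.frame(snp_id = causal, effect = 0.1),
                           h2_polygenic = 0.3, noise_sd = 0.05, seed = 8)

K    <- kinship(Gf)
scan <- mlm_scan(Gf, phen$phenotypes, K)
head(scan, 3)
#> # A tibble: 3 × 8
#>   snp_id       chrom      pos    maf effect      se  p_value fdr_adjusted_p
#>   <chr>        <chr>    <int>  <dbl>  <dbl>   <dbl>    <dbl>          <dbl>
#> 1 S01_38893484 chr01 38893484 0.0936 0.0961 0.00803 3.06e-28       5.12e-25
#> 2 S01_29344535 chr01 29344535 0.132  0.0256 0.00687 2.30e- 4       1.54e- 1
#> 3 S01_38852757 chr01 38852757 0.0577 0.0316 0.00862 2.77e- 4       1.54e- 1
```

The causal marker (planted with a 0.1 aspect-ratio-unit effect per minor
allele) is the top hit with its effect estimated at 0.096, and only it
survives FDR control; the runners-up include a linked neighbour ~40 kb
away. From here:

```r
significance_report(scan)            # FDR < 0.05 and p < 1e-4 lists
strong_ld_window(Gf, scan$snp_id[1]) # D' >= 0.80 window around the peak
prof <- selection_probability(Gf, phen$phenotypes, B = 100, seed = 9)
theoretical_threshold(prof$q_avg, theta = 1, p = prof$p)
run_pipeline(list(synthetic = list(n_accessions = 200, n_snps = 1000),
                  seed = 1, output_dir = "demo_run"))  # end to end
```

`autoplot()` methods draw the PCoA scatter, the LD decay curve and the
selection-probability profile; `plot_manhattan()` / `plot_qq()` cover the
scan.

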