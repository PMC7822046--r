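---
title: "Seed aspect-ratio GWAS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed aspect-ratio GWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaspect)
```

This vignette is the package's account of the science it implements: the
statistical models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where a
design decision was genuinely open.

## The trait and its measurement

Seed shape is summarised by the **aspect ratio**: the seed's major axis
divided by its minor axis, dimensionless and ≥ 1 (1 is a circle).
`measure_seeds()` labels 8-connected foreground components of a binary scan
image and measures each by its *equivalent ellipse* — the ellipse with the
same second central moments as the pixel set. For a uniform ellipse the
covariance eigenvalues are $a^2/4$ and $b^2/4$, so the ratio is
$\sqrt{\lambda_1/\lambda_2}$; this is the standard morphometric "fit
ellipse" notion. Whether the original image tool used fitted-ellipse or
Feret (caliper) axes is generally not documented by imaging pipelines; for
convex seed outlines the two differ negligibly, and the moment definition
is rotation- and translation-invariant by construction (verified to a
0.02 discretization tolerance in the tests). Components below `min_area`
(default 10 px) or touching the image border are dropped; touching seeds
are *not* split — scans are expected to have seeds spaced apart, and a
watershed step is out of scope. Grayscale input is accepted via Otsu
thresholding as a logged convenience.

Per accession the customary protocol scans ten seeds;
`accession_aspect_ratio()` takes the arithmetic mean and warns when the
count differs from ten. `normality_check()` provides standard-normal QQ
pairs at plotting positions $(i - 0.5)/n$ and a Shapiro–Wilk test
(verdict "normal" iff $p \ge 0.05$), since the mixed model downstream
assumes a roughly Gaussian trait.

## Marker quality control

`snp_stats()` computes, per SNP: missing-call rate; heterozygosity among
non-missing calls; and minor allele frequency over non-missing calls, two
alleles per diploid. MAF and heterozygosity are computed over non-missing
calls only — the usual convention, chosen explicitly since array pipelines
rarely state it. `filter_snps()` removes a SNP iff missingness > 20%,
heterozygosity > 20% or MAF < 0.01, with **strict** inequalities, so a SNP
at exactly a boundary is kept (the printed thresholds read as strict; a
boundary SNP at MAF exactly 0.01 survives). All statistics come from the
input matrix before any removal, which makes the filter idempotent. The
removal log attributes each dropped SNP to the first matching reason in
the order missing → het → maf; the precedence affects only the log, never
the retained set. Per-accession missingness is reported but no accessions
are dropped.

The 20% heterozygosity filter matters because highly selfing crops such as
peanut are nearly homozygous: an excess of heterozygous calls at a marker
is an array-genotyping artifact, not biology. `het_sensitivity_sweep()`
re-runs filter + scan over a ladder of heterozygosity thresholds (5%, 10%,
then every 10% to 100%) and reports marker counts and significance counts
at FDR 0.05 and raw p < 1e-4, showing how tolerated heterozygosity trades
specificity for extra (unvalidated) hits.

## Population structure

`genetic_distance()` uses the per-locus allele-sharing dissimilarity
$d(i,j) = \operatorname{mean}_m |x_{im} - x_{jm}|/2 \in [0, 1]$ over SNPs
non-missing in both accessions. This transparent metric stands in for the
codominant genotypic distance of classical population-genetics toolkits,
whose exact option sets are rarely reported; missing data are handled
pairwise rather than by imputation to keep distances unbiased.
`pcoa()` is classical metric MDS: Gower double-centering of $-D^2/2$,
eigendecomposition, axes ordered by eigenvalue. Negative-eigenvalue axes
(the metric is not exactly Euclidean) carry no representable variance:
they are dropped and excluded from the variance denominator, so the
reported per-axis fractions sum to one over the positive spectrum.

## The kinship mixed model

Association testing uses the standard kinship mixed linear model
$y = \mu\mathbf{1} + x\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$, testing $\beta$ per marker with a Wald
t-test. Design choices:

* **Kinship**: VanRaden method 1 with per-SNP mean imputation of missing
  calls, plus a ridge of $10^{-6}\,\overline{K_{ii}}$ for numerical
  positive-definiteness. For a fully inbred panel $K_{ii} \approx 1 + F
  \approx 2$; the reported $h^2$ therefore uses the per-accession genetic
  variance $\sigma_g^2 \overline{K_{ii}}$, not the raw ratio.
* **REML**: one spectral decomposition of $K$ reduces the restricted
  likelihood to a 1-D function of $\lambda = \sigma_g^2/\sigma_e^2$,
  maximized on an 81-point log grid over $e^{\pm 10}$ followed by
  golden-section refinement to $10^{-6}$. A boundary optimum triggers a
  "heritability at bound" warning (routine on permuted/null phenotypes).
* **P3D**: by default variance components are estimated once from the
  no-marker model and fixed for all marker tests — the standard
  compromise that makes a 14k-marker scan a single whitening transform
  plus vectorized least squares. `mode = "full_reml"` re-estimates them
  per marker. Compression-style accession clustering used by some mixed
  -model packages is a speed heuristic, not a different inferential
  model, and is not reimplemented.
* **Covariates**: kinship-only by default; leading PCoA axes can be added
  as fixed effects (`covariates` / `n_pcs`), but structure control is
  primarily K's job and the default keeps the model minimal.
* Missing genotypes are mean-imputed per SNP for testing; monomorphic
  markers are skipped with a message. With $\sigma_g^2$ forced to 0 the
  scan provably reduces to ordinary least squares (tested to $10^{-8}$).

Multiplicity is handled by Benjamini–Hochberg: `bh_fdr()` implements the
step-up rule $\text{adj}_{(i)} = \min_{j \ge i} p_{(j)} m / j$ capped at
1, with an `m_total` argument so a printed table of top hits can be
adjusted against the full test count $m$ (the count of QC-surviving
markers). Report conventions: "significant" means adjusted p < 0.05,
"candidate" means raw p < 1e-4.

## Linkage disequilibrium

Array genotypes are unphased, so two-locus haplotype frequencies come from
an EM over the double-heterozygote phase ambiguity (`two_locus_em()`),
initialized at linkage equilibrium and iterated to $10^{-8}$ or 100
iterations. Because both phasings of a double heterozygote carry the same
allele counts, the EM preserves the observed allele-frequency margins,
which reduces the likelihood to a 1-D family — the property the
grid-search oracle in the tests exploits. From the frequencies:
$D = f_{AB} - f_A f_B$; $D' = |D|/D_{\max}$ with
$D_{\max} = \min(f_A f_b, f_a f_B)$ for $D > 0$ and
$\min(f_A f_B, f_a f_b)$ otherwise; $r^2 = D^2/(f_A f_a f_B f_b)$.
A monomorphic margin leaves $D'$ and $r^2$ undefined (returned as `NA`).
Note $r^2 \le D'$ is *not* a theorem and is never asserted.

`pairwise_ld()` restricts to intra-chromosomal pairs with MAF strictly
above 0.01, optionally capped by distance (`max_bp`) and subsampled
(`max_pairs`, seeded) — decay estimation does not need every one of the
$\binom{m}{2}$ pairs. `decay_fit()` fits, for $r^2$, the Hill–Weir drift
expectation with its finite-sample term (sample size $n$ = number of
chromosomes, i.e. $2\times$ accessions), a one-parameter nonlinear
least-squares problem solved on a log grid; for $D'$, a monotone
exponential-plus-floor $a e^{-d/b} + c$ via Levenberg–Marquardt. The
**decay distance** is the smallest distance where the fitted curve equals
the cutoff (bisection to 1 bp), 0 if it starts below, `Inf` if the
asymptote never crosses. The default statistic is $r^2$ at cutoff 0.1 —
the convention behind headline "LD decays by ~150 kb" figures — while
$D'$ remains available because descriptive LD reporting often quotes it.

`strong_ld_window()` grows an interval from an index SNP, admitting each
next marker while its $D'$ with the index is ≥ 0.80 and stopping at the
first failure per side — an index-anchored simplification of
confidence-interval block finding (Gabriel-style blocks are a non-goal).
`candidate_genes()` intersects an interval (or peak ± 150 kb flank) with
gene models using inclusive-coordinate overlap; the flank is
configurable because reported candidate regions in practice vary between
the LD-decay flank (±150 kb) and wider strong-LD spans.

## Stability selection

The selection model is the penalized least-squares objective
$$Q(\beta) = \tfrac{1}{2n}\lVert y - X\beta\rVert^2
  + \lambda\alpha\lVert\beta\rVert_1
  + \lambda(1-\alpha)\lVert\beta\rVert_2^2,$$
with the quadratic term carrying **no factor ½** — the form is
implemented exactly as printed in the method it follows, and the mapping
to the common library convention ($\lambda_g\alpha_g = \lambda\alpha$,
$\lambda_g(1-\alpha_g)/2 = \lambda(1-\alpha)$) is cross-checked against
an independent solver in the tests. $\alpha = 1$ (the default, LASSO) is
the regime the selection procedure is reported in; the elastic-net
generalization is exposed. The solver is cyclic coordinate descent with
soft thresholding (convergence at $10^{-7}$ max coefficient change) and
an active-set strategy, in compiled code.

`selection_probability()` chooses $\lambda$ **once** on the full data by
5-fold cross-validated MSE over a 30-point log grid from $\lambda_{max}$
down to $\lambda_{max}/100$, then holds it fixed across $B = 100$
bootstrap resamples (n-out-of-n with replacement; each resample is
restandardized). Fixing $\lambda$ makes the selection probability a
well-defined per-marker quantity, consistent with the stability-selection
literature; a max-over-the-grid variant (`lambda_per_fit`) and
half-sample subsampling are available behind flags. The selection
probability of marker $j$ is the fraction of resamples with
$\hat\beta_j \ne 0$, and $q_\Lambda$ is the mean selected-set size.

Two thresholds control false selections at a tolerated expected count
$\theta$ (default 1):

* theoretical: $\pi_\theta = q_\Lambda^2/(2\theta p) + \tfrac12$
  (`theoretical_threshold()`; values above 1 are returned as computed,
  with a warning, never silently capped);
* empirical: $\pi^*_\theta$, the mean over `B_perm` phenotype
  permutations of the $\theta$-th largest selection probability obtained
  by rerunning the bootstrap procedure on the permuted data
  (`empirical_threshold()`). The penalty is held at the value used for
  the observed-data profile (pass `prof$lambda`): the permutations must
  estimate the null of *that* procedure — re-tuning $\lambda$ per
  permutation yields the null of a typically sparser procedure and, when
  cross-validation happened to choose a small $\lambda$ on the observed
  data, an anti-conservative threshold. `B_perm` defaults to 20 — the
  permutation count is rarely stated in applications, and 20 keeps the
  $21 \times B$ model fits affordable while the tests show false
  selections are controlled at this setting; raise it for a steadier
  threshold.

`select_markers()` applies a strict `>` comparison (so probability-1.0
markers survive any threshold below 1, and a threshold of exactly 1 —
possible when $q_\Lambda$ is large — selects nothing), ranking by
probability with genome-order tie-breaks.

## The synthetic-data generator

`simulate_panel()` emulates the statistical structure the analysis
assumes, not any particular germplasm collection:

* **Panel shape**: defaults of 384 accessions and 14,030 biallelic SNPs
  on 20 chromosomes, matching the scale of a mid-density array panel
  after QC; chromosome length is set so overall marker density is
  5.91 SNPs/Mb.
* **Inbreeding**: accessions are fully inbred lines (one haplotype,
  doubled). Observed heterozygosity is injected as an array-artifact
  process, reflecting how a selfing crop's array data actually look.
* **Structure**: ancestral allele frequencies uniform in `maf_range`
  (default 0.05–0.5); subpopulation frequencies by a Balding–Nichols
  draw at differentiation `fst` (default 0.15, two subpopulations —
  strong enough that the leading PCoA axis clearly separates groups, as
  expected for a germplasm panel spanning distinct origins; admixture
  proportions are not modelled, K subpopulations with a single fst are).
* **LD**: a latent-uniform copying process along each chromosome — the
  uniform variate deciding an allele is copied from the previous SNP
  with probability $e^{-d/L}$ ($L$ = `ld_block_bp`, default 150 kb) —
  giving allelic correlation $\approx e^{-d/L}$ and an $r^2$ decay
  below 0.1 around $1.15L$. Copying the latent uniform rather than the
  allele keeps marginal frequencies exact. The allele-frequency field
  itself varies on a slower AR(1) scale ($4L$) so that neighbouring
  markers have similar frequencies; otherwise frequency mismatch, not
  recombination distance, would set the realized decay length. This is
  a deliberate stand-in for coalescent machinery, which is out of
  scope: it is controllable and sufficient for decay-detection tests,
  but it does not produce realistic haplotype block boundaries, allele
  frequency spectra under selection, or recombination hotspots.
* **Contamination**: missingness (mean 5%) and heterozygous-call
  injection (mean 10%) are heterogeneous across markers, each SNP
  drawing its rate from a right-skewed Beta with the stated mean — on
  real arrays a minority of bad probes carries most of the
  contamination, which is what gives the QC filter something real to
  remove. Rates are "20%-scale" in the sense that the bad tail crosses
  the 20% filter thresholds.

`simulate_phenotype()` builds
$y = \text{baseline} + \sum_j \text{effect}_j x_j + u + \varepsilon$
with baseline 1.63 (a typical panel-mean aspect ratio), polygenic
$u \sim N(0, K)$ rescaled so its variance share equals `h2_polygenic`
— solving $v_{poly} = h^2_{poly}(v_{causal} + \sigma^2)/(1 - h^2_{poly})$
— and Gaussian noise. Values below the geometric floor of 1 are truncated
with a logged count. The truth record carries the realized genetic values,
so parameter-recovery tests regress phenotype on truth rather than
trusting the generator's bookkeeping. `simulate_seed_images()` rasterizes
one filled ellipse per seed with axis noise at a given coefficient of
variation, recording the exact axes used.

Passing tests on these panels show the pipeline recovers what it is owed
*under the generator's assumptions* (exchangeable inbred lines, smooth
LD, Gaussian trait); they cannot certify behaviour under admixture
gradients, assay batch effects, or non-Gaussian traits.

## Numerical choices and degenerate inputs

* Genotype containers hold dosages of the **minor** allele (0/1/2,
  re-polarized on read; re-polarization is idempotent, allele flips are
  involutive). Missingness is `NA`, never a sentinel that could leak
  into arithmetic.
* Coordinates are 1-based inclusive bp everywhere (the VCF/GFF3
  convention); distances are position differences in bp.
* Degenerate cases are explicit: all-missing SNPs are flagged with MAF
  recorded as 0; a constant phenotype, an all-monomorphic panel, a pair
  of accessions with no shared calls, and an unset selection threshold
  are errors, not silent results; an empty seed image yields an empty
  table.
* Problem sizes in the test suite are chosen to exercise study-scale
  behaviour (n = 384 panels, up to 5000 markers, B = 100 bootstraps with
  20 permutations) while keeping a full run in the minutes range;
  Monte-Carlo assertions state their replicate counts and were derived
  from the null/power simulations they test.

## Known limitations

* The LD generator's decay is calibrated at the scale level, not
  pair-exact: injected heterozygosity and frequency variation attenuate
  realized $r^2$ somewhat below the pure copying curve.
* The empirical stability-selection threshold at its default `B_perm`
  has visible Monte-Carlo spread; applications that quote the threshold
  itself (rather than the selected set) should increase `B_perm`.
* `full_reml` mode is a per-marker grid-plus-refinement search and is an
  order of magnitude slower than P3D; it exists for verification, not
  routine scans.
* Image analysis assumes one seed per connected component; touching
  seeds are measured as one object.
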