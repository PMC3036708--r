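---
title: "Methods: dissecting weak population substructure with svepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting weak population substructure with svepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`svepop` analyses fine-scale population structure in diploid genome-wide
SNP panels where differentiation is extremely weak — multilocus F_ST on
the order of 10^-4 to 10^-2, as is typical when comparing provinces or
regions within a single country. At that magnitude almost every analysis
choice (estimator bias near zero, permutation conventions, exact versus
asymptotic tails) is material, which is why this vignette spells out the
conventions the package fixes.

The workflow mirrors how such studies are actually run: quality control on
merged multi-platform genotype sets, identity-by-state (IBS) distances
visualised by classical MDS, Weir–Cockerham F_ST with permutation
inference (flat and hierarchical region/province decompositions), per-SNP
allele-frequency chi-square scans summarised by the overdispersion factor
λ, EM-based two-locus D′ decay, isolation by distance via Mantel tests on
great-circle distances, per-sample inbreeding coefficients, grid-circle
local statistics on a map, a maximum-likelihood admixture decomposition
with the Evanno ΔK criterion, and Monmonier barrier detection on
geography-corrected F_ST residuals.

# The synthetic panel generator

Because real intra-national genotype cohorts are access-restricted, the
package ships a generator (`sim_config()` / `simulate_panel()` /
`inject_artifacts()`) whose defaults encode the study conditions the
analyses assume:

* **Differentiation model.** Balding–Nichols: subpopulation allele
  frequencies are Beta(p(1−f)/f, (1−p)(1−f)/f) draws around the ancestral
  frequency p. Its single parameter f equals the expected F_ST, so every
  estimator can be tested closed-loop against the generating value. Drift
  is applied hierarchically: regions around the ancestral frequencies with
  `f_region` (default 4e-4), provinces around their region with
  `f_province` (default 3e-4) — the magnitudes typical of within-country
  structure.
* **Ascertainment.** Ancestral frequencies are uniform on [0.05, 0.5],
  mirroring genotyping panels filtered at MAF 0.05.
* **Cline.** In clinal mode each sample's expected frequency mixes its
  province frequency with a two-endpoint latitudinal gradient; the true
  ancestry proportions are a linear function of latitude (correlation 1 by
  construction), giving ground truth for admixture recovery.
* **Geography.** Samples scatter isotropically around province centroids
  (Gaussian, sd `jitter_km`, converted at 111.195 km/degree latitude and
  cos(lat)-scaled for longitude — adequate at the simulated 55–67° N).
  The default map is three latitudinal regions of two provinces each with
  larger samples in the south, echoing uneven provincial sampling.
* **Artifacts.** Per-platform entry-wise missingness, near-duplicate
  individuals (genotype copies that diverge only through independent
  missingness), "batch" SNPs whose frequency is shifted on one platform,
  and case/control labels assigned independently of genotype (null
  labels).

What the generator does **not** emulate: linkage disequilibrium between
loci (genotypes are independent across SNPs; LD-module tests instead build
haplotype-level LD directly from specified haplotype frequencies),
mutation/recombination genealogy, non-Gaussian settlement geography, and
platform-specific genotype-calling error modes. Passing tests therefore
demonstrate correctness of the statistics under the stated sampling models,
not robustness to every artifact of real array data.

# Conventions fixed by the package

**Quality control.** Filter order is samples by call rate → SNPs by call
rate → exact Hardy–Weinberg per population → MAF on the whole retained
dataset. Thresholds (0.99/0.95/1e-7/0.05) follow the GWAS-era convention;
order matters near thresholds and is fixed so runs are reproducible. The
HWE test uses the exact conditional distribution (total probability of
heterozygote counts no more probable than the observed one) rather than
the asymptotic chi-square, because removal thresholds like 1e-7 are deep
in the tail where the asymptotic approximation fails. Near-duplicate
removal keeps, within each connected component of pairs under the IBS
distance threshold (default 0.05), the sample with the highest call rate,
ties broken by id order. LD pruning defaults to window 50 / step 5 /
r² 0.5 — a widely used convention, exposed in the API.

**IBS and MDS.** IBS distances are pairwise-complete (missing entries are
skipped per pair, not imputed). Classical (Torgerson) MDS is computed via
`stats::cmdscale`; IBS matrices are generally non-Euclidean, so negative
eigenvalues arise and are excluded from both the coordinates and the
variance-explained denominator (variance explained by axis k is its
eigenvalue over the sum of positive eigenvalues).

**Permutation conventions.** All permutation p-values count the observed
statistic once: p = (1 + #{extreme}) / (n_perm + 1), so the smallest
attainable p is 1/(n_perm + 1) — with the conventional 5000 F_ST
permutations, p ≤ 2·10^-4. Differentiation tests (F_ST, Mantel) are
one-sided upper; the IBS Mann–Whitney comparison is two-sided by doubling
the smaller empirical tail. The Mann–Whitney null distribution permutes
*individual* labels and rebuilds both within-group pair sets, because
pairwise distances sharing an individual are dependent; permuting pooled
pair values would be anticonservative. Hierarchical F-statistics use two
schemes: whole provinces permuted among regions for F_CT, individuals
permuted among provinces within their region for F_SC.

**F_ST.** The estimator is Weir–Cockerham θ (ratio of summed variance
components, observed heterozygosity in the within-individual component).
Negative estimates are reported as-is: truncation at zero would bias the
estimator upward exactly in the near-zero regime the package targets.
The hierarchical decomposition is a nested ANOVA on allele-copy
indicators with unequal-size coefficients; it satisfies
(1−F_ST) = (1−F_CT)(1−F_SC) identically.

**λ.** The overdispersion factor is the ratio of means of the smallest
90% of observed 1-df chi-square statistics to the same-rank expected
quantiles qchisq((i−0.5)/m, 1). The (i−0.5)/m plotting positions
approximate expected order statistics with O(1/m) error — negligible at
genome scale. The 90% cut uses floor(0.9·m). Populations are downsampled
to equal size (conventionally 115) before scans so λ is comparable across
pairs.

**LD.** Two-locus haplotype frequencies come from the standard EM over
unphased diploids (only double heterozygotes are phase-ambiguous),
initialized at linkage equilibrium; the two-locus likelihood is unimodal
in practice, and the log-likelihood is asserted non-decreasing on every
run. D′ is D normalized by its frequency-bound maximum, reported in
[0, 1]. Decay profiles use half-open 40-kb windows anchored at 10-kb
multiples starting at zero (the window/step sizes are conventional; the
anchoring is this package's choice). Pair lists drawn around random index
SNPs within 500 kb are de-duplicated when two index SNPs are mutual
neighbours.

**Spatial statistics.** Great-circle distances use the haversine formula
with the IUGG mean Earth radius 6371.0088 km. Grid-circle statistics lay
a ~25-km grid over the sample bounding box and, at each grid point,
aggregate the samples within 150 km: medians (inbreeding, ancestry)
require ≥ 20 members, the local genetic–geographic correlation requires
≥ 40 members (read as 40 samples, i.e. ≥ 780 pairs) and is a plain
Pearson r without a permutation p. Inbreeding uses the observed-versus-
expected homozygote count with the 2n/(2n−1) small-sample correction,
relative to total-sample frequencies.

**Admixture.** Bayesian MCMC clustering is deliberately replaced by the
maximum-likelihood admixture model fitted with block EM: the same
binomial likelihood family, deterministic given a seed, and fast enough
to run replicate scans over K. The likelihood is multimodal for K ≥ 2, so
several random restarts are run (default 3) and the best final
log-likelihood kept; cluster allele frequencies are clipped to
[1e-6, 1−1e-6] each iteration for numerical safety. The Evanno ΔK
statistic consumes replicate log-likelihoods from any source; it needs
≥ 3 consecutive K values and non-zero replicate standard deviation, and
is undefined at the boundary K values.

**Barriers.** Monmonier's maximum-difference algorithm runs on the
Delaunay triangulation (via `deldir`) of province centroids, with each
triangulation edge weighted by the residual of F_ST regressed on
centroid great-circle distance. A barrier starts across the
maximum-weight unused edge and extends from both ends, at each step
crossing the adjacent not-yet-crossed edge of maximal weight, stopping at
the convex hull or at an existing barrier; ties break deterministically
by sorted pair index. Residual (geography-corrected) input is the
default; raw F_ST can be supplied directly since any
`square_distance_matrix` is accepted.

# Numerical and degenerate-input choices

* Loci monomorphic across all populations are skipped in θ and flagged
  (chi2 = 0, p = 1) in scans; they never enter λ.
* Sample pairs with zero overlapping non-missing loci are an error, named.
* The EM haplotype solver errors on loci monomorphic in the
  pairwise-complete subset (D′ undefined there).
* All simulation, permutation and EM entry points take explicit seeds;
  identical seeds give bit-identical results.
* The pipeline derives per-stage seeds as master seed + 1000·stage index,
  so any stage can be re-run in isolation.

# Problem sizes used in the test-suite

The packaged tests exercise the full stack at desk scale, chosen as the
smallest sizes at which the statistical claims are sharp: λ calibration
on 50,000 null SNPs for two 115-diploid samples (tolerance ±0.02); θ
recovery at f ∈ {0.001, 0.005, 0.02} with 2 × 200 samples, 20,000 SNPs
and 10 seeds (±15% relative on the mean); the 5000-permutation F_ST floor
on a 3 × 100-sample panel at f = 0.05; permutation-p uniformity checks
with 200 null replicates of 99 permutations each; admixture recovery with
mean |Q − Q_true| < 0.05 at K = 2, f = 0.1, 2 × 100 samples, 5,000 SNPs;
and exhaustive-enumeration equivalence for the exact HWE test (all tables
to 24–30 alleles), the Mann–Whitney and Mantel permutation tests (n ≤ 6)
and the signed-rank test (2^6 sign patterns).

# Interfaces and limitations

The package's interface is its exported R functions plus the
`run_pipeline()` orchestrator; there is deliberately no shell executable,
since users of this kind of analysis drive it from R scripts, and every
stage writes plain TSV artifacts that external plotting or GIS tools can
consume. Known limitations: no binary PLINK BED support (text PED/MAP
only), no imputation, no haplotype phasing beyond two loci, no coalescent
simulation (the generator draws independent loci), no GO-enrichment of
annotated genes, and the interval-enrichment binomial p ignores local LD
(it is flagged with an explicit caveat in the result).
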