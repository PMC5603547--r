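---
title: "Methods: models, parameters and design choices in lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lncnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

lncnet implements the downstream path of a two-group, two-time RNA-seq
analysis centred on lncRNA–mRNA co-expression: QC summaries, CPM filtering,
median-of-ratios normalization, MDS outlier screening, an exact
negative-binomial test for differential expression, a Pearson co-expression
network over the differentially expressed (DE) transcripts, hypergeometric
pathway enrichment, and a lncRNA–pathway projection. This vignette documents
the statistical models, every tunable parameter that matters, and the design
decisions taken where the methodology was genuinely open.

## The count model and the simulator

`simulate_experiment()` draws counts from

$$y_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\ \phi\right),\qquad
\mu_{gj} = s_j\, \mu_g\, 2^{x_j \beta_g}\, e^{\lambda f_{m(g),j}},$$

with per-sample library factors $s_j \sim U(0.7, 1.3)$ (so normalization is
non-trivial), log-normal baselines $\mu_g$, a treated-at-24 h indicator
$x_j$, planted log2 fold changes $\beta_g$ (zero for non-DE genes), and a
standard-normal latent factor $f_{m,j}$ shared by all genes of module $m$
and scaled by `module_strength` $\lambda$. $\phi$ is the NB dispersion
(variance $\mu + \phi\mu^2$; $\phi = 0$ gives Poisson draws).

The latent-factor construction was chosen because the downstream network is
defined purely by pairwise Pearson correlation: a shared multiplicative
factor yields a tunable pairwise correlation without specifying a full
covariance matrix. On the log scale the within-module population correlation
is approximately $\lambda^2 / (\lambda^2 + \sigma^2_\varepsilon)$ with
$\sigma^2_\varepsilon \approx \ln(1 + \phi + 1/\mu)$, which makes explicit
why a strict $r \ge 0.99$ band requires either strong modules or many
samples.

Defaults, chosen once as representative of a bulk muscle RNA-seq experiment
of this design:

| parameter | default | rationale |
|---|---|---|
| `n_mrna`, `n_lncrna` | 2000, 400 | a filtered expressed transcriptome at package-test scale; the lncRNA minority mirrors real catalogues |
| `n_samples_per_group` | 4 | replicates per treatment-by-time cell in the emulated design |
| `base_mean_log_mu`, `base_mean_log_sigma` | log(100), 1 | counts spanning roughly 10–1000, typical after CPM ≥ 1 filtering |
| `dispersion` | 0.1 | a common bulk-tissue biological CV of ~30% |
| `frac_de`, `de_log2fc_min/max` | 0.1, 1–3 | a minority of genes DE, all beyond the 2-fold call threshold |
| `de_time` | 24 | effects planted at 24 h only, emulating a transient response that has largely resolved by 72 h |
| `n_modules`, sizes | 3 × (10 lnc + 20 mRNA) | small planted modules, disjoint from each other and from DE genes |
| `module_strength` | 3 | gives log-scale within-module correlation ≈ 0.99 at the default noise level, i.e. modules detectable but not trivial at the network threshold |
| `n_pathways`, `pathway_size` | 20, 50 | the enrichment-table scale of a KEGG-style annotation |
| `n_enriched_pathways`, `frac_pathway_de_overlap` | 5, 0.5 | half of each enriched set drawn from planted DE mRNAs |

All draws flow from the single `seed` in a fixed order, so one config
reproduces the experiment bit for bit. What the generator does **not**
emulate: read-level artefacts (GC, length bias, positional effects),
gene-specific dispersions, correlated library quality, batch structure, and
any sequence content beyond transcript lengths and ORF lengths. Passing the
planted-truth tests therefore demonstrates correctness of the algorithms
under the stated model, not performance on any particular real dataset.

## QC summaries

`summarize_mapping()` reports the conventional aggregate statistics of a
read-accounting table. Two conventions matter and are fixed here: all
percentages are rounded half-up at one decimal (matching how such tables are
printed; base R's round-half-even would disagree on boundary cases), and the
mean mapping ratio averages the already-rounded per-sample ratios rather
than pooling $\sum \text{mapped}/\sum \text{clean}$ — the unweighted mean of
the printed column is what summary sentences in the field usually quote, and
the two differ when library sizes vary.

`assembly_stats()` computes N50 on the supplied length set itself (no
reference-genome NG50 variant) by the descending cumulative sum crossing
half the total; the median uses the midpoint convention for even counts.

## Filtering, normalization, outliers

- `filter_expressed()` keeps genes with CPM ≥ `min_cpm` (default 1) in at
  least `min_samples` samples. The pipeline defaults `min_samples` to the
  smallest group-by-time cell size, the weakest requirement that still
  demands consistent expression within one experimental cell. CPM uses the
  library sizes of the input matrix, so the judgment scale is fixed before
  any subsetting.
- `median_of_ratios()` re-implements the standard size-factor estimator:
  reference genes are those positive in every sample; $s_j$ is the median
  ratio to the per-gene geometric mean. The factors are identified only up
  to a common rescaling (the geometric means themselves move when a column
  is rescaled), so the tests assert the ratio form of scale equivariance.
  A single-sample matrix yields $s = 1$ by construction.
- `mds_outliers()` embeds samples by classical MDS of $1 - r$ between
  log₂(CPM + 1) profiles and flags samples whose distance to their own group
  centroid exceeds median + `k`·MAD (default `k = 3`) of all within-group
  centroid distances, capped at `n_flag_max` (default 2). Published analyses
  of this kind typically report MDS outliers without stating a criterion;
  this rule is the package's documented stand-in — conservative, capped, and
  with singleton groups exempt (they define no spread). The pseudocount and
  `k` are configurable.

## Differential expression

The two-group test conditions on the per-gene total. Samples are first
equalized by dividing each column by its median-of-ratios size factor
(normalized to geometric mean 1) and rounding to pseudo-counts. Raw
library-sum ratios are deliberately **not** used for this step: a few genes
with strong shared variation (exactly what the planted modules create) can
dominate column totals, and total-count equalization then inflates every
gene's apparent within-group variance; the robust factors do not have this
failure mode.

Under the null the group sums $Y_A, Y_B$ of pseudo-counts are treated as
negative binomial with means proportional to group size and dispersion
$\phi / n_\text{group}$. Conditional on $t = y_A + y_B$, the two-sided
p-value sums the probabilities of all partitions of $t$ no more likely than
the observed one, normalized by the total. Numerical choices:

- $\phi = 0$ uses the exact binomial partition law (the Poisson limit).
- Probabilities are computed in log space and renormalized; the observed
  partition is compared with a $1 + 10^{-10}$ slack so ties are included.
- For $t > 10^4$ the partition range is restricted to the conditional mean
  ± 50 SD (always including the observed value); the neglected mass is
  below machine precision at that width.
- $t = 0$ is defined as $p = 1$, log2FC = 0.

The common dispersion is a 20%-trimmed mean of per-gene moment estimates
$\max\{0, (v - \bar m)/\bar m^2\}$ on equalized counts, with means and
variances averaged over groups. It is deterministic and deliberately simple;
tagwise/trended empirical-Bayes shrinkage is out of scope. The trade-off is
visible in pipeline runs: genes whose true variance far exceeds the common
value (the planted module genes) can be called DE spuriously — the classic
argument for tagwise dispersions, accepted here as a documented limitation.

Fold changes are reported as
$\log_2\!\big((y_B/n_B + c) / (y_A/n_A + c)\big)$ with `prior_count`
$c = 0.125$ damping low-count ratios; calls use the same value that is
reported. DEG calls require both $q < \alpha$ (BH, default 0.05) and
$|\text{log2FC}| > \log_2(\text{fc\_min})$ (default fold change 2). Each
time point is analyzed as an independent two-group contrast.

## lncRNA classification

`classify_transcripts()` uses the standard heuristic: length ≥ 200 nt,
longest ORF < 100 aa, and no protein-database hit (when a hit table is
supplied) ⇒ lncRNA; a long ORF or a hit ⇒ mRNA; anything else (short, low
coding potential) is reported as `ambiguous` rather than forced into a
class. The 100 aa cutoff is the widespread lncRNA convention; both
thresholds are exposed because identification pipelines differ.
`longest_orf()` scans all six frames for ATG…stop spans and requires an
in-frame stop; `N` never matches a start or stop codon. Machine-learning
coding-potential scores are out of scope — an external hit column stands in
for homology evidence.

## Co-expression network

For every candidate lncRNA–mRNA pair, Pearson's $r$ is computed on
log₂(normalized value + 1). The log transform is a documented choice: on
the raw scale the correlation of multiplicatively noisy counts is bounded
away from 1 (a pair with 10% multiplicative noise cannot reach $r = 0.99$
regardless of how strong the shared signal is), so a strict threshold would
measure mean magnitude rather than co-regulation; `log2 = FALSE` restores
the raw scale. P-values come from the $t = r\sqrt{n-2}/\sqrt{1-r^2}$
transform ($r = \pm 1$ maps to $p = 0$ by convention; zero-variance profiles
are excluded and counted); the test form behind a correlation FDR is rarely
stated in applied work, and the $t$ test is the package's documented choice.
BH adjustment is applied **jointly over all tested pairs** (one family), not
per-lncRNA. Edges require $r \ge$ `r_threshold` (default 0.99; positive-only
by default since co-expression is usually meant as positive correlation,
with `signed = "absolute"` as the alternative) and $q <$ `q_threshold`
(default 0.05).

Hubs are the top-`k` nodes by degree (default `k = 20`), ties broken
lexicographically by id so the selection is deterministic; a
`top_fraction` rule (ceiling of fraction × nodes) is provided as the
principled alternative. The pipeline correlates over the retained samples
of the analyzed time point by default (`pool_samples = TRUE` uses all
retained samples and is what the planted-module recovery experiment uses,
since modules persist across both time points and the doubled sample count
sharpens the correlation estimate).

## Enrichment and projection

`hypergeom_enrich()` computes the upper-tail hypergeometric probability
inclusive of the observed overlap, BH-adjusts across pathways, and reports
the rich factor $kN/(Kn)$ — the observed over expected gene count. The
universe defaults, in the pipeline, to the CPM-filtered expressed mRNAs
(configurable): enrichment should be judged against what could have been
detected, not the whole annotation. Out-of-universe query genes are dropped
with a count; empty-in-universe pathways are skipped with a note.

The projection links a lncRNA to a pathway when at least `min_support`
(default 1) of its co-expressed mRNA partners belong to the pathway's gene
set, restricted by default to pathways with $q <$ `enrich_alpha`. One
supporting mRNA is the weakest reading of "associates with a common
pathway"; raising `min_support` covers the stricter reading. Each edge
records its supporting mRNAs so the projection is fully auditable, and a
per-pathway summary counts regulatory lncRNAs in descending order.

## Problem sizes and reproducibility

The test suite and the acceptance script validate each stage with:
brute-force oracle comparisons (hypergeometric enumeration at universe size
12, binomial partition enumeration at totals ≤ 200, BH step-up at m ≤ 100,
N50 candidate scans at ≤ 50 contigs, Pearson's definition); a seeded null
simulation of 2000 genes at 4 + 4 samples and $\phi = 0.2$ for the type-I
error and dispersion recovery; a planted-DE simulation of 2000 genes with
$|\text{log2FC}| = 2$ for sensitivity; the generator defaults (2400 genes,
16 samples) for module precision and enrichment power; and a 10,000-pair
null screen at 8 samples for the network threshold. These sizes were chosen
as the smallest at which the asymptotic behaviour of each statistic is
visible; all are driven by fixed seeds, and rerunning the pipeline with the
same configuration rewrites every output byte-identically (no timestamps
are embedded).

## Known limitations

- A single common dispersion: genes with much larger true dispersion can be
  miscalled (see above); per-gene shrinkage is out of scope.
- The exact-test equalization rounds to pseudo-counts rather than using a
  quantile adjustment, a known approximation; the package's guarantees are
  stated as type-I/power properties, not value-for-value equality with any
  other implementation.
- The MDS outlier rule and the correlation p-value form are documented
  conventions for steps whose criteria applied studies usually leave
  unstated.
- The simulator's planted truth validates algorithms, not biology: real
  data add batch effects, gene-specific dispersions and annotation noise
  that the model omits.
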