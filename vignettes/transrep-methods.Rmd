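---
title: "Methods: trans-ethnic GWAS replicability with transrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-ethnic GWAS replicability with transrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transrep)
```

## The scientific question

When a genome-wide association study (GWAS) in one ancestry reports a
disease-associated SNP, does the association hold in another ancestry?
The answer bears on whether GWAS signals are driven by common causal
variants shared across populations (which would replicate, with similar
effect sizes) or by population-specific rare variants tagged through local
linkage disequilibrium (LD), which would not. `transrep` implements the
statistical machinery for this analysis on curated tables of discovery
records and replication attempts: curation filters, replication power,
power-adjusted ("effective") replicability, publication-bias bounds,
cross-ancestry effect-size concordance, and a varLD-style comparison of
local LD patterns between two reference panels.

Because curated replication databases and phased reference panels are
external resources, the package also ships first-class synthetic
generators for both, with known ground truth. All empirical statements in
this vignette are properties the test suite computes.

## Data model and curation

Three tab-separated tables describe a replication database: `studies`
(one GWAS per row, with ancestry, stage sample sizes and whether imputed
SNPs were used), `associations` (one discovered SNP per row, with the
discovery odds ratio referenced to the risk allele, its p-value and MAF)
and `attempts` (one replication attempt per row). `load_tables()`
enforces schema, a strict numeric dialect (a comma decimal such as
`"1,23"` is an error, never a silent `NA`) and referential integrity.

`apply_discovery_filters()` applies the discovery-side inclusion rules:

* sex-specific-only associations are dropped;
* the genome-wide significance threshold is `5e-7`, tightened to `5e-8`
  when the discovery study used imputed SNPs (strict `<` in both cases);
* the MHC region is excluded — the window is configurable and defaults to
  chr6:25,000,000–35,000,000 (inclusive), since the region is
  conventionally named without exact coordinates;
* within each disease and chromosome, SNPs closer than 200 kb are chained
  transitively (single linkage — "less than 200 kb from each other" is a
  pairwise relation) into one region, and only the SNP with the lowest
  p-value per region is kept, ties going to the smaller coordinate. The
  boundary is strict: two SNPs exactly 200,001 bp apart form two regions.

Filtering is idempotent, and every dropped row is logged with exactly one
reason. Odds ratios are compared on the log scale throughout, because the
OR scale is asymmetric (an OR of 2 for one allele is an OR of 0.5 for the
other); `reference_risk_allele()` performs that orientation and records a
`shift` flag when the reporting allele differs from the discovery risk
allele.

## Replication power

A replication attempt is *successful* when the same risk allele as in the
discovery study reaches `p < alpha` (default 0.05). The probability of
this under a log-additive model is computed by `replication_power()` as a
one-stage two-proportion z-test on allele counts: with risk-allele
frequency $p_0$ in the replication population and per-allele odds ratio
$\psi$, the case frequency is $p_1 = \psi p_0 / (1 + p_0(\psi-1))$, the
standard error is
$SE = \sqrt{p_1(1-p_1)/2n_{\mathrm{cases}} + p_0(1-p_0)/2n_{\mathrm{controls}}}$,
and same-direction power at two-sided level $\alpha$ is
$\Phi(|ncp| - z_{1-\alpha/2})$ with $ncp = (p_1-p_0)/SE$.

Design choices made here, deliberately:

* **Prevalence is ignored** (control frequency = population frequency),
  the standard low-prevalence approximation for a CaTS-style calculation
  without a prevalence input.
* **Power counts same-direction significance only**, because the success
  criterion requires the same risk allele; at $\psi = 1$ power is exactly
  $\alpha/2$. A `direction = "any"` flag adds the opposite tail for
  sensitivity analyses.
* **One-stage only**: replication attempts are evaluated on their GWAS
  stage, so no two-stage design power is modelled.

The analytic formula is validated in the test suite against a
200,000-replicate Monte-Carlo oracle (simulated allele-count tables,
pooled-variance z-test) on a 27-point grid $\psi \in \{1.1,1.3,1.5\}$,
$p_0 \in \{0.1,0.3,0.5\}$, $n \in \{500,2000,10000\}$, with agreement
within $\pm 0.01$ everywhere.

## Replicability statistics

`replicability_summary()` combines the observed rate, the null
expectation and the exact upper-tail binomial test against the null that
every success is a type I error. Two null conventions exist, and both are
exposed: `"alpha"` ($n\alpha$ expected; any significant result counts)
and `"alpha_half"` ($n\alpha/2$; significance *and* the same risk allele,
which the success criterion actually requires). The default is
`"alpha"`, the more conservative headline convention; the discrepancy is
deliberate and documented rather than hidden.

*Effective replicability* is the observed number of successes divided by
the power-expected number $\sum_i \mathrm{power}_i$
(`expected_replications()`). It is the replication rate after correcting
for the fact that many replication cohorts are underpowered; values above
1 can occur by sampling noise and are flagged, not truncated.

`publication_bias_bounds()` implements two bounding arguments against
selective reporting. First, if all $k$ observed positives were false
positives, they would be the fraction $\alpha \cdot p_{\mathrm{dir}}$
(significance times the null probability of drawing the same risk allele,
$0.5$) of an implied pool $k/(\alpha p_{\mathrm{dir}})$ of attempts; a
Garwood (chi-square quantile) exact Poisson interval on $k$, scaled by
the same factor, gives its confidence interval. Note that no standard
Poisson interval parametrization exactly reproduces every historically
printed interval for this construction; the method is configurable
(`"exact"` or `"normal"`) and we report our own exact interval. Second,
treating every plausibly-unreported attempt as a failed replication gives
the lower-bound rate $k/(n_{\mathrm{gathered}} + n_{\mathrm{unreported}})$.

Heterogeneity of replicability across diseases is tested with a
chi-square homogeneity test on the disease-by-outcome table, switching to
a Monte-Carlo p-value (10,000 resamples) when any expected cell is
below 5.

## Effect-size concordance

`concordance_stats()` quantifies cross-ancestry agreement of effect sizes
with the Spearman rank correlation (average-rank ties method) and an OLS
regression of the replication log(OR) on the discovery log(OR) (intercept
fitted, slope reported — a slope of 1 means the discovery effect is an
unbiased predictor). Spearman p-values use the exact null distribution of
the rank statistic for $n \le 10$ without ties and the t-approximation
otherwise.

`windowed_replicability_profile()` classifies attempts into sliding
windows along the discovery OR (folded to $\max(\psi, 1/\psi)$ so
protective alleles read as risk ORs above 1) or along the MAF, and
reports per window the mean power, observed rate and effective rate.
Published figure captions of this kind are ambiguous between a window
width and a step; we implement both explicitly, defaulting to width 0.3
and step 0.05, and suppress windows with fewer than 20 attempts. Windows
overlap, so neighbouring profile points are correlated; the profile is a
description, not a set of independent estimates.

`stratified_comparison()` splits attempts at a discovery sample size of
10,000 individuals ("small" vs "large" studies) and compares MAF and OR
distributions between the strata with two-sided Mann-Whitney tests, plus
per-stratum concordance.

## LD divergence: the varLD raw score

For a window of 50 consecutive SNPs, `signed_r2_matrix()` computes
pairwise signed $r^2$ (Pearson correlation of phased haplotype allele
indicators, squared, carrying the sign of $r$) within each population.
`varld_raw_score()` eigen-decomposes both matrices, ranks the eigenvalues
in descending order and sums the absolute differences of the ranked
eigenvalues. The score is a pseudometric on LD patterns: non-negative,
symmetric, zero iff the spectra coincide, and invariant to a simultaneous
reordering of the SNPs in both windows. Each correlation matrix has trace
equal to the window size, which the tests assert as a spectral sanity
check.

Numerical and degenerate-input choices:

* correlations are computed on phased haplotypes; SNPs monomorphic in a
  window get zero off-diagonal entries (diagonal stays 1) and are counted
  in the output — the published tool's handling of this case is not
  specified, and zeroing preserves symmetry;
* eigenvalues are paired by descending rank, not by eigenvector matching;
* no genome-wide standardisation of scores is applied: downstream
  inference uses raw scores and permutation p-values only.

`sliding_window_scan()` scans 50-SNP windows in 5-SNP steps from 300
SNPs upstream to 300 SNPs downstream of a focal SNP — 121 windows, which
requires 650 consecutive SNPs (the ±300-SNP span plus the 25-SNP window
overhang on each side). A region with only 600 SNPs cannot host the full
scan; the scan then truncates with a warning and records the offsets it
did evaluate. Alongside varLD the scan reports the difference in average
expected heterozygosity $2p(1-p)$ (population 1 minus population 2) per
window; swapping the populations flips the sign of the heterozygosity
difference but leaves the varLD score unchanged.

`permutation_pvalue()` tests the null that LD correlations in a window
are equal in the two populations by relabelling diploid individuals
(both haplotypes move together) across populations, preserving sample
sizes, with the add-one empirical estimate
$(1 + \#\{s_{\mathrm{perm}} \ge s_{\mathrm{obs}}\})/(n_{\mathrm{perm}}+1)$,
so p-values are never zero and are valid under exchangeability.
`maf_matched_background()` builds the genome-wide expectation: groups of
random SNPs MAF-matched (±0.02, widening to ±0.05 with a warning) to a
focal set, each scored by the central-window permutation p-value, with
the across-group median and 2.5%/97.5% ECDF envelope.
`group_window_comparison()` compares two groups of scanned regions
offset-by-offset with two-sided Mann-Whitney tests, flagging offsets
below a significance threshold (default 0.01).

## Synthetic data: what it emulates, and what it does not

### Replication databases

`gen_replication_database()` draws, per association, a true per-allele
log OR $|\mathcal{N}(\mu, \sigma)|$ (risk-allele referenced, so
$\psi \ge 1$), a discovery MAF, and a latent `shared` flag with
probability `pi_share` that the causal effect exists in the replication
population. Each attempt's z-statistic is $\mathcal{N}(ncp, 1)$ when
shared — with *the same* non-centrality as `replication_power()`, so
analytic and simulated power agree by construction — and
$\mathcal{N}(0,1)$ when not, i.e. a true OR of exactly 1 in the
replication population. Consequences that the tests verify: non-shared
attempts have Uniform(0,1) p-values and a same-direction success rate of
exactly $\alpha/2$; mixtures follow
$\pi \cdot \overline{\mathrm{power}} + (1-\pi)\alpha/2$; and effective
replicability regressed on the true `pi_share` over
$\{0, 0.25, 0.5, 0.75, 1\}$ has slope 1 within ±0.1.

Defaults are set to the operating point of a realistic curated
trans-ethnic database: tens of diseases, a few hundred attempts,
discovery ORs centred at 1.2, replication cohorts of 300–2,000 cases and
controls (giving a mean replication power near 0.6) and a sharing
fraction of 0.8, so the simulated effective replicability sits near 80%.
The distribution of true ORs across loci is not identifiable from
published tables; the folded-normal choice on the log scale is a stand-in
and is exposed in the configuration. Winner's curse is *not* simulated by
default (curation that takes discovery ORs from internal replication
stages largely avoids it); a `winners_curse` flag re-draws discovery
estimates from the significance-truncated sampling distribution for
robustness experiments. Discovery records are generated to pass the
curation filters by construction, which the tests assert.

What the generator does not emulate: correlated attempts within
consortia, heterogeneous true effects across ancestries (the shared
effect is identical by construction), covariate adjustment, and
case-control imbalance effects beyond the sample sizes themselves. A
passing recovery test therefore shows the *statistics* behave as derived
under the stated model, not that real databases satisfy that model.

### Haplotype panels

`gen_two_pop_haplotypes()` builds a founding pool of haplotypes as
mosaics of `n_founders` founder haplotypes (founder alleles Bernoulli
with per-SNP probabilities uniform above `maf_floor`; the mosaic template
switches between adjacent SNPs with probability `recomb_prob`, which sets
the baseline LD decay — with 2 founders and no switching, every
polymorphic pair is in complete LD, a worked special case in the tests).
Two populations then drift independently for `drift_generations`
Wright-Fisher generations at `2 * pop_size` haplotypes and are sampled
into panels of diploid individuals (defaults 60 and 90, the scale of the
classic European and combined East Asian reference panels, with total
divergence defaulting to $F_{ST} \approx 0.07$).

Drift includes recombination at `region_morgans` per transmitted
haplotype (at most one crossover per meiosis; default 0.005, i.e. 0.5 cM,
the genetic length scale of a half-megabase region). Single-locus drift
dynamics are unchanged by this — the tests verify the Wright-Fisher
expectation $F_{ST} \approx 1 - (1 - 1/2N)^g$ via the Hudson estimator —
but without recombination a long drift would let whole regions coalesce
to a single haplotype, a degenerate state real ascertained panels never
show. Even with recombination, very long drift
($g/2N \gtrsim 1$) erodes the LD contrast in a minority of regions
(recombination-drift equilibrium), so the detection rate of the
permutation test saturates below 100% there; the tests assert ≥90% of
strongly drifted regions at $p \le 0.05$ and ≥75% pinned at the minimal
empirical p.

With `drift_generations = 0` the two panels are exchangeable draws from
one pool, and permutation p-values are uniform — the calibration property
the acceptance tests check across 200 regions. A `local_drift` option
applies extra drift to a SNP segment of one population only, emulating a
region whose divergence is confined to the focal window; scans of such
regions show significant offsets only where windows overlap the drifted
segment, reproducing the qualitative signature of LD-divergence-driven
replication failure concentrating at the associated SNP.

There is no mutation model and no demography beyond drift: the generator
reproduces the *statistical structure* the scan assumes (decaying LD,
tunable allele-frequency and LD divergence), not coalescent realism.

## Problem sizes and determinism

The test suite uses scaled-down but statistically meaningful problem
sizes, chosen as the package's own defaults for routine verification: 200
exchangeable regions for the uniformity calibration, 27 grid points ×
200,000 replicates for the power oracle, five sharing fractions × ~2,350
attempts for parameter recovery, 100 random 50×50 matrix pairs for the
eigen oracle (agreement to $10^{-8}$ against an independent
shift-and-SVD eigenvalue route), and 12 + 12 regions for the targeted
drift comparison. Every stochastic component takes an explicit seed; the
pipeline derives per-stage seeds deterministically from one top-level
seed, records it in the run manifest, and identical configurations
produce byte-identical output tables.

## Known limitations

* The curation filters operate on coordinates only; associations excluded
  in the source literature as "HLA alleles" rather than by position
  cannot be reproduced beyond the MHC coordinate window.
* The power model is allelic and one-stage; genotype-level logistic
  regression power, covariates and multi-stage designs are out of scope.
* The publication-bias operations implement bounding arithmetic, not a
  formal selection model.
* The varLD implementation reports raw scores and permutation p-values;
  the published tool's genome-standardised units are intentionally not
  computed, so raw scores are comparable only within an analysis.
* Attempt-level non-independence (several attempts per SNP) is handled by
  deterministic subset selection (`select_attempts()`), not by
  hierarchical modelling.
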