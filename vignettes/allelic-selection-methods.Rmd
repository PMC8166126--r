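---
title: "Detecting somatic allele-specific selection: model and methods"
author: "aiselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic allele-specific selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiselect)
```

## The problem

Somatic copy-number events in tumors are rarely allele-neutral: an
amplification or deletion affects one parental homolog at a time, producing
allelic imbalance (AI) at every heterozygous SNP on the affected chromosome
arm. If a germline allele confers a growth advantage to tumor cells, the
homolog carrying it should be *promoted* (kept at higher copy number) more
often than chance across independent patients. aiselect quantifies this
cohort-level preference per SNP from paired tumor/normal whole-exome allelic
read depths, without requiring computational phasing or absolute copy-number
calls.

By convention the A allele is the reference allele and B the alternate.
A cohort-level preference for promotion of B (its estimate statistically
above 0.5) is read as positive somatic selection of the B allele
("selected-for"); below 0.5 as negative selection ("selected-against").

## The model

For SNP $i$ and patient $j$ with a heterozygous normal genotype, the
observed reference-allele depths in tumor and normal, conditioned on their
totals, are beta-binomial:

$$y_{Aij} \mid (y_{Aij}+y_{Bij}) \sim \mathrm{BB}\!\left(y_{Aij};\,
  y_{Aij}+y_{Bij},\, 1-p_i,\, \theta_i\right), \qquad
  y'_{Aij} \mid (\cdot) \sim \mathrm{BB}\!\left(\cdot,\, 1-p'_i,\,
  \theta_i\right),$$

in the mean–precision parameterization ($\alpha = p\theta$,
$\beta = (1-p)\theta$). The expected B-allele shares propagate the
allele-fraction vector through two nuisance distortions,

$$ (a, b) = (1-\pi_i,\ \pi_i)
   \begin{pmatrix} 1-\delta_i & \delta_i \\ \delta_i & 1-\delta_i \end{pmatrix}
   \begin{pmatrix} 2(1-\varphi_i) & 0 \\ 0 & 2\varphi_i \end{pmatrix},
   \qquad p_i = \frac{b}{a+b}, $$

with the normal-tissue share $p'_i$ obtained from $(0.5, 0.5)$ in place of
$(1-\pi_i, \pi_i)$. Here $\pi_i \in (0,1)$ is the tumor preference for the
B allele ($\pi_i = 0.5$ in balanced tissue), $\delta_i$ the base-calling
error, $\varphi_i$ the reference-mapping bias ($0.5$ = none) and $\theta_i$
the beta-binomial precision. The per-sample depth scale multiplies both
components of the vector and cancels in the ratio, so coverage
normalization factors (stored per sample as global-median over
sample-median depth) do not affect the estimate; they are retained for
reporting only. Because both tissues share $\delta_i$ and $\varphi_i$ and
only the tumor carries $\pi_i$, the matched normal identifies the technical
bias and the tumor/normal contrast identifies selection — a design we
verify in a test where a simulated mapping bias of 0.6 is absorbed by
$\hat\varphi$ while $\hat\pi$ stays at 0.5.

One deliberate reading: written with $\delta$ on the diagonal, the error
matrix would *invert* alleles as $\delta \to 0$; we place $1-\delta$ on the
diagonal so that zero base-calling error is the identity, which is the only
form consistent with the small-error limit.

### Priors and MAP fitting

The posterior factorizes over independent priors,
$P(\pi,\delta,\varphi,\theta \mid \mathrm{data}) \propto
\mathcal{L} \, P(\pi) P(\delta) P(\varphi) P(\theta)$. The reference prior
table for this family of models is not publicly specified, so the defaults
are documented stand-ins, all configurable through `ai_priors()`:

| parameter  | prior               | interval          | rationale |
|------------|---------------------|-------------------|-----------|
| $\pi$      | uniform             | $[0.01, 0.99]$    | agnostic about selection |
| $\delta$   | Beta(1, 50)         | $[10^{-6}, 0.1]$  | base-calling error is small |
| $\varphi$  | Beta(20, 20)        | $[0.2, 0.8]$      | mapping bias centered on none |
| $\theta$   | log-uniform         | $[1, 10^4]$       | scale-free precision |

Densities are used unnormalized on their truncation intervals; only the
mode's location matters for MAP estimation. The fit maximizes the log
posterior by bounded quasi-Newton (L-BFGS-B) in transformed coordinates —
scaled logit for $\pi$, $\delta$, $\varphi$ and logit of $\log\theta$ — with
an analytic gradient, from a deterministic multi-start at
$\pi \in \{0.3, 0.5, 0.7\}$ ($\delta = 0.005$, $\varphi = 0.5$,
$\theta = 100$). Ties in the objective break toward the $\pi$ closest to
0.5, the conservative choice. Convergence is declared when the relative
objective reduction falls below $10^{-8}$. A test asserts the MAP never
falls below any point of a dense grid over the posterior, and that the
compiled objective equals the plain-R reference implementation to
$10^{-10}$.

### Significance: the arm-swap permutation null

Phase is preserved within an AI event — one whole parental homolog gains or
loses copies — so the null hypothesis "promotion is indifferent to the
allele" can be simulated exactly by relabeling: for each (sample, arm)
independently, with probability 0.5 every A count on the arm becomes B and
vice versa, in tumor and matched normal alike. Totals, heterozygote calls
and linkage structure are untouched; only the association between allele
and promotion status is destroyed. Each permutation refits every SNP and
the statistic $|0.5 - \hat\pi|$ is pooled across permutations and SNPs (the
reference analysis pools 1000 permutations; the permutation count is a
parameter). Per-SNP empirical p-values use the add-one rule
$p = (1+r)/(1+N)$, which guarantees $p > 0$ and validity as a permutation
p-value; at the pool sizes involved the difference from $r/N$ is
negligible. Permutation refits are warm-started at the observed fit plus a
central start at $\pi = 0.5$; a test confirms they agree with cold
multi-start fits.

False-discovery control uses Storey q-values: $\hat\pi_0$ is estimated on
the $\lambda$ grid $0.05, \dots, 0.95$ with a cubic smoothing spline
evaluated at the largest $\lambda$, falling back to $\pi_0 = 1$
(Benjamini–Hochberg-equivalent) below 10 p-values.

### Downstream statistics

Deleteriousness uses a CADD-style score with the strict cutoff
score $> 10$; enrichment of deleterious alleles in each stratum
(direction $\times$ significance level) is an upper-tail hypergeometric
test against the background of all analyzed SNPs, with the complementary
depletion tail reported alongside. Case/control allele-frequency shifts
use Fisher's exact test per SNP on the 2$\times$2 allele-count table — the
exact test is the conservative choice at the small counts typical of rare
alleles — with case frequencies computed from *normal-sample* genotypes
(germline dosage, not tumor counts) and Storey q-values thresholded at
$q < 0.05$. Gene-dependency skew is a two-sample Kolmogorov–Smirnov test,
with a one-sided option for "selected genes skew more essential". Sampling
distributions of stratum fractions come from a percentile bootstrap over
alleles, and pairwise stratum differences are assessed on the bootstrap
replicates with Tukey's honest-significant-difference procedure; the
resampling scheme behind the reference violin plots is unstated, so the
bootstrap-over-alleles is this package's documented choice.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

* **Genotypes.** Each (SNP, sample) is heterozygous with probability
  `het_prob`, otherwise homozygous for either allele; phase (which homolog
  carries B) is independent per SNP with probability 0.5 — no linkage
  disequilibrium.
* **Depths.** Per-site totals are negative binomial with mean
  `coverage_mean` and dispersion 0.3 by default (Poisson available); the
  depth law is not specified by the reference analysis, and 0.3 is a
  typical whole-exome overdispersion.
* **Events.** Each (sample, arm) acquires an AI event with probability
  `event_rate`. The promoted homolog is drawn with probability proportional
  to $\prod_i \pi_i$ or $1-\pi_i$ over the sample's heterozygous SNPs on
  the arm, so a SNP that is its arm's only non-null locus has its
  B-homolog promoted with probability exactly `pi_true`; when several
  planted SNPs share an arm the marginal rates attenuate toward 0.5
  (recovery studies therefore plant at most one non-null SNP per arm).
  Within one (sample, arm) every SNP shares the promoted homolog.
* **Fractions and counts.** At an event site the tumor-cell B fraction is
  `promoted_fraction` (or its complement); contamination mixes it linearly
  toward 0.5 with weight `1 - purity`; base-calling error and mapping bias
  distort tumor and normal identically; counts are beta-binomial with
  precision `theta_true`. Homozygous sites keep their degenerate fractions,
  so heterozygote calling on the normal counts behaves as on real data.

`simulate_annotations()` adds CADD-like scores, control-population allele
frequencies and per-gene dependency scores, optionally associated with the
planted selection signal (`assoc_strength`) so the enrichment stages have
recoverable ground truth.

### What the generator does not emulate

Reads and alignments (no mapping artifacts beyond the $\varphi$ summary),
linkage disequilibrium, subclonal structure, absolute copy numbers (events
act only through allele-fraction shifts, consistent with the model
conditioning on totals), and per-sample heterogeneity in AI magnitude —
`promoted_fraction` is a single knob and the model averages over samples.
Passing tests on synthetic cohorts therefore demonstrate the estimator,
the permutation machinery and the enrichment statistics, not robustness to
alignment artifacts or population structure in real tumor data.

### Calibration design: two promotion modes

The default `promotion = "stochastic"` mode draws one promoted homolog per
(sample, arm), so per-sample tumor fractions at a selected SNP are
*bimodal* (e.g. 0.7 with probability $\pi$, 0.3 otherwise). The fitted
beta-binomial absorbs that mixture in $\theta$, and its estimated mean sits
near the mixture mean but is pulled toward the majority mode — with
complete clonal events and $\pi_\mathrm{true} = 0.8$ we measure
$\hat\pi \approx 0.93$. The estimated $\hat\pi$ is therefore a monotone
*surrogate* for the promotion preference, not an unbiased estimate of it;
significance calls are unaffected because the permutation null is built
from the same statistic.

Estimator-recovery studies need data drawn from the model's own
observation law. `promotion = "expected"` provides it: every event site
receives the cohort-expected fraction
$\pi \cdot f + (1-\pi)(1-f)$, which with `event_rate = 1`,
`promoted_fraction = 1` and `purity = 1` equals $\pi_\mathrm{true}$
exactly. The parameter-recovery and null-recovery studies below use this
mode; the power, calibration and end-to-end studies use the realistic
stochastic mode.

## Numerical choices

* Optimization runs unconstrained in logit-transformed coordinates clamped
  to $[-12, 12]$ (within $6\times10^{-6}$ of the parameter range ends), so
  the optimizer cannot strand itself on a saturated sigmoid.
* `betabinom_logpmf()` is evaluated via `lchoose` and `lbeta`; the binomial
  constant is precomputed per SNP inside the fit loop.
* Degenerate simulated fractions (0 or 1 at homozygous sites) bypass the
  beta draw; an expected allele fraction of exactly 0 or 1 inside the model
  is an error.
* Empirical p-values use a $10^{-12}$ tie tolerance so null values equal to
  the observed statistic count toward the upper tail.
* Fits with fewer than `min_het` informative samples are skipped and
  excluded downstream (reported as non-converged); the reference analysis'
  unavailable quality-filter stage is stood in for by the
  minimum-heterozygote-count filter (default 10), on the rationale that
  variants with few heterozygotes carry little evidence either way.

## Problem sizes used in the shipped studies

The calibration studies run at desk scale, chosen as the smallest sizes at
which the checked bands are meaningfully tight: type-I error on 500 null
SNPs $\times$ 100 samples with a 200-permutation pooled null; null
recovery on 50 SNPs $\times$ 200 samples; parameter recovery at
$\pi \in \{0.3, 0.5, 0.7\}$ with 50 loci; power against contamination at
purities 1.0/0.7/0.4; end-to-end planted recovery on 300 SNPs (10%
planted at $\pi = 0.8$, one per arm) $\times$ 200 samples with 100
permutations. `scripts/acceptance.R` re-runs the first two and the
swap-rate check from a fresh seed.

## Known limitations

* $\delta$ and $\varphi$ are weakly separated (both shrink or shift the
  fractions); the informative normal tissue and the tight $\delta$ prior
  resolve this in practice, but $\hat\delta$ itself should not be
  over-interpreted.
* The pooled null assumes exchangeability of $|0.5-\hat\pi|$ across SNPs;
  SNPs with very different heterozygote counts have different sampling
  variances, which the pooled procedure averages over (per-SNP nulls would
  remove this at much higher cost).
* $\hat\pi$ from stochastic clonal AI is a surrogate for the promotion
  preference (see above).
* With several non-null SNPs on one arm the generator's marginal promotion
  rates attenuate; the analysis itself is unaffected.
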