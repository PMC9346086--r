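---
title: "Modeling the unguarded X: sex-linked mutation load and sex differences in survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the unguarded X}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unguardedX)
```

## The question and the model

Across many animals the heterogametic sex (XY males, ZW females) is the
shorter-lived one. The "unguarded X" hypothesis attributes this to
hemizygosity: partially recessive deleterious mutations on the X are
sheltered in heterozygous females but fully expressed in males, so at
mutation–selection balance males should carry a larger realized load on
survival. This package implements a deterministic population-genetic
model that turns that verbal argument into numbers, so the hypothesis
can be evaluated quantitatively rather than rhetorically.

The model is built from standard ingredients. Each X-linked locus $i$ is
biallelic, with mutation to the deleterious allele at rates
$\mu_{f,i}$ (eggs) and $\mu_{m,i}$ (sperm), selection coefficients
$s_{f,i}$ (homozygous females) and $s_{m,i}$ (hemizygous males),
dominance $h_i$, and component effects $\alpha_{f,i}, \alpha_{m,i}$ —
the fraction of each sex's total fitness effect that acts through the
focal component, survival or longevity. Assuming selection strong
relative to mutation, the balance frequency is

$$\hat p_i = \frac{2\mu_{f,i} + \mu_{m,i}}{2 s_{f,i} h_i + s_{m,i}},$$

and with multiplicative effects across $n_X$ loci the mean component
values are
$\bar W_f = \exp(-\sum_i 2 h_i s_{f,i}\alpha_{f,i}\hat p_i)$ and
$\bar W_m = \exp(-\sum_i s_{m,i}\alpha_{m,i}\hat p_i)$
(`genome_loads_exact()`). The effect size is their ratio. When the
sexes are symmetric and $h_i$ varies independently of the other
parameters, a Taylor expansion to second order in $h_i - \bar h$ gives

$$\frac{\bar W_f}{\bar W_m} \approx \exp\!\left(3 U_X \bar\alpha \left[
\frac{1-2\bar h}{1+2\bar h} + \frac{8\,\mathrm{var}(h)}{(1+2\bar h)^3}
\right]\right)$$

(`ratio_baseline()`), and dropping the variance term the baseline form
$\exp\!\left(3 U_X \bar\alpha \tfrac{1-2\bar h}{1+2\bar h}\right)$
(`ratio_simplified()`), where $U_X$ is the deleterious mutation rate
per X chromosome per generation. Three variants relax the symmetric
assumptions: constant sex-differential purifying selection
$\beta = s_m/s_f$ with equal viability effects per sex
(`ratio_sexdiff()`); fully sex-limited effects at half the loci
(`ratio_sex_limited()`, where dominance drops out entirely); and
hemizygous effects scaled by $k \le 1$ to represent absent dosage
compensation (`ratio_no_dosage_comp()`).

$U_X$ itself comes from the genome-wide deleterious rate $U_H$, the
X-linked genome fraction $P_X$, and male-biased mutation
$R_\mu = \bar\mu_m/\bar\mu_f$ (`ux_rate()`, `uz_rate()`): an X spends
two-thirds of its time in females, so male-biased mutation *dampens*
the X-linked budget (toward $\tfrac{2}{3}U_H P_X$) and inflates the
Z-linked one (toward $\tfrac{4}{3}U_H P_Z$). Z-linked ("unguarded Z")
predictions reuse the same algebra with sex labels reversed and
$\beta$ inverted; the `system` tag on a scenario only controls labels
and budget choice, never the arithmetic.

## Parameters that matter, and their defaults

| parameter | meaning | default | basis |
|---|---|---|---|
| $U_H$ | deleterious mutations per haploid genome per generation | 0.5 or 1.1 | mutation-accumulation/pedigree estimates: ~0.5 (fly, worm, mouse) to ~1.1 (human) |
| $P_X$, $P_Z$ | sex-linked genome fraction | 0.2 / 0.05 / 0.1 | Drosophila / mammal / bird karyotypes |
| $R_\mu$ | male/female per-site mutation | 1–4 | compiled estimates: typically 1–4 (mammals), 1–3 (birds) |
| $\bar h$ | mean dominance of deleterious mutations | 0.25 | mutation-accumulation data (plausible range ~0.18–0.36) |
| $\bar\alpha$ | survival share of fitness effects | 0.1–0.3 | Drosophila quantitative-genetic estimates |
| $\beta$ | male/female selection | 1–1.5 | sexual-selection assays |

`builtin_scenarios()` packages the standard combinations; the headline
predictions are deliberately small: 1.7% (mammal-like) and 3%
(Drosophila-like) female survival advantages, below 1% with plausible
sex-differential selection, 3.3–5.2% *male* advantages for bird-like ZW
genomes, and ~15% (log scale) only for haplodiploids, whose entire
haploid genome is hemizygous in males ($P_X = 1$).

## The recursion oracle and its domain

Every closed form above is an approximation, so the package carries an
exact deterministic check: a two-sex allele-frequency recursion for an
X-linked locus (`recursion_step()`, `solve_equilibrium()`), with census
at zygotes, viability selection (female fitnesses $1, 1-hs_f, 1-s_f$;
male $1, 1-s_m$) before gametogenesis, and one-way $A \to a$ mutation
in gametes. This ordering matches the standard derivation of the
balance frequency; the pooled X frequency is
$(2p_{egg}+p_{sperm})/3$. Iteration runs to an absolute per-generation
change below $10^{-12}$ (default cap $10^6$ generations), warm-started
from the closed form for speed; a cold start from zero reaches the
same fixed point and is used as an independence check in the tests.

Two accuracy regimes deserve explicit statement:

* **Mutation weak relative to selection.** The balance formula assumes
  $2\mu_f + \mu_m \ll 2s_f h + s_m$; the package warns when mutation
  pressure exceeds 1% of the selection denominator. At
  $\mu \sim 10^{-3}, s = 0.02$ the closed form is ~6% off the
  recursion.
* **Weak per-locus selection.** The closed form also carries an $O(s)$
  relative remainder (measured $\approx 0.33\,\max(s_f,s_m)$): ~0.3%
  at $s = 0.01$, ~1.6% at $s = 0.05$, ~10% at $s = 0.3$. The model's
  intended domain is the mildly deleterious mutations that dominate
  genomic deleterious rates ($s$ of order $10^{-2}$), and the
  validation grid samples $s \in [0.01, 0.025]$, $h \in [0.05, 0.5]$,
  $\mu \le 10^{-6}$, where agreement is within 1% everywhere (maximum
  observed 0.79% over 1,440 combinations). The breakdown at larger $s$
  is itself asserted in the test suite, not hidden.

A genuinely interesting non-failure: at $h = 0$ (full recessivity) the
closed form still holds for X-linked loci, because males remain
hemizygously exposed — $\hat p \to 3\mu/s_m$, not the
$\sqrt{\mu/s}$ scaling of autosomal recessives. The recursion confirms
agreement to ~0.5% there.

At the genome level, `validate_genome()` compares four routes to the
same ratio — recursion loads, the exact multiplicative sum, and the
two Taylor forms — on the same locus collection. On $10^4$ generated
loci the exact sum tracks the recursion to ~0.2% and the second-order
form tracks the exact sum to <0.1% on the log-ratio. The fourth-order
Taylor remainder is visible if dominance is spread widely: for
$h \sim U(0.1, 0.4)$ it is ~0.13%, a useful reminder that the
second-order formula is second-order.

## What the synthetic data do and do not emulate

`sample_loci()` draws per-locus parameters with exactly the
independence structure the summary formulas assume: $h$ from a beta
distribution rescaled to $(0, 0.5)$ with mean 0.25 and standard
deviation 0.07 (the data constrain the mean, not the family; the
dispersion is a plausible choice, and both are adjustable), $s$
constant or log-normal, $\alpha$ constant or beta, and a coupling rule
that can enforce the equal-viability-effect constraint
$\alpha_f s_f = \alpha_m s_m$ used by the sex-differential model.
Passing tests on these collections therefore shows internal
consistency of the model chain — locus draws through budgets through
ratios through the recursion — not that real genomes satisfy the
independence, multiplicativity, or equilibrium assumptions. Linkage,
epistasis, drift, and distributions of fitness effects fitted to real
data are all out of scope by design.

`sample_rmu_table()` emulates a curated literature compilation of
$R_\mu$ estimates: lineage groups with different typical sex bias,
duplicate estimates per species, missing interval bounds, and injected
outliers. It exists so the curation pipeline (`load_rmu()`,
`apply_exclusions()`, `species_average()`, `group_summary()`) can be
tested against known structure. The pipeline order is fixed —
exclusions, then per-species averaging, then group summaries — because
excluding an implausible estimate (the canonical example is a single
$R_\mu \sim 20$ human value) *after* averaging would contaminate that
species' mean. Applied to the published compilation this pipeline
yields the reported 118 species-level estimates; that file is not
redistributable here, so the packaged tests exercise the pipeline on
synthetic tables only.

## Numerical and design choices

* All load sums are accumulated in log space and exponentiated once;
  with $10^4$–$10^6$ loci each contributing $\sim 10^{-7}$, naive
  products would lose precision.
* A ratio is reported in three labelled percent conventions —
  `excess` $= 100(r-1)$, `deficit` $= 100(1-1/r)$, `log_pct`
  $= 100\ln r$ — because the literature mixes them; every report says
  which it uses. Ratios are printed to 4 significant figures and
  percents to 1 decimal.
* Survival factors $\le 0$ raise errors rather than being clamped: the
  linearized per-locus model is meaningless there.
* $h > 0.5$ is accepted (up to 1, overdominance excluded) with a
  warning; predicted ratios are then $\le 1$.
* Combining $\beta \ne 1$ with $k < 1$ is rejected rather than
  guessed: the two departures interact in a way the model does not
  define. Likewise the dosage-compensation variant is a $k$-scaling
  re-derivation that reproduces the three qualitative conclusions
  expected of it (restricted dominance range with an effect only for
  $\bar h < k/2$, dampening for all $k < 1$, no dampening at
  $h = 0$); its exact published counterpart is not available for
  line-by-line comparison, so it is documented as a variant.
* Haplodiploidy is treated as an XY system with $P_X = 1$ and
  $R_\mu = \beta = 1$.
* Problem sizes in the shipped tests and scripts — 1,440 grid
  combinations and $10^3$–$10^4$ loci for the recursion checks — were
  chosen to characterize the approximations cleanly; all recursions
  are vectorized across loci, so a full validation run takes seconds.

## Worked example

```{r example, eval = FALSE}
library(unguardedX)

# a named scenario end to end
predict_scenario("drosophila_baseline")

# the same number assembled by hand
U_X <- ux_rate(U_H = 0.5, P_X = 0.2, R_mu = 1)
ratio_simplified(U_X, h_bar = 0.25, alpha_bar = 0.3)

# and validated by brute force on a sampled genome
loci <- sample_loci(1e4, seed = 1)
validate_genome(loci)
```

## Limitations

The model is deterministic and single-locus at heart: no drift, no
linkage or background-selection interference, no epistasis (synergistic
epistasis would amplify haploid-expressed loads), no attempt to infer
parameters from sequence data. Predictions inherit the uncertainty of
$U_H$, $\bar h$, and $\bar\alpha$, which are point estimates from a
handful of model organisms. These are limitations of scope, not bugs:
the point of the package is that even taking the hypothesis's
assumptions at face value, the predicted sex differences in survival
are an order of magnitude too small to explain observed longevity gaps
in most taxa — with haplodiploids the interesting exception.
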