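---
title: "Assigning pregnancy from blubber progesterone: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning pregnancy from blubber progesterone: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belugapreg)
```

## The problem

Progesterone is the primary progestogen of pregnancy and, being lipophilic,
accumulates in blubber. A remote biopsy from a free-ranging whale (or a
necropsy sample from a carcass) therefore carries a signal of the animal's
reproductive state. Two questions follow:

1. **Individual**: given a blubber progesterone (BP) concentration, was this
   female pregnant when sampled?
2. **Population**: given a set of blindly collected samples — sex, maturity
   and reproductive status unknown at darting time — what fraction of the
   mature females is pregnant?

The second question is harder than it looks: a blind sample contains males
(removable by genetic sexing), immature females, lactating females that are
under-sampled because a flanking calf makes darting risky, and females whose
maturity can only be guessed from skin colour. This package implements the
full chain from raw immunoassay output to a maturity-corrected population
pregnancy rate, with a synthetic-data generator so every stage is testable.

## Units and preprocessing

The immunoassay reports pg/mL of resuspended extract. The back-calculation
to tissue concentration is the standard ELISA chain,

$$\mathrm{BP}_{\mathrm{tissue}} =
  \frac{\mathrm{raw} \times V_{\mathrm{buffer}} \times D / 1000}
       {r \times m_{\mathrm{blubber}}}\ \ \mathrm{ng\,g^{-1}},$$

with buffer volume $V$ defaulting to 0.5 mL (a 500-µL resuspension), dilution
factor $D \ge 1$, recovery fraction $r \in (0,1]$ (assay batches here
measured 0.883 for carcasses and 0.710 for biopsies) and wet blubber mass
$m$ in grams. The published protocol never writes this formula out; we fix
it so that unit tests are bit-exact. Because the chain is a single product,
the order of dilution and recovery correction is immaterial.

Per-lipid concentrations are
$\mathrm{BP}_{\mathrm{lipid}} = \mathrm{BP}_{\mathrm{tissue}} / \ell$ with
$\ell$ the lipid mass fraction. Carcass samples without a measured $\ell$
are imputed with 0.664 (the mean of the measured carcass subset) and
flagged. Samples with $\ell \le 0.05$ are excluded before analysis — the
boundary is inclusive because the rule is stated as "at or below 5%" — since
tiny lipid masses make the per-lipid ratio explode and drive unit-dependent
assignment flips; flips concentrate below 10% lipid.

All models run on natural-log BP. The natural (not base-10) log is pinned by
the printed correspondence $\ln 55 \approx 4.0$. Non-positive values are
rejected rather than silently floored; `floor_detection_limit()` (default
0.1 ng/g, the smallest observed group value) is the explicit alternative.

## Three classifiers

**Fixed threshold.** Concentrations at or above 100 ng/g tissue (150 ng/g
lipid) are called pregnant. The threshold sits in an empirically empty band
(no observed values between 85.9 and 114 ng/g tissue); `find_gap()` locates
such a band as the widest spacing between consecutive order statistics
inside a search window (default 1–1000 ng/g, so the unbounded gap above the
maximum never wins; ties break toward the lower interval). Values exactly at
the threshold are classified pregnant — the data never produce one, so the
convention is free, and we fix inclusive-above.

**Bayesian Gaussian mixture.** Log BP is modelled as a K-component normal
mixture sampled by Gibbs. Priors are weakly informative: means
$\mathcal{N}(0, 10^2)$ on the log scale (covering the plausible log-BP range
of roughly −2.3 to 7.1 without favouring any cluster), SDs Half-Normal(5),
weights symmetric Dirichlet(1). The SD update is a random-walk Metropolis
step on $\log\sigma$ (the Half-Normal prior is not conjugate); everything
else is conjugate. Label switching is handled by re-sorting components into
ascending-mean order inside every sweep, so the identifiability constraint
$\mu_1 \le \dots \le \mu_K$ holds in every retained draw — an invariant the
test suite asserts draw by draw. The highest-mean component is pregnant; with
K = 3 the middle component is the "intermediate" cluster where lactating and
recently parturient females tend to sit; K = 1 is labelled undifferentiated
with a warning. K is chosen over {1, 2, 3} by WAIC,
$-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, using the variance form of
$p_{\mathrm{WAIC}}$ (the common default; the choice of variant is not
prescribed by the protocol we follow). Per-sample membership probabilities
are responsibilities averaged over retained draws; rows sum to 1 within
$10^{-9}$.

**Bayesian logistic regression.** Pregnancy (1) versus non-pregnancy (0) is
regressed on log BP with $\mathcal{N}(0, 10^2)$ priors on both coefficients.
Males, immature females, resting and lactating females train as 0; pregnant
females as 1; recently parturient females — whose blubber may still carry
the ended pregnancy's signal — enter as missing responses and are predicted,
as is every unknown-status individual. Missing responses contribute nothing
to the likelihood, so their posterior predictive probability
$E[\mathrm{logit}^{-1}(\beta_0 + \beta_1 x)]$ is exact, not an imputation
approximation. The sampler is a component-wise random-walk Metropolis on the
centred predictor (centring removes the intercept–slope correlation that
cripples mixing on the raw scale). A probability at or above 0.5 indicates
pregnancy (boundary inclusive, as the rule is stated). The odds ratio
$e^{\beta_1}$ is per unit of *log* BP — the published phrasing "per ng/g" is
ambiguous, but the predictor is explicitly log-transformed, so per-unit-log
is implemented and the ambiguity documented rather than resolved. The
equal-odds concentration is $e^{-\beta_0/\beta_1}$ per draw; it is refused
(with advice to summarise on the log scale) when slope draws straddle zero.

### MCMC protocol and diagnostics

The canonical settings are 50 000 iterations × 3 chains, burn-in 10 000,
thinning 40 — 1000 retained draws per chain. `scaled_mcmc_settings()` (5000
iterations, burn-in 1000, thinning 4) retains the same 1000 draws per chain
at a fraction of the cost and is what the test suite and simulation studies
use; recovery behaviour is indistinguishable on these well-separated
mixtures. Convergence is summarised by the classic Gelman–Rubin statistic
$\hat R = \sqrt{\left(\tfrac{n-1}{n}W + \tfrac{B}{n}\right)/W}$ for every
parameter; anything above 1.1 triggers a warning with the offending
parameters named (the original protocol assessed traces visually; 1.1 is the
conventional numeric stand-in). For exactly duplicated chains $B = 0$ and
$\hat R = \sqrt{(n-1)/n} < 1$: the statistic reaches 1 only asymptotically,
which is why the duplicate-chain test uses long chains. Draws are
bit-reproducible: each chain's seed derives deterministically from the one
user seed via `split_seed()`, which also isolates the RNG from the caller's
session state.

## Evaluation

Classifiers are scored against necropsy truth with an adjudication rule:
pregnant and recently parturient females are expected pregnant (the
post-partum BP decay lag is assumed longer than the sampling gap), everyone
else non-pregnant. This is an assumption, not ground truth — the two
recently parturient females with already-low BP count against any
classifier under it. Intermediate-cluster assignments score as non-pregnant
in the dichotomous comparison, mirroring the pregnancy-rate arithmetic that
counts intermediates in the mature denominator but not the pregnant
numerator. `unit_switch_fraction()` quantifies how many assignments flip
between per-tissue and per-lipid reporting and joins the flips to lipid
fractions, because low-lipid samples are where the flips live.

## Pregnancy rate with maturity correction

Colour class (grey → off-white → white) is an imperfect maturity proxy.
Necropsies of 3+-year-old females give the schedule: white 100%, off-white
100%, grey 10% mature; with a three-year calving cycle, a third of mature
females should be pregnant in any year (`cycle_fraction = 1/3`,
overridable). Females repeatedly flanked by a newborn calf that would have
been darted but were not ("virtual biopsies") enter as lactating — mature,
non-pregnant — records with no BP value, so classifier and rate see the same
world without the anti-lactation sampling bias.

The raw rate divides presumed-pregnant females by the *minimum* mature count
(pregnant + intermediate + virtual lactating). The correction distributes
the remaining non-pregnant females over colour classes, adds
$\mathrm{round}(\sum_c n_c p_c)$ to the denominator, and reports both rates
with a per-class audit table. Rounding is to the nearest integer with halves
away from zero — the only convention that reproduces both published
roundings (49.2 → 49 totals built from a 4.2, and 10.5 → 11). Unrounded
values are always carried alongside.

## The synthetic world

The generator exists so that every stage has a testable stand-in for the
archived field data. Its defaults are the stated world, chosen once:

* **Known-status groups**: the seven validation groups with their published
  raw-scale moments (pregnant 365 ± 244, recently parturient 273 ± 227,
  lactating 38.4 ± 100, resting 3.1 ± 4.5 ng/g, …, n = 62 in total). The
  within-group distributional form is *not* published; we use a lognormal
  with moment-matched parameters ($\sigma^2 = \ln(1+s^2/m^2)$,
  $\mu = \ln m - \sigma^2/2$) as the minimal choice consistent with positive
  concentrations and log-scale modelling. This is an implementation choice,
  not a claim about the data.
* **Blind populations**: mixtures of those groups. The biopsy-like default
  uses three components (resting/lactating/pregnant) with weights near the
  observed 20/23/22 three-cluster split, lipid fractions Beta-distributed
  with mean 0.243 (biopsies) versus 0.664/0.609 (carcasses) — the published
  ≈2.6-fold contrast — and SD 0.15 for biopsies, wide enough to reproduce a
  realistic share of sub-5% lipid samples; and the observed colour mix
  (≈25% grey). Lipid draws are truncated at $10^{-4}$ so per-lipid units
  stay finite. The latent component of each draw is stored only in
  `latent_truth`, a column no classifier reads — recovery tests use it,
  inference never does.

What the generator does **not** emulate: assay noise beyond the group SDs
(no plate effects, no inter-/intra-assay CV structure), carcass decay
effects on lipid and hormone recovery, age or senescence structure within
groups, and spatial/herd segregation. A green recovery test therefore
establishes that the inference machinery works when the world matches the
model's assumptions — it cannot certify the field data satisfy them.

## Numerical and degenerate-input choices

* `sd_raw = 0` groups are point masses (no RNG consumed); empty spec lists
  give empty, correctly typed tables.
* Beta moment matching refuses infeasible pairs ($s^2 \ge m(1-m)$) instead
  of clipping.
* The Gibbs sampler initialises means at evenly spaced order statistics and
  SDs at the pooled SD — deterministic, so reproducibility rests on the seed
  alone. Empty components fall back to their priors for that sweep.
* `find_gap()` requires two distinct values and errors on degenerate input;
  a constant sample has no gap.
* CSV round trips are exact: doubles are written with 17 significant digits.
* Schema validation reports row numbers; duplicate ids, unknown enum values
  and negative concentrations are hard errors, not warnings.

## Limitations

Per-dataset K selection is treated as canonical; pooling samples across
programs into one fit is available by simple concatenation but changes the
meaning of the clusters (forcing K = 2 on biopsy-like data merges the
intermediate and high clusters and drags the implied threshold below
biologically sensible levels). The adjudication of recently parturient
females is an assumption either way. The maturity schedule comes from
carcasses and is applied to live animals; grey colouration can persist into
adulthood, so the grey maturity probability is likely the weakest number in
the chain. None of the rate machinery corrects for reproductive senescence,
calf mortality or late-parturient inflation.
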