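---
title: "Methods: two-sample and multivariable MR in mrlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and multivariable MR in mrlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlink)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure. For variant $j$, a GWAS of the exposure provides
$\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$, and an independent GWAS
of the outcome provides $\hat\beta_{Yj}$ with $\sigma_{Yj}$. If variant $j$
is a valid instrument — associated with the exposure, unconfounded, and
affecting the outcome only through the exposure — then
$\beta_{Yj} = \theta\,\beta_{Xj}$, and $\theta$ is the causal effect of the
exposure on the outcome. Binary exposures analysed by logistic regression
enter on the log-odds scale, and $\theta$ is interpreted against a latent
liability: a unit increase in the log odds is an $e$-fold ($2.72\times$)
multiplicative increase in the odds, so $\theta \ln 2$ is the effect per
doubling of liability (a good approximation to a doubling of prevalence
when the condition is rare).

The inverse-variance weighted (IVW) estimator is the zero-intercept
weighted least-squares slope of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with
weights $1/\sigma_{Yj}^2$. Cochran's
$Q=\sum_j w_j(\hat\beta_{Yj}-\hat\theta\hat\beta_{Xj})^2$ on $n-1$ df
measures heterogeneity; under the default multiplicative random-effects
model the IVW standard error is inflated by $\sqrt{\max(1, Q/(n-1))}$, so
overdispersion widens intervals but underdispersion is never allowed to
narrow them. The same convention applies to the MR-Egger fit and the
multivariable model.

## Sensitivity estimators and their assumptions

Each estimator trades efficiency for robustness to a different violation:

* **MR-Egger** frees the intercept; under the InSIDE assumption
  (pleiotropic effects independent of instrument strength) the intercept
  estimates the average directional pleiotropic effect and the slope is a
  pleiotropy-adjusted causal estimate. Identification requires a common
  orientation, so rows are flipped to $\hat\beta_{Xj} \ge 0$ before
  fitting; inference uses the $t$ distribution on $n-2$ df. Because the
  exposure coefficients are measured with error, the Egger slope suffers
  regression dilution; **SIMEX** re-estimates the slope after inflating
  that error by factors $\lambda$ over a grid (default
  $\{0, 0.5, 1, 1.5, 2\}$, 200 replicates per $\lambda$), fits a quadratic
  in $\lambda$, and extrapolates to $\lambda=-1$, the error-free limit.
  The SE is a jackknife over replicates; with zero exposure-coefficient SE
  the procedure returns the plain Egger slope.
* **Weighted median**: consistent when instruments carrying $\ge 50\%$ of
  the inverse-variance weight are valid. The estimate interpolates the
  per-SNP Wald ratios $\hat\beta_{Yj}/\hat\beta_{Xj}$ at cumulative
  standardized weight 0.5; the SE is a parametric bootstrap (default 1000
  resamples) drawing both coordinates from normal distributions centred on
  the observed values.
* **Weighted mode**: consistent when the largest cluster of instruments is
  valid. The ratio density is kernel-smoothed with bandwidth
  `bandwidth_factor` $\times\,0.9\min(\mathrm{sd},\mathrm{mad})\,n^{-1/5}$;
  when the mad degenerates to zero (a majority of identical ratios) the
  spread falls back to IQR$/1.349$, then to the sd.
* **MR-RAPS** solves the profile-score equation with standardized
  residuals
  $t_j(\theta) = (\hat\beta_{Yj}-\theta\hat\beta_{Xj}) / \sqrt{\sigma_{Yj}^2+\theta^2\sigma_{Xj}^2+\tau^2}$,
  which accounts for exposure-side sampling error and is therefore robust
  to weak instruments. The default uses the Huber influence function
  (tuning constant 1.345) and profiles the overdispersion $\tau^2$ through
  the second-moment equation $\sum_j(\psi(t_j)t_j-\delta)/\sigma_j^2=0$
  with $\delta=E[\psi(Z)Z]=2\Phi(1.345)-1$ for standard normal $Z$
  ($\delta = 1$ for the `l2` loss). Estimation minimizes the integrated
  objective rather than bracketing the score's root — the score decays to
  zero in both tails, so sign-change bracketing is unreliable on small
  instrument sets — and the SE is the usual sandwich.
* **Steiger filtering** discards variants more strongly associated with
  the outcome than the exposure: $r^2$ from $t^2/(t^2+n-2)$ for continuous
  traits and from the observed-scale approximation $z^2/n$ for binary
  traits (default). An alternative log-odds-based approximation,
  $r^2 = 2f(1-f)\beta^2 / (2f(1-f)\beta^2 + \pi^2/3)$, is available behind
  `binary_method = "logodds"` but requires allele frequencies; the
  observed-scale default was chosen because the ADHD- and ASD-style inputs
  this package emulates ship without frequency columns. The per-variant
  z-test compares the two correlations through Fisher's transformation.

## Instrument processing

Selection keeps variants with $p \le$ `p_threshold` (conventionally
$5\times10^{-8}$; a relaxed threshold such as $5\times10^{-7}$ buys power
for underpowered traits at the cost of potential weak-instrument bias —
which is why MR-RAPS is part of the default battery). Clumping is greedy:
variants are ranked by p-value (ties broken by id for determinism) and
accepted only if their $r^2$ with every accepted variant on the same
chromosome within `clump_kb` (default 10 000 kb; 1-based coordinates,
window test $|pos_a-pos_b| \le$ `clump_kb` $\times 1000$) stays below
`clump_r2` (default 0.01). LD comes from a local three-column table;
pairs absent from it are treated as unlinked and noted once, matching
common clumping-tool behaviour. Instruments missing from the outcome GWAS
are replaced by their best LD proxy with $r^2 >$ `proxy_r2` (default 0.9)
present in both tables, or dropped with a logged reason.

Harmonization aligns every trait to the first exposure's effect allele:
swapped allele orders negate the beta, alternate-strand records are mapped
through the base complement first, and palindromic A/T and C/G variants —
whose strand cannot be resolved from the alleles — are excluded by
default. When `use_eaf = TRUE` both sides' allele frequencies may rescue a
palindromic variant by matching the minor allele, unless either frequency
falls within `eaf_window` (default 0.08, i.e. 0.42–0.58) of 0.5, where
orientation is hopeless. The default reproduces unconditional exclusion
because the binary-trait inputs this package emulates carry no frequency
columns; the rescue stays behind a flag for frequency-bearing inputs. In
multivariable runs the additional exposures are harmonized onto the first
exposure's allele before the outcome, making results stable under a
declared exposure order.

## Multivariable MR

With $K$ exposures the direct effects solve the weighted regression of
$\hat\beta_{Yj}$ on the $K$ exposure-coefficient columns without
intercept. Heterogeneity uses the exposure-uncertainty-adjusted
$Q_a(\theta)=\sum_j
(\hat\beta_{Yj}-\sum_k\theta_k\hat\beta_{X_kj})^2 /
(\sigma_{Yj}^2+\sum_k\theta_k^2\sigma_{X_kj}^2)$ on $n-K$ df. Conditional
instrument strength for exposure $k$ minimizes the analogous statistic of
$\hat\beta_{X_kj}$ on the other exposures' columns and divides by
$n-K+1$; values near the univariable mean F indicate instruments specific
to that exposure, values near zero indicate none. Cross-exposure
covariances of the estimated coefficients are taken as zero throughout —
they are not recoverable from separate summary files — and the
denominator is floored at `1e-300` so the zero-noise limit diverges
cleanly rather than erroring.

The weak-instrument-robust estimator minimizes $Q_a$ itself (Nelder–Mead
from the IVW solution with restarts at $\pm20\%$ perturbations,
convergence tolerance $10^{-10}$; golden-section search when $K=1$).
Confidence intervals are percentile 2.5/97.5 from a non-parametric
bootstrap resampling SNPs with replacement (default 1000 iterations) —
the simplest faithful reading of a non-parametric bootstrap — and the
result records whether each robust CI overlaps the IVW CI, the
concordance check used to support findings in the presence of weak
instruments.

## The synthetic generator

`simulate_pair()`/`simulate_mvmr()` draw true exposure effects
$\beta_{Xj}\sim N(0,$ `bx_sd`$^2)$ (default 0.02, truncated so every
instrument's expected $|z| \ge 6.5$ when significant instruments are
requested, and optionally forced positive — the orientation in which the
Egger intercept estimates the mean directional effect), set
$\beta_{Yj}=\theta\beta_{Xj}+\alpha_j$, and add sampling noise with
$\mathrm{SE}=1/\sqrt{2nf(1-f)}$ at reference allele frequency $f$ (drawn
uniform(0.05, 0.5) when frequencies are requested, constant 0.25
otherwise; doubled for log-odds-scale binary traits — the typical
inflation of logistic over linear coefficient SEs at moderate
case fractions). Pleiotropy $\alpha_j$ is zero, mean-zero normal,
directional (mean = magnitude), or InSIDE-violating (correlated with
instrument strength), applied to a configurable fraction of variants. LD
blocks are exchangeable within-block $r^2$ draws, zero across blocks —
enough structure for clumping and proxy logic, far simpler than a real
LD map. Emitted p-values equal the two-sided normal p of $z=\beta/SE$,
floored at the smallest normalized double (published GWAS files truncate
extreme p-values the same way).

`fixture_bundle()` emits four bundles shaped like the published
ADHD/ASD/educational-attainment/cognitive-ability analyses: 11, 10 and
481 primary instruments with per-SNP F drawn from the reported ranges
(30–51, 26–36, 30–240), always a 212-instrument cognitive-ability second
exposure (F 30–120, a package choice — no range is published), GWAS
sizes taken from the source studies (55 374; 46 350; 766 345; 269 867),
and generative direct effects set to the published direct estimates with
cognitive-ability effects of ±0.3 to ±0.5. Each instrument carries an LD
satellite ($r^2=0.95$, strictly weaker p-value, so clumping always
prefers the instrument), one instrument is withheld from the outcome
table to exercise proxy substitution, outcome records mix copied,
swapped and strand-complemented representations, and null fillers (some
palindromic) pad the tables. The education-attainment bundles embed
exactly 81 (ADHD outcome) and 62 (ASD outcome) reverse-direction
contaminants whose outcome variance explained is three times their
exposure variance explained; all other instruments are
direction-guarded, so Steiger filtering removes exactly the contaminant
set by construction. Weak cross-trait effects are clamped at $|z|\le4.5$
so no stray variant crosses the instrument threshold and perturbs the
counts.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: genome-wide LD with realistic decay,
allele-frequency-dependent power, sample overlap between GWAS, dynastic
effects and assortative mating, selection into diagnosis, and the
pervasive correlated pleiotropy of behavioural traits. Estimator
calibration here demonstrates correctness of the implementations under
their own assumptions, not robustness of any substantive conclusion.

## Numerical choices and degenerate inputs

Ties in clumping break by ascending variant id; p-value validation
(optional, off by default because published files truncate p-values)
tolerates 0.5 on the $\log_{10}$ scale; one-SNP IVW degrades to the Wald
ratio with an undefined heterogeneity p; Egger-family methods refuse
fewer than three instruments as a classed error, which the pipeline
reports as a not-estimable row rather than aborting; zero exposure
effects are a data error naming the variant (the Wald ratio is
undefined); collinear exposure columns (relative singular value below
$10^{-8}$) raise a numerical error advising inspection of the
conditional F. All randomized procedures (SIMEX, bootstraps, the
generator) require explicit seeds, and `run_plan()` seeds once from the
plan, so identical plans produce byte-identical reports.

## Simulation design of the verification suite

The test-and-acceptance experiments use problem sizes chosen to estimate
each property precisely at desk scale: CI coverage from 1000 replicates
of 50 strong instruments (Monte Carlo SE of the coverage estimate
$\approx 0.7$ points); multivariable recovery of $(0.3, -0.2)$ from 500
replicates of 200 SNPs; weak-instrument comparisons from 200 replicates
at mean F $\approx 5$ (exposure effect SD set to twice the coefficient
SE at $n=20\,000$); and the weighted-median contamination experiment at
education-GWAS-scale sample sizes ($10^5$ exposure, $10^6$ outcome),
where per-SNP ratio noise is small enough for the estimator's asymptotic
consistency to be visible through 30% invalid instruments.

## Limitations

The per-SNP F statistic is the squared z approximation, appropriate for
summary data without variance-explained columns. The binary-trait Steiger
$r^2$ is an observed-scale approximation; liability-scale conversion is
not attempted. SIMEX extrapolation is quadratic — the conventional
choice, but still an extrapolation. Conditional F assumes independent
exposure GWAS (zero estimate covariance). More than two exposures are
supported by the algebra but exercised only lightly. The doubling-of-
liability interpretation assumes a rare condition; for common conditions
the odds–prevalence equivalence degrades, which the conversion does not
model.
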