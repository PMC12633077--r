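---
title: "Cosinor rhythmometry for cross-sectional circadian designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosinor rhythmometry for cross-sectional circadian designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmr)
```

## The model and its assumptions

`rhythmr` fits the single-cosinor model

$$Y(t) = M + A\cos\!\left(\frac{2\pi t}{\tau} + \phi\right) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

to data from a **cross-sectional** circadian design: each subject is
measured once, at one zeitgeber time, and the rhythm is estimated across
subjects. The period $\tau$ is fixed (24 h by default) rather than
estimated — the sampling designs this package targets (six timepoints at
4-h spacing) cannot resolve period and phase simultaneously, and a fixed
24-h period is the convention for entrained animals. With $\tau$ fixed,
the model is linear in $\beta = A\cos\phi$ and $\gamma = -A\sin\phi$:

$$Y = M + \beta x + \gamma z, \qquad
x = \cos\frac{2\pi t}{\tau},\; z = \sin\frac{2\pi t}{\tau},$$

so plain OLS estimates $(M, \beta, \gamma)$ with covariance
$\sigma^2 (X^\top X)^{-1}$, $\hat\sigma^2 = \mathrm{RSS}/(n-3)$. No
weighting or robust loss is applied: the additive homoscedastic Gaussian
error model is the one the OLS cosinor presumes, and the simulators
generate from exactly that model so that calibration statements are
meaningful.

Amplitude and acrophase are delinearized as
$A = \sqrt{\beta^2 + \gamma^2}$, $\phi = \mathrm{atan2}(-\gamma, \beta)$,
and the acrophase is reported as the clock time of the fitted peak,
$(-\phi\,\tau/2\pi) \bmod \tau$, in hours on $[0, \tau)$ — the convention
used in published rhythm tables — rather than as a negative angle in
radians ($\phi$ is kept internally). Standard errors for $A$ and the
acrophase come from the delta method applied to the $(\beta, \gamma)$
block of the OLS covariance; the acrophase SE is converted from radians
to hours by $\tau/2\pi$. The delta method is a large-sample
approximation that degrades when $A/\mathrm{SE}(A)$ is small — the
acrophase of a barely-rhythmic feature is poorly determined, and its
nominal SE should be read with that in mind.

Assumptions, explicitly: independent errors across subjects (guaranteed
here by the one-measurement-per-subject design — there is no
repeated-measures correlation to model), equal error variance across
timepoints, and a single sinusoidal component. Waveforms with harmonics
are estimated consistently for their fundamental but the zero-amplitude
test loses power against them.

## Rhythm detection and group comparison

The **zero-amplitude test** asks whether the cosine explains anything
beyond a flat mean:
$F = (\mathrm{MSS}/2)/(\mathrm{RSS}/(n-3)) \sim F(2, n-3)$ under the
null, equivalently $F = (R^2/2)\,/\,((1-R^2)/(n-3))$. Degenerate inputs
are resolved, not crashed on: a flat series returns $F = 0$, $p = 1$; a
perfect fit (RSS numerically zero against a nonzero model sum of
squares) returns $p = 0$ with an infinite statistic and a
`perfect_fit` note.

For two groups, the comparison of each rhythm parameter uses a
Wald-type ratio
$F = (\hat\theta_1 - \hat\theta_2)^2 / (SE_1^2 + SE_2^2)$ on
$F(1, n_1 + n_2 - 6)$ — six denominator degrees of freedom removed for
the two fits' three coefficients each. This was a genuine design choice:
the cited methodology fixes only the df structure ("number of populations
and total number of subjects"), not the statistic. The Wald form was
chosen because it reduces to a squared two-sample $t$ in the balanced
case, uses exactly the delta-method SEs already reported in the rhythm
table, and is symmetric in the groups. Its finite-sample calibration is
checked by simulation (see below) rather than assumed.

Acrophases live on a circle, so their difference is wrapped onto
$(-\tau/2, \tau/2]$ before testing: peaks at ZT23.5 and ZT0.5 differ by
1 h. The antipodal boundary (a difference of exactly $\tau/2$) is
assigned $+\tau/2$ by convention — a measure-zero tie-break that keeps
the function total. When either group's amplitude is numerically zero
($A < 10^{-10}\max(1, |M|)$) its acrophase is undefined, and the
acrophase comparison returns a flagged non-result instead of propagating
`NaN` through the table.

**Population-mean cosinor.** When several fits contribute (per-cage
series, bootstrap replicates), their *linearized* coefficients
$(M, \beta, \gamma)$ are averaged and the mean vector is delinearized.
Averaging in the $(\beta, \gamma)$ plane is essential: acrophase angles
averaged directly would put the mean of 1 h and 23 h at noon. SEs come
from the empirical covariance of the contributing vectors (defined for
$k \ge 2$). One ambiguity deserves note: with every subject measured
once, a per-subject cosinor fit is impossible, so "averaging across
samples" cannot mean subjects. The package therefore exposes both
pathways — the pooled single cosinor per group (the default throughout
the pipeline) and `population_cosinor()` for genuinely multi-series
inputs — rather than guessing.

**Per-timepoint tests.** The companion analysis is a pooled-variance
Student's t at each timepoint (Welch is available by flag but pooled is
the default, matching how such tests are conventionally reported for
small balanced groups). Zero-variance cells return $p = 1$ (equal means)
or a flagged $p = 0$ (unequal), since the t statistic does not exist
there.

**Multiplicity.** Benjamini–Hochberg adjustment is applied within each
test family across features: zero-amplitude over feature × group rows,
and each comparison family over features. Raw p-values are always kept
alongside adjusted ones, because single-feature analyses (a targeted
qPCR panel) are conventionally read unadjusted while screens (per-taxon
scans) are read at an adjusted threshold; the default flag for
compositional screens is adjusted $p < 0.01$, versus $\alpha = 0.05$ on
raw p for the `rhythmic` flag.

## The microbiome stage

Counts are aggregated at a taxonomic rank by summation (per-sample
totals are conserved exactly; taxa missing the rank pool into
`unclassified_<nearest named parent>`), then converted to relative
abundances. The per-taxon cosinor runs **on the raw proportion scale**:
published rhythm tables report microbial MESORs as proportions, and
keeping that scale makes the fitted parameters directly comparable. An
arcsine-square-root option exists for users who prefer
variance-stabilized proportions, but it is off by default — with it on,
MESOR and amplitude are no longer in abundance units. Proportions also
make the analysis invariant to library size by construction.

Two caveats are inherent to compositional data and worth stating. First,
when one taxon truly oscillates, closure forces every other proportion
to oscillate weakly in antiphase; a "flat" taxon in proportion space is
flat only relative to the whole community. Second, Dirichlet-multinomial
noise on a proportion is not Gaussian; the F-test on proportions is
justified by the central-limit behaviour of per-sample proportions at
realistic library sizes (tens of thousands of reads), and its
calibration under the package's own generator is verified by simulation,
not assumed for arbitrary real data.

Community-level testing is a one-way PERMANOVA on Bray–Curtis
dissimilarities: pseudo-$F$ from among- versus within-group sums of
squared dissimilarities, with $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$
over seeded random relabelings. The $+1$ correction means $p$ is never
exactly zero and is bounded below by $1/(1+n_{perm})$. The permutation
stream is a pure function of the seed, so results are bit-reproducible.
Bray–Curtis + PERMANOVA was chosen as the community statistic because it
is the standard distance-based test with a clean permutation null;
ordination-based alternatives (canonical correspondence analysis)
conflate projection and testing and are out of scope here.

## The synthetic generators

`simulate_cohort()` emulates the motivating design: groups × six
zeitgeber times at 4-h spacing, 3–6 subjects per cell (drawn uniformly
per cell by default, with a fixed-n override for power work), each
subject measured once, values from the cosinor model plus Gaussian
noise. Subject IDs are shared across features within a cell — one animal
yields all its measurements — but feature noise is independent; the
generator does not model between-feature correlation. Where no
dispersion estimate exists for a published parameter set, the package
convention is `noise_sd = amplitude/4`, i.e. a signal-to-noise ratio of
4, a clearly-detectable but not noiseless rhythm.

`simulate_microbiome()` draws, per sample, expected proportions
$p_i(t) \propto b_i + A_i\cos(2\pi t/\tau + \phi_i)$ (renormalized;
amplitudes are validated to keep every expected proportion positive), a
Dirichlet vector with concentration $c \cdot p(t)$ for overdispersion,
and multinomial counts at a lognormal library size (median 20,000 reads
by default, a typical 16S depth). `concentration = Inf` collapses to a
pure multinomial. Not modeled: chimeras, copy-number variation,
taxon-taxon interactions, longitudinal autocorrelation. Passing tests on
these generators therefore demonstrates correctness of the estimators
and calibration *under the stated model*, not robustness to every
pathology of real sequencing data.

Both generators are pure functions of (parameters, seed) and leave the
caller's RNG state untouched.

## Numerical choices

* Rank checks are explicit: fewer than three distinct timepoints modulo
  the period, or a collinear design, is an error naming the problem — no
  silent pseudo-inverse.
* $A < 10^{-10}\max(1, |M|)$ flags the amplitude as numerically zero and
  the acrophase as undefined; downstream comparisons return flagged
  non-results.
* Flat-series and perfect-fit branches of the zero-amplitude test use a
  relative tolerance of $10^{-12}$ on the sums of squares.
* Timepoints are compared modulo the period after rounding to $10^{-9}$ h
  to avoid floating-point aliasing.
* Cohort TSVs are re-parsed with C `strtod` so that a written table reads
  back to bit-identical doubles (a round trip is byte-identical).
* One sign convention: relabeling all clock times $t \to t + \Delta$
  (values unchanged) moves the fitted acrophase *forward* by $\Delta$
  modulo $\tau$; M, A, $R^2$ and all p-values are unaffected.

## Problem sizes and verification

The test suite verifies the estimators against independent oracles
(explicit normal-equations solve; incomplete-beta F tail; brute-force
BH step-up; exhaustive 3+3 permutation enumeration; `vegan::adonis2`
for the PERMANOVA pseudo-F) and checks calibration and power by
simulation at the design's own scale: 2000-replicate nulls for the
zero-amplitude test (6 ZTs × n = 5) and for the three group-comparison
tests (n = 30 per group), 500-replicate parameter-recovery harnesses for
published parameter sets (6 ZTs × n = 8, noise SD = amplitude/4), and
100-run screens for the microbiome spike-in, null-calibration and
acrophase-shift scenarios. These sizes hold Monte-Carlo error on a
rejection rate near 0.05 to about ±0.005–0.01 while keeping the full
suite fast on a single core.

## Known limitations

* Fixed period only: no period estimation, no multi-component cosinor,
  no Lomb–Scargle/JTK-style alternatives.
* Two-group comparisons only; no omnibus test across three or more
  groups, and no joint amplitude–acrophase test (the Wald tests treat
  parameters marginally).
* The published parameter sets used as simulation ground truths
  occasionally imply amplitudes exceeding the MESOR — negative fitted
  troughs for nonnegative quantities. They are used exactly as printed
  (the recovery harness only requires the generating model to be
  refittable), with no reinterpretation.
* Compositional cosinor results are per-taxon marginal statements; no
  log-ratio framework is provided.
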