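---
title: "Methods: the free-response kappa and its interval estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the free-response kappa and its interval estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freekappa)
```

## The model

Two raters independently assess the same material and report only positive
findings; an adjudicator matches the two reports, so every distinct finding
ends up classified as concordant-positive ($d$), positive for rater 1 only
($c$), or positive for rater 2 only ($b$).  The double-negative cell $a$ of
the usual 2×2 agreement table is unobserved, and in imaging applications it
is effectively unbounded: the number of anatomical structures that could
have carried a lesion is far larger than the number that did.

Cohen's kappa on the full table can be written in closed form as

$$K = \frac{2(ad - bc)}{(b + c)N + 2(ad - bc)}, \qquad N = a+b+c+d.$$

Its partial derivative in $a$ is strictly positive whenever $b + c \ge 1$
and $d \ge 1$, so $K$ increases monotonically in the assumed number of
double negatives and converges to a finite limit, the **free-response
kappa**

$$K_{FR} = \frac{2d}{b + c + 2d}.$$

`kappa_curve()` traces $K$ against $a$; `free_response_kappa()` evaluates
the limit.  Two consequences shape the package's behaviour:

* $K_{FR}$ is an *upper bound* on chance-corrected agreement over all
  finite completions of the table — the property tests assert
  $K(a) < K_{FR}$ for every finite $a$ and $|K(10^{10}) - K_{FR}| <
  10^{-6}$.
* $K_{FR}$ is interpretable on its own terms: the proportion of confirmed
  positive individual ratings ($2d$) among all positive individual ratings
  ($b + c + 2d$), so the usual kappa benchmarks carry over.

### Clustering

When patients contribute several findings, the pooled estimate is exactly a
weighted mean of per-patient kappas,
$K_{FR} = \sum_k \nu_k \, 2d_k/(b_k + c_k + 2d_k)$ with
$\nu_k = (b_k + c_k + 2d_k)/(b + c + 2d)$.  `cluster_decomposition()`
returns the weights and per-patient values; the identity is asserted to
$10^{-12}$ on random cluster configurations.  All-negative patients have
weight zero — the point estimate ignores them — but they stay in the
bootstrap's resampling frame because they are part of the sampling design.
The decomposition holds for any partition, so the same machinery compares
agreement across subgroups.

## Interval estimation

Three procedures assume mutually independent positive pairs; the fourth
handles clustering.

**Logit delta method.**  On the logit scale the delta-method variance is
$\mathrm{Var}(\mathrm{logit}\,K_{FR}) = (b+c+d)/((b+c)\,d)$; a normal
interval is formed there and back-transformed, so the bounds are always
inside $(0,1)$.  The method is undefined when $d = 0$ or $b + c = 0$
(logit of 0 or 1); `logit_variance()` signals a classed error rather than
returning an infinity.

**Binomial-proportion routes.**  $K_{FR} = 2p/(1+p)$ is a monotone
transform of the congruent-pair proportion $p = d/(b+c+d)$, so any binomial
interval for $p$ with $x = d$ successes in $n = b+c+d$ trials maps
endpoint-by-endpoint to the kappa scale (`p_interval_to_kappa()`).  The
package implements Agresti–Coull (add $z^2/2$ successes and failures;
bounds clipped to $[0,1]$ before transformation, since the method can
overshoot at the extremes) and Clopper–Pearson (exact beta quantiles;
lower bound exactly 0 at $d = 0$, upper exactly 1 at $d = n$).  Both are
defined for degenerate samples, unlike the logit method.  The critical
value is always `qnorm((1 + level)/2)`, never a hard-coded 1.96, so any
confidence level works.

**Cluster bootstrap.**  For clustered data the closed-form variance is
biased, so `cluster_bootstrap_ci()` resamples *patients* with replacement
(the patient is the random factor; findings within a patient travel
together), pools each resample and recomputes $K_{FR}$.  The default
interval is the percentile interval at 10,000 replicates — the simplest
defensible flavour — with bias-corrected-and-accelerated (BCa) bounds
available via `type = "bca"` (jackknife over patients for the acceleration
constant).  Replicates whose resample contains no positive finding are
dropped and counted; a warning fires when more than 1% are dropped and an
error when none remain.  A seed is required for reproducibility; when
omitted, one is drawn from R's RNG and reported so the run can be repeated.

## The coverage simulation

`run_cell()`/`run_table()` study the three independent-data intervals under
their own sampling model: fix a true kappa $K$, invert the transform to
$p = K/(2-K)$, draw $d \sim \mathrm{Binomial}(n, p)$, and set
$b + c = n - d$.  The split of the discordant total into $b$ and $c$ is
statistically inert — every implemented statistic depends on $b + c$ only —
and is fixed at $b = n - d$, $c = 0$.  Per replicate the observed kappa is
$2d/(n+d)$ and each requested interval is scored for covering $K$ and for
its width on the kappa scale.

Degenerate samples ($d = 0$ or $d = n$) leave the logit interval undefined;
they are scored as non-coverage for that method and excluded from its mean
width, while Agresti–Coull and Clopper–Pearson use every replicate.  The
logit method's coverage restricted to non-degenerate samples is reported
alongside, since the unconditional figure mixes two failure modes.  The
probability of a degenerate sample has the closed form $(1-p)^n + p^n$,
which the tests use as an oracle against the simulated fraction.

Because $K = 2p/(1+p)$ is concave, Jensen's inequality makes the mean
observed kappa fall below the target, noticeably at small $n$ — at $n=20$,
$K = 0.3$ the mean is near 0.291 — and the gap shrinks as $n$ grows; this
is asserted as a property.

The default grid crosses $n \in \{20, 50, 100, 200\}$ with
$K \in \{0.3, 0.5, 0.7, 0.9\}$ at the 95% level and 50,000 replicates per
cell.  Per-cell seeds derive from the master seed by a stable integer hash
of $(n, 1000K)$, so cells are reproducible independently of grid order.
The routine test suite runs reduced grids (1,000–5,000 replicates) with
correspondingly wide tolerances; the single cell checked against published
behaviour ($n = 20$, $K = 0.3$) runs at the full 50,000 replicates, where
Monte-Carlo error on a coverage near 0.95 is about $\pm 0.003$ (3 SE).

## The generative study model

`generate_study()` simulates the kind of data the estimator is meant for:
each of `n_patients` carries $\mathrm{Poisson}(\texttt{lesion\_rate})$ true
lesions; rater $i$ detects each lesion independently with per-lesion
sensitivity $s_i$; lesions missed by both raters are never recorded (the
paradigm has no double negatives); and each rater adds
$\mathrm{Poisson}(\texttt{fp}_i)$ false-positive findings per patient.

Defaults used throughout the tests — lesion rate 3 per patient,
sensitivities 0.8, no false positives — mirror a realistic multi-lesion
imaging study of moderately good raters.  Under this model a lesion seen by
at least one rater is seen by both with probability
$p = s_1 s_2/(s_1 + s_2 - s_1 s_2)$, and the transform collapses to the
harmonic-mean form

$$K_{FR} \rightarrow \frac{2 s_1 s_2}{s_1 + s_2},$$

which equals $s$ when $s_1 = s_2 = s$.  This gives exact targets for
parameter-recovery tests (0.8 at equal sensitivities 0.8; 0.72 at
$(0.9, 0.6)$) and a known truth for the bootstrap coverage experiment
(500 generated studies of 200 patients; nominal 95% intervals from 1,000
bootstrap replicates are required to cover 0.8 between 93% and 97% of the
time).

Two deliberate simplifications: false positives never match between raters
(true matching of spurious findings depends on the rating protocol and
would only lower agreement further), and the adjudicator who pairs the two
raters' findings is treated as error-free.  Real studies meet neither
assumption perfectly, so passing tests validate the estimator's arithmetic
and sampling behaviour, not the adjudication step of any particular study.

## Numerical and design notes

* Counts are validated as nonnegative integers and never rounded: a
  non-integer tally is an input error, not data.
* `cohen_kappa()` is defined whenever its denominator is nonzero — perfect
  agreement ($b = c = 0$, $a, d > 0$) cleanly returns 1 — and signals a
  classed error only when the denominator vanishes exactly.
  `free_response_kappa()` returns 0 at $d = 0$ and 1 at $b + c = 0$; only
  the all-zero case errors.
* The identity $K_{FR} = 2p/(1+p)$ is exact in real arithmetic; the two
  floating-point evaluation orders can differ in the final ulp, so tests
  compare at $10^{-14}$ relative tolerance.
* `kappa_curve()` interprets `a_values` as study-wide totals; the
  per-patient convention common in imaging (sites per patient × number of
  patients, minus the observed positives) is provided via
  `sites_per_patient`/`n_patients` and in the CLI's `--per-patient` flag.
* Display rounds to 3 decimals, matching reporting practice; full precision
  is retained internally and in CSV/JSON output.

## The embedded case study

`case_study_fixtures()` carries the matched-rating tables of a published
study of 84 paediatric whole-body MRIs (249 distinct lesions in 58
children; pooled counts $b = 19$, $c = 57$, $d = 173$), including the three
region-of-interest aggregations (patient level; 9 regions per patient; 95
regions per patient).  The tests reproduce every kappa those tables imply.
The study's own clustered bootstrap intervals are *not* reproduced: they
depend on the unpublished per-patient composition of the 58 positive
children, which the pooled tables do not determine.

## Known limitations

* Two raters, dichotomous ratings only; multi-rater and ordinal extensions
  are out of scope.
* The closed-form variance assumes independent positive pairs; for
  clustered data only the bootstrap is offered.
* The free-response kappa is an upper bound on chance-corrected agreement;
  when the universe of potential findings is genuinely small, complete the
  table with the known $a$ and use `cohen_kappa()` instead.
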