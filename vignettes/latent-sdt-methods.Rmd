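---
title: "Latent item and person measures from m-AFC responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent item and person measures from m-AFC responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtlatent)
```

## The internal-response model

An m-alternative forced-choice (m-AFC) trial offers `m >= 2` response
alternatives, exactly one of which the experimenter has defined as correct.
The SDT account is mechanistic: each alternative elicits an internal
response on a common decision axis, and the person chooses whichever
alternative produced the largest one. With the correct alternative drawing
`x_C ~ N(mu2, sigma)` and each incorrect alternative an independent
`x_I ~ N(mu1, sigma)`, only the separation in pooled standard-deviation
units matters, so without loss of generality we set `mu1 = 0`, `sigma = 1`
and write `d'` for `mu2`. The probability of a correct choice is

$$p(C) \;=\; L_m(d') \;=\; \int_{-\infty}^{\infty} \varphi(x - d')\,
\Phi(x)^{m-1}\,dx ,$$

the chance that the correct draw beats the maximum of `m - 1` standard
normals. Two structural facts drive everything downstream:

* `L_m(0) = 1/m` exactly — chance performance always sits at `d' = 0`,
  for every `m`, with no guessing parameter needed;
* `L_2(d') = Phi(d'/sqrt(2))` in closed form, which provides a free
  analytic oracle for the quadrature.

To place *items* on this axis we follow the IRT strategy: item `h` gets a
latent measure `b_h`, person `i` an ability `theta_i`, and the response
probability is `L_m(theta_i - b_h)`. Negative `b` means an easier item. The
model is criterion-independent by construction (each alternative has its
own "detector"; the maximum decides); criterion-dependent yes–no variants
of SDT are out of scope.

## Numerical evaluation

`pc_mafc()` evaluates the integral with a fixed 64-point Gauss–Hermite rule
after centring the Gaussian factor at `d'` (substituting
`x = d' + sqrt(2) t` turns the integrand into `e^{-t^2}` times a bounded,
monotone, analytic factor). A fixed rule was chosen over adaptive
quadrature because it is deterministic, vectorises across parameter values,
and converges spectrally for this integrand; the test suite verifies
agreement with `stats::integrate` below `1e-9` over `d' ∈ [-6, 6]`,
`m ≤ 8`, and with the `m = 2` closed form below `1e-8`. The inverse
`dprime_mafc()` brackets the root on `[-10, 10]` (doubling the bracket for
extreme probabilities) and polishes with `stats::uniroot` to a probability
residual below `1e-10`; round-trips are accurate to `1e-6` in `d'`. These
tolerances are two to three orders tighter than any quantity the package
reports.

A generalised variant of the integrand (point-mass correct-response
density, normal or logistic alternative CDF) exists for diagnostics: by the
sifting property of the Dirac delta the integral collapses to
`F(d')^{m-1}`, and with the logistic `F` at `m = 2` this is exactly the
dichotomous Rasch model — the sense in which Rasch is a special case of
SDT. The tests verify that identity to `1e-12`.

## Two-stage estimation

A full joint MLE over hundreds of persons and items is computationally
unattractive; the package's primary estimator mirrors how IRT practice
anchors the scale to the sample:

1. **Item calibration** (`calibrate_items()`). Treat all responses to item
   `h` as repeated measures from one "average" person fixed at
   `theta = 0`. Then `p_h = L_m(-b_h)` and the observed proportion correct
   inverts directly to `b_h`. Binomial 95% confidence intervals (Wilson
   score method, whose endpoints never touch 0 or 1) are mapped through the
   same inverse; the order of the endpoints flips because `b = -d'`.
2. **Person MLE** (`fit_person()`, `fit_all_persons()`). Given the item
   measures, each `theta_i` is a one-parameter MLE of
   `sum_m [ sum_{b in A_im} log L_m(theta - b) + sum_{b in B_im} log(1 - L_m(theta - b)) ]`,
   maximised by golden-section/parabolic search (`stats::optimize`) on
   `[-10, 10]` d′ to `1e-6`. Standard errors are
   `(-l''(theta_hat))^{-1/2}` with the curvature from a central second
   difference (step `1e-3` d′) — the observed-information reading of
   "reciprocal of the square root of the Hessian".

**Degenerate scores.** An item answered correctly by everyone (or no one)
has no finite calibrated measure; the package substitutes
`(n_c + 0.5)/(n + 1)` and sets `degenerate_flag`, which keeps the measure
finite and ordered correctly relative to neighbouring items. A person with
all-correct (or all-incorrect) responses has a likelihood monotone in
`theta`; the estimate is clamped to the ±10 d′ search bound, flagged, and
given no standard error. These policies are this package's choices — the
problem is inherent to the design, and analogous exclusion or extrapolation
rules are standard Rasch practice.

## The alternating refinement (`method = "em"`)

Initialised at the two-stage solution, the refinement alternates exact 1-D
coordinate maximisations: each item measure given the current person
measures, then each person measure given the current item measures, until
the largest absolute parameter change falls below `tol` (default `1e-4` d′,
below reporting precision; `max_iter` 100, with non-convergence reported in
the object rather than thrown). Because the likelihood depends only on the
differences `theta - b`, it is invariant under a common translation, and an
explicit anchor is required for identifiability: after every cycle the mean
person measure is subtracted from all `theta` and all `b`, keeping the
average person at `theta = 0` — the same convention the initialisation
uses. Letting the origin drift would converge equally well; re-anchoring
was chosen so that approx and EM fits live on the same scale. Each
half-step maximises the joint likelihood in a block of coordinates, so the
total log-likelihood is non-decreasing along the recorded trace (the tests
allow `1e-9` slack for the anchoring arithmetic). After refinement the
Wilson mapping no longer applies (it assumes every respondent at
`theta = 0`), so EM item intervals are Wald intervals from the item-step
observed information.

**When the two estimators differ.** If persons were literally identical the
two-stage solution would be an exact fixed point of the refinement (the
tests construct this case). Under real heterogeneity the average-person
step evaluates `E_theta[L_m(theta - b)]`, which is flatter than
`L_m(bar(theta) - b)`, so the calibrated item scale — and with it the
person scale — is mildly compressed. At the heterogeneity of the default
simulator (person SD 0.8 d′) the compression is roughly 10%: enough that a
simulated paired condition effect is recovered unbiasedly by the EM person
measures but attenuated by the two-stage ones. Both estimators rank items
and persons near-identically (r² > 0.99 on item measures in the acceptance
checks); the refinement matters when the absolute d′ scale does.

## The Rasch comparator

`rasch_fit()` implements the dichotomous Rasch model
`p(R = 1) = logistic(theta - b)` by joint maximum likelihood: alternating
damped Newton blocks (persons, then items), each step-halved until the
likelihood does not decrease, anchored by convention at mean item measure
zero. JMLE was chosen over conditional or marginal ML because it mirrors
the alternating structure of the SDT refinement and respects the mean-item
anchoring convention; no bias correction is applied. Persons and items with
extreme raw scores are excluded (iteratively) before estimation and listed
in the result.

`compare_rasch_sdt()` regresses Rasch logits on SDT d′ item measures by
ordinary least squares within each `m` group ("best-fitting lines", read as
OLS). Within an `m` group the relation is close to linear — for pure 2-AFC
data at moderate spread the slope is near the classical logit-per-probit
factor divided by the 2-AFC compression, `1.7/sqrt(2) ≈ 1.202` — but the
intercepts must differ across `m`, because SDT anchors chance at `d' = 0`
for every `m` while the Rasch logit of chance performance depends on `m`.
That intercept separation is the practical argument for the SDT scale when
a battery mixes values of `m`.

## The simulator and what it does (not) emulate

`simulate_truth()` + `simulate_responses()` generate studies shaped like
the motivating clinical design: `n_persons = 100` (each of 50 subjects
contributing one "person" per condition of a paired intervention),
`n_items = 192` with alternatives cycling `2, 3, 3` (one 2-AFC task for
every two 3-AFC tasks), items partitioned into 8 blocks, and each subject
randomised to a block parity so that the treatment person answers one half
of the battery and the control person the complementary half — disjoint
person groups thus respond to disjoint item sets, as block-randomised
magnification designs produce. Ability is `a_s ~ N(0, 0.8)` d′ with the
treatment person at `a_s + 0.552`; item measures are `b ~ N(-1, 1)` d′,
i.e. items mostly easier than the average person, the regime clinical
batteries aim for. The 0.552 default is the effect size the package's
acceptance checks recover; the truth distributions are defaults chosen once
to echo the ranges such studies report, not claims about any dataset.

Two response generators are provided and are equal in distribution:
`"model"` draws Bernoulli scores at `L_m(theta - b)`, while
`"mechanistic"` simulates the internal responses themselves (one
`N(theta - b, 1)` draw against the maximum of `m - 1` standard normals).
Their agreement is itself a test of the quadrature, and `mc_pc()` exposes
the mechanistic rate directly as a Monte-Carlo oracle. All generators take
explicit integer seeds; identical seeds give bit-identical tables.

The simulator emulates design structure, not psychology: no learning or
fatigue across blocks, no criterion effects, no item-by-person interaction
(a single `theta - b` difference governs each trial), no response times,
and no uncertainty about the defined truth state. Passing recovery tests on
these data therefore validates the estimation machinery under the model's
own assumptions — it cannot certify the model against real observers.

## Problem sizes and reproducibility of the checks

The package's acceptance checks run the full pipeline on a 200-person ×
192-item complete-design study (38,400 responses; 100 subject pairs), a
scale at which the two-stage fit takes a few seconds and the refinement
under a minute: truth-versus-estimate correlations (r > 0.95 for items,
r > 0.90 for persons at the fixed seed), recovery of the 0.552 d′ paired
effect within its 95% CI, item-measure agreement between the two estimators
(r² > 0.99), and the likelihood/anchoring contract of the refinement.
Desk-checkable calibration values (e.g. 47 of 49 correct on a 2-AFC item
mapping to `b = -2.463`) are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The d′ unit is model-relative: if a criterion-dependent process better
  describes a task, measures from different tasks are not automatically
  commensurate.
* The two-stage estimator compresses the scale under strong person
  heterogeneity (see above); use `method = "em"` when absolute effect
  sizes matter.
* Degenerate (perfect-score) items and persons receive flagged, bounded
  estimates rather than being dropped; downstream analyses should respect
  `degenerate_flag`.
* JMLE Rasch estimates carry the usual small multiplicative bias with few
  items; the comparator is meant for the structural comparison, not as a
  production Rasch tool.
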