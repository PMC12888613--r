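---
title: "Modelling how people learn others' personality traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling how people learn others' personality traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitlearn)
```

## The task and the modelling question

In the trait-learning task, a participant meets six unfamiliar "profiles" —
three with trait patterns typical of borderline personality disorder (BPD)
and three control-like — and, over 40 trials per profile, predicts how the
profile rated itself on each of 40 Big Five trait adjectives (1–8 scale).
After every prediction the profile's true self-rating is shown. The
modelling question is *how* predictions improve: do people keep fixed
default expectations, update broad factor-level beliefs, or maintain
trait-level expectations that generalise feedback through trait–trait
similarity? And do people with and without BPD differ in these mechanisms
when learning about in-group versus out-group profiles?

All model-internal values live on a *favorability* scale: ratings on
negative traits are reverse-coded, r → (scale_min + scale_max) − r, so that
"higher = more favorable" holds for every trait. A factor-level expectation
over raw mixed-valence ratings would be incoherent; reverse coding first is
therefore a structural choice, not merely a convention, and raw ratings are
restored only at the I/O boundary. Absolute prediction errors are unaffected
(|F − P| is invariant when both arguments are reverse-coded).

## The model family

Eight base models cross three generative families with three reference-point
regimes:

| family | state | update after feedback F on trait j |
|---|---|---|
| no learning | none | none — predict RP(trait) forever |
| coarse | one value per Big Five factor | V_f ← V_f + α (F − V_f), f = factor(j) |
| fine | one value per trait | V_i ← V_i + α s(i, j) (F − V_j), all i |

Reference points RP are either population trait norms or the participant's
own self-ratings (collected after the learning phase, as in the task). The
two no-learning models use them directly; learning models may blend one in
at prediction time, P̂ = w·RP + (1 − w)·V, with weight w ∈ [0, 1] — we read
"balancing learning against a reference point" as a prediction-time convex
mixture; an initialisation-only variant (RP as V0) can be emulated by the
estimated-V0 models. Setting w = 1 (or α = 0 with V0 at the reference point)
collapses a learning model onto its no-learning counterpart, which the test
suite exploits as an exact oracle.

Responses are modelled as Gaussian around P̂ with SD σ (a free parameter per
participant). The likelihood is a plain, untruncated normal: the comparison
metric downstream is squared error, which the Gaussian matches, and the
discreteness and bounds of the response scale are handled in *simulation*
(noise added, rounded, clipped) but deliberately ignored in *evaluation* to
keep the likelihood smooth. Trials flagged invalid (items a participant did
not understand) contribute zero log-likelihood.

The latent state resets at every profile change: each profile is a new
person, so expectations restart at V0. In the base models V0 is the scale
midpoint (4.5); the extended `_v0` variants estimate a per-trait V0 vector
at the condition level, shrunk toward a condition mean (see below). Six
learning models therefore have estimated-V0 twins, giving a 14-entry
registry with the eight base models as the canonical comparison set.

The fine models' similarity matrix s(i, j) is not printed anywhere as data;
the package computes it from a reference rating table as trait–trait Pearson
correlations on reverse-coded ratings (`empirical_similarity()`), with
optional shrinkage toward zero and optional clipping of negative entries.
Correlations are naturally signed and we keep the sign by default:
anti-correlated traits update in opposite directions, which is the
behaviourally sensible generalisation. The package ships a synthetic
reference generator (`synthetic_reference()`) that draws raters from a
one-latent-score-per-factor model, yielding a realistic within-factor block
structure; the resulting matrix is labelled synthetic and any externally
derived matrix can be supplied instead. Under the idealised *block*
similarity (1 within factor, 0 across) with factor-tied V0, the fine model
reproduces the coarse model's trajectories exactly — a property the test
suite verifies to 1e-10, and a useful sanity anchor for the fine update.

## Hierarchical estimation

Each condition (participant group × profile type) is fitted independently —
four datasets, matching the design in which every pairing is of scientific
interest; no parameters are shared across conditions. Within a condition,
participant-level parameters sit on unconstrained scales (logit α, logit w,
log σ) with

* z_s ~ Normal(μ, τ) per parameter,
* μ ~ Normal(0, 1), τ ~ HalfNormal(1),
* estimated-V0 variants: v0_i ~ Normal(v0_bar, τ_v0), v0_bar ~
  Normal(midpoint, 2) in rating units, τ_v0 ~ HalfNormal(1).

These priors are weakly informative on the natural scales (the implied
prior median for α is 0.5 with mass over the whole unit interval; for σ,
median 1 rating point). They are proper, and with no informative trials the
sampler returns them unchanged — a prior-predictive check in the suite.

The estimated V0 is a *condition-level* vector: one initial-expectation
profile shared by the condition's participants, with per-trait shrinkage
toward the condition mean. A per-participant per-trait V0 (40 × N extra
parameters) is not identifiable at this scale, and the scientific quantity
of interest is the condition-average V0 anyway ("how favourable do people
in this condition expect this kind of profile to be, before any
feedback?").

Sampling is adaptive random-walk Metropolis-within-Gibbs with the
teacher-forced trajectory likelihood compiled in C++: per-participant
proposals with Robbins–Monro scale adaptation during warmup, conjugate
Gibbs draws for each μ, random-walk steps on each log τ *plus an
interweaved non-centered step* (hold the standardised deviations fixed,
propose τ, rescale) that breaks the funnel coupling between group spread
and participant parameters. The V0 block additionally gets a translation
move (shift the whole vector and its mean together), because the
per-coordinate walk moves the average V0 only diffusively. Convergence is
assessed with split-chain potential scale reduction and effective sample
size via coda; the default thresholds (R̂ < 1.01, ESS ≥ 400) are strict for
desk-scale chain lengths, and a fit missing them is returned *flagged*,
never silently accepted. "Divergent transitions" have no analogue in
random-walk MH; acceptance rates are recorded instead.

Posterior contrasts between conditions sample the difference distribution
of the group-level draws and summarise it by its mean and the 95% shortest
probability interval (SPI): the narrowest contiguous window containing 95%
of sorted draws, i.e. the highest-density interval for unimodal posteriors.
A difference is called credible when the SPI excludes zero.

## Model comparison

Predictive fit is leave-one-participant-out cross-validation: for each fold
the model is fitted to all other participants of the condition and the
held-out participant's trials are scored by mean squared error between
their observed predictions and the model's teacher-forced expected ratings.
The held-out participant contributes no fitted parameters; self-reference
models do use the held-out participant's *own* self-ratings, which are task
inputs, not estimates. Two fold-fitting modes exist: `fast` (default in
tests) fits one pooled parameter set per training fold by penalised maximum
likelihood with σ profiled out analytically (the Gaussian MLE is the RMS
residual), so alpha-only models reduce to a 1-d search; `accuracy` runs the
full hierarchical sampler per fold and predicts with posterior means.

Models are compared pairwise by the 2×SE rule: ΔMSE = mean of the paired
per-participant score differences, SE = sd/√n, credible iff |ΔMSE| > 2·SE —
roughly the conventional frequentist boundary, applied without multiplicity
correction. Rankings report the best model and its equivalence set (every
model not credibly worse), with exact MSE ties broken by fewer free
parameter blocks, then lexicographically. A naive baseline — predict the
training participants' grand mean rating everywhere — anchors the MSE
scale; any model with learnable structure should beat it.

## The synthetic study

The generator reproduces the design features the analysis relies on:

* **Lexicon**: 40 traits, 7–9 per factor, 20 positive / 20 negative, 1–8
  scale (all configurable; a strict mode enforces the canonical design).
* **Profiles**: per-class per-trait means with the control-like class more
  favourable. Defaults place the classes at the groups' observed
  valence-specific self-rating means (positive/negative 6.28/2.84
  control-like, 5.79/3.89 BPD-like — a favorability gap of ≈ 0.77 rating
  points), item SD 1.3. Candidates are screened by the typicality rule —
  at most six traits deviating more than one class SD from the class mean —
  and resampled until they pass. Because screened exemplars are by
  construction less dispersed than their population, candidates are drawn
  at 0.75 of the class SD; at the full SD the screen would reject ~99% of
  draws, which tells you it describes *selected* profiles, not random ones.
* **Cohort**: 30 BPD-like and 31 control-like participants; parameters drawn
  logit-/log-normally around natural-scale medians (defaults α 0.3, w 0.4,
  σ 0.7 rating points — mid-range learning with realistic response noise);
  integer self-ratings drawn from the group's valence-specific means, so
  the BPD-like group rates itself less favourably.
* **Sessions**: profiles in the fixed order CON, BPD, CON, BPD, BPD, CON;
  trait order reshuffled per participant and block from per-participant
  substreams of one master seed; responses generated by each participant's
  own model (expected rating + noise, rounded, clipped); optional emulation
  of item exclusions (0–2 invalid trait words per participant, off by
  default). The three participants of the original sample with a deviating
  profile order are not emulated.

What the generator does *not* emulate: real trait semantics (labels are
placeholders), response times, order effects within the self-rating phase,
and any dependence of σ or α on trial content. Passing recovery tests on
these data therefore shows that the estimation and comparison machinery is
correct and well-calibrated *under the generative assumptions*, not that
the winning model is true of people.

## Numerical choices and degenerate inputs

* Teacher forcing everywhere: states update on observed feedback, so the
  likelihood factorises over trials and is exactly additive over blocks.
* Zero-variance trait columns in a similarity reference table yield
  undefined correlations; their generalization weights are set to 0 with a
  warning.
* σ is bounded away from zero in pooled fits (floor 1e-3 on the profiled
  RMS) to survive pathological zero-residual folds.
* `shortest_interval()` requires ≥ 100 draws; on constant draws it returns
  a zero-width interval rather than failing.
* Single-participant data cannot identify a hierarchical spread;
  `fit_hierarchical()` refuses them and points to `fit_map_subject()`
  (multi-start penalised optimisation, ≥ 5 seeded starts).
* LOGO-CV folds whose fit fails are dropped with a warning and the overall
  MSE is reported over the successful folds.

## Problem sizes

The package's own test-suite simulations use reduced but honest sizes:
parameter recovery runs ten replicates of 16 participants × 240 trials with
two chains of 400 + 400 draws (interval coverage of the condition-level
learning rate and true-versus-recovered correlation ≥ 0.7); model recovery
runs ten replicates of 12 participants scoring all eight models plus the
baseline. The analysis drivers run the full 61-participant synthetic study.
These sizes were chosen as the smallest at which the checks are
statistically meaningful; all of them scale up by changing one argument.

## Known limitations

* Trend inference uses OLS slopes with a cluster bootstrap over
  participants — a transparent stand-in that is *not* equivalent to
  mixed-model inference with Satterthwaite degrees of freedom; at few
  clusters the bootstrap intervals are mildly anticonservative.
* The exact functional form of the original reference-point mechanism
  (mixture vs initialisation) and the provenance of the published
  similarity structure are not recoverable from the task description alone;
  both choices here are explicit and switchable.
* The Gaussian response likelihood ignores the discreteness and bounds of
  the 8-point scale; with σ below ~0.3 the rounding error becomes a visible
  fraction of σ and recovered noise parameters inflate accordingly.
* Conditions are fitted independently; a joint model sharing participant
  parameters across profile types is out of scope.
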