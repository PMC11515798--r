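---
title: "Topic-model dysbiosis scoring and causal mediation in periodontal trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-model dysbiosis scoring and causal mediation in periodontal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periotopics)
```

## The scientific problem

Periodontitis is driven by a dysbiotic shift of the subgingival microbiome
toward pathobiont dominance. Adjunctive systemic antibiotics
(amoxicillin/metronidazole) after mechanical periodontal therapy improve
clinical outcomes, but the mechanism is debated: does the antibiotic act on
attachment loss directly, or through the microbial community it reshapes?
`periotopics` implements an analysis chain that makes this question
answerable on taxa count tables from a randomized two-arm trial: a latent
community model that turns counts into a one-dimensional dysbiosis score, a
trajectory clustering that turns score time courses into an ordinal
microbial response category, regression models linking score and category
to site-count outcomes, and a DAG-informed difference-method mediation
analysis.

## The latent community model

For sample $d$ with taxon counts $w$, latent Dirichlet allocation assumes
each sequencing read arises from one of $K$ latent communities ("topics"):
$\phi_k \sim \mathrm{Dir}(\eta)$ over taxa, $\theta_d \sim \mathrm{Dir}(\alpha)$
over topics, and each read's taxon is drawn from $\phi_{z}$ with
$z \sim \theta_d$. We fix $K = 2$: the model is then interpretable as a
normobiotic and a dysbiotic community, and the **dysbiosis score** of a
sample is its loading on the dysbiotic topic — exactly the relative
proportion of the dysbiotic to the normobiotic community.

Inference is collapsed Gibbs sampling over token-level assignments
(`fit_topics()`, C++ backend), with point estimates the posterior means of
the smoothed proportions $(n_{dk}+\alpha)/(n_d+K\alpha)$ and
$(n_{kw}+\eta)/(n_k+V\eta)$ over post-burn-in sweeps. Collapsed Gibbs was
chosen over variational EM because its posterior is directly checkable
against exhaustive enumeration: on corpora with at most 8 tokens the test
suite enumerates all $K^N$ assignment vectors, weights them by the
collapsed Dirichlet-multinomial joint, and requires the sampler's
document-topic means to agree within 0.02. A variational backend could be
added behind the same interface.

Numerical choices:

* **Hyperparameters.** $\alpha = 50/K$, $\eta = 0.1$, common topic-model
  practice. Note $\alpha = 25$ is a strong smoother for tiny documents;
  real 16S libraries (about 20,000 reads) overwhelm it completely.
* **Determinism and exchangeability.** The sampler is seeded, and samples
  and taxa are canonicalized to sorted-id order before sampling, so fits
  are exactly invariant to row/column permutations of the input.
* **Label switching.** Topic indices are arbitrary across seeds; all
  downstream semantics go through `label_topics()`, which labels as
  dysbiotic the topic with strictly greater topic-word mass on a
  pathobiont reference list (signature species of periodontal dysbiosis);
  a margin below $10^{-6}$ is an error instructing manual labeling rather
  than a silent guess. Reference lists are arguments and can be overridden
  — useful because published normobiotic driver lists sometimes carry
  idiosyncratic labels.
* **Convergence.** The collapsed joint log-likelihood is traced each
  sweep; a fit whose trace still trends upward at the end (drift over the
  last tenth exceeding both the trace noise and 1% of the total climb) is
  flagged with a warning, not an error.
* **Fold-in.** New samples are scored with topic-word distributions held
  fixed (Gibbs over the new tokens only), which is how external validation
  cohorts are projected onto a fitted model without refitting; taxa
  missing from the fitted vocabulary are dropped with a logged fraction.

## Response patterns

Per-subject trajectories of the dysbiosis score over visits (baseline
required; missing later visits imputed by last observation carried forward,
or subjects dropped) are clustered with agglomerative hierarchical
clustering, Ward linkage on Euclidean distance, cut at $k = 4$ — the four
named patterns. Ward/Euclidean is the standard choice for recovering
trajectory shapes; the linkage is configurable. Clusters are then mapped to
ordinal categories from their mean trajectory relative to a normobiosis cut
of 0.5 (the score is a two-community proportion, so 0.5 is the natural
"which community dominates" boundary, and it is configurable):

| mean trajectory (baseline, first post-treatment, final) | category |
|---|---|
| dysbiotic at all three anchors | 0 non-responder |
| normobiotic early, normobiotic at the end | 3 responder |
| normobiotic early, dysbiotic again at the end | 2 short-term responder |
| anything else | 1 indifferent |

Two clusters may map to the same name (a warning, not an error): categories
are labels of clusters, not forced to be unique. One structural point is
worth recording: under these rules an "indifferent" cluster mean must end
below the cut while a "short-term responder" mean ends above it, so mean
dysbiosis at the final visit cannot be strictly monotone across all four
categories — the ordinality of the categories is about clinical outcome,
not about final-visit dysbiosis. The generator therefore enforces
endpoint monotonicity (non-responder highest, responder lowest at the final
visit) rather than full monotonicity.

## Clinical models

* `median_dichotomize()` flags subjects strictly below the within-visit
  median percentage (ties go to "above": *below median* read literally).
* `treat_to_target()` is the boundary-inclusive endpoint
  "≤ 4 sites with PPD ≥ 5 mm".
* `fit_logistic()` reports the association of a binary indicator with the
  normobiotic proportion **per 0.1 increase** — the exposure unit is
  stated prominently because odds ratios per full unit of a proportion are
  uninterpretable; rescale by powering if needed.
* `fit_ordinal_mediator()` is the proportional-odds model of the response
  category on treatment, the baseline-normobiotic indicator, and age band,
  sex, smoking. A score-test-style heuristic (per-threshold binary logits,
  equality test per predictor) flags violations of proportionality.
* `fit_nb_outcome()` is NB2 with log link and log total sites as offset,
  i.e. a model of the per-site rate of further attachment loss ≥ 1.3 mm.
  The response category enters as ordinal numeric 0–3 by default (constant
  per-category rate ratio, matching "per increase in category"
  interpretation); a dummy-coded option exists for prediction grids with
  free category steps. Published prediction tables of this design do not
  show exactly constant category steps, so the dummy option is the one to
  use when mimicking them cell by cell.
* `prediction_grid()` evaluates sites × exp(linear predictor) over a
  covariate grid; the total site count is an explicit argument (reported
  reference values in this literature vary between 126 and 146 sites per
  patient, and the grid makes no attempt to pick one for you).

### Small-sample bias and its correction

Maximum-likelihood ordinal logistic regression overestimates odds ratios at
trial scale: at $n = 163$ with eight parameters and large true effects the
geometric-mean inflation is 5–10% on the OR scale. Because the package's
recovery simulations compare geometric means across hundreds of refits
against the configured truth, `fit_ordinal_mediator(bias_correct = TRUE)`
offers a parametric-bootstrap correction: simulate `n_boot = 30` datasets
from the fitted model, measure the mean coefficient inflation, and subtract
it. The correction is centered at each dataset's own fit (never at any
external truth) and slightly overcorrects when the truth exceeds the
estimate, an expected second-order effect. NB coefficient estimates show no
measurable bias at this scale and are used uncorrected.

## The causal mediation analysis

The study DAG (`build_study_dag()`) encodes: randomized treatment (no
incoming edges) affecting outcome directly and via the response pattern;
baseline characteristics affecting the response pattern; age, sex and
smoking affecting both the response pattern and the outcome.
`backdoor_adjustment_sets()` enumerates minimal adjustment sets by explicit
path enumeration plus the d-separation blocking rule — these graphs are
small, so no algorithmic sophistication is warranted, and the test suite
checks the implementation against an independent moral-ancestral-graph
oracle over every conditioning subset.

For the effect of treatment on attachment loss the minimal set is empty
(randomization), so the **total-effect** model is NB with treatment only.
The **direct-effect** model adds the mediator and its minimal
mediator-outcome adjustment set: response category, age, sex, smoking.
Both are fitted as Bayesian NB regressions (`fit_bayesian_nb()`, JAGS):
normal(0, 2.5) priors on log-rate coefficients, half-normal(5) on the NB
size (the inverse-dispersion), 4 chains; the fit fails loudly if any
split R-hat exceeds 1.05. The difference-method **indirect effect** is
$c - c'$ on the log-rate scale, computed from posterior draws of the two
independently fitted models. Independent fits admit no canonical draw
pairing; draws are paired uniformly at random under a fixed seed, which
leaves the distribution of the difference (the convolution) unchanged.
Point estimates are posterior medians (robust to the skew of rate-ratio
posteriors); intervals are equal-tailed 95% credible intervals. When the
indirect interval is wide, the supported claim is the presence, not the
magnitude, of mediation — the consistency flag in `mediation_difference()`
records when median arithmetic and the ratio of medians disagree by more
than 10%, which happens for strongly skewed posteriors.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions; `generate_cohort()` realizes
them. Defaults (all configurable):

* **Design.** 163 patients, balanced permuted allocation to antibiotics
  vs placebo (as in a stratified multi-center trial), microbial sampling
  at months 0, 2, 8, 14, 26. The published design names baseline, month 2
  and month 26 explicitly and intermediate sampling "at various
  intervals"; 8 and 14 are the package's stand-in interior visits.
* **Taxa layer.** 200 taxa; the two community distributions are drawn
  once per cohort from Dirichlet priors concentrating ~60% of mass on
  disjoint signature sets (6 pathobionts, 5 commensals); library sizes are
  lognormal with mean 20,000 reads; counts are multinomial over the
  score-weighted mixture of the two communities — exactly the LDA
  generative process, so the topic model is correctly specified for it.
* **Baseline state.** True baseline dysbiotic proportion
  $\sim\mathrm{Beta}(1.8, 0.5)$ (median 0.865, matching the
  dysbiosis-dominated baselines of untreated periodontitis, with ~14% of
  subjects below the 0.5 cut — the "baseline normobiotic" subgroup). The
  published work dichotomizes baseline state without stating a cut; the
  generator uses score < 0.5. Healthy controls draw from Beta(1, 20)
  (mean 0.048).
* **Mediator layer.** Category 0–3 per subject from the proportional-odds
  model with treatment log-odds log(6.42), baseline-normobiotic log-odds
  log(7.8) (the published ordinal-model estimates), smoking −0.5, age
  bands −0.2/−0.4, sex 0, cutpoints (0.2, 1.4, 2.6) chosen once so that
  all four categories are well populated in both arms at n = 163.
* **Trajectories.** Category archetypes interpolate anchors at baseline
  (0.85), first post-treatment visit and final visit — non-responder
  (0.85, 0.75, 0.85), indifferent (0.85, 0.60, 0.45), short-term
  responder (0.85, 0.25, 0.62), responder (0.85, 0.15, 0.10) — plus
  Gaussian noise (SD 0.1) clamped to [0, 1]. The baseline Beta draw
  enters the mediator model only through the indicator; realized scores
  come from the archetypes, so zero-noise configurations yield identical
  trajectories within category.
* **Outcome layer.** Sites per patient 6 × teeth, teeth ≈ 24 on average;
  attachment-loss counts NB with size 2 (site counts in this literature
  are clearly overdispersed; the size is configurable), log-rate intercept
  log(8.14/146) (the reference cell of the published prediction grid),
  direct treatment effect log(0.82), per-category log(0.72), smoking
  log(1.85), age bands log(1.18)/log(1.47), sex 0. Pocket-depth and
  bleeding site counts are binomial with rates tied to the current true
  dysbiosis score, giving the association models realistic structure.

`implied_total_effect()` reports the marginal treatment rate ratio the
configuration implies (Monte Carlo with common random numbers and a
paired-ratio delta-method SE) — needed because the outcome model
conditions on the mediator, so the total effect is not a parameter.
`calibrate_total_effect()` root-finds the mediator treatment log-odds that
makes the implied marginal effect hit a target; with all other defaults at
their published values, hitting a marginal rate ratio of 0.73 requires a
smaller mediator treatment effect (log-odds ≈ 0.85) than the published
conditional odds ratio — the default configuration's published effect
sizes jointly imply a stronger marginal effect (≈ 0.58) than the published
marginal estimate, which is a real tension in the source numbers, not a
generator artifact.

### What the generator does and does not emulate

It reproduces the design (randomization, repeated sampling, confounding of
the mediator-outcome path by age/sex/smoking), the count nature and
overdispersion of both the taxa and the outcome layers, and ground truth
for every latent quantity. It does **not** simulate sequencing error,
chimeras, taxonomic misassignment, batch effects between sequencing
platforms, within-subject autocorrelated noise beyond the archetypes,
multi-center stratification, or informative missingness. Passing recovery
tests therefore demonstrates correctness of the estimators under the
assumed generating process — not robustness to the artifacts of real 16S
pipelines.

## Problem sizes used by the test suite

Simulation scales were chosen once as the package's own test design: 200
cohorts of n = 163 for effect-size recovery (geometric means compared at
3 Monte-Carlo SEs); a 100-seed topic-labeling run on reduced cohorts
(30 patients, 120 taxa, 2,000 reads, 150 sweeps — the labeling decision is
already unambiguous at this depth); trajectory-recovery checks on
generator-truth scores at full n = 163; one joint topic fit of baseline
patients plus 40 healthy controls at full library size for the
healthy-vs-disease contrast; and 60 seeds for the null-mediation coverage
check (each seed fits two 4-chain MCMC models), with the coverage bound at
the nominal rate minus ~2.5 binomial SDs. Parameter-recovery invariants are
additionally checked on a single cohort of 5,000 subjects against
model-based standard errors.

## Known limitations

* Topic labeling needs at least one reference taxon in the vocabulary;
  heavily aggregated tables (genus level) can dilute the signature lists.
* The proportional-odds bias correction targets the geometric-mean scale;
  reported per-fit standard errors remain the ML ones.
* The d-separation machinery enumerates simple paths and is intended for
  graphs of study size (≲ 15 nodes), not for discovery-scale networks.
* `fit_bayesian_nb()` parametrizes dispersion as the NB size with a
  half-normal prior; extremely small dispersions (size ≫ 100, i.e.
  near-Poisson data) push against the prior unless `size_sd` is raised,
  as the conjugate-limit test does.
* The indirect-effect interval from independently fitted models is the
  convolution of the two posteriors; it ignores the (beneficial, in
  practice) posterior correlation a joint model would induce, and is
  therefore conservative.
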