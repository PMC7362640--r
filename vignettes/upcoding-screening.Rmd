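---
title: "Screening hospital claims for DRG upcoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening hospital claims for DRG upcoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital reimbursement under Diagnosis Related Groups (DRGs) creates an
incentive to *upcode*: to register diagnoses and procedures so a
hospitalization falls into a more remunerative DRG class — typically the
"with complications/comorbidities" (CC) member of a paired DRG. Auditors who
screen administrative discharge data for this behavior face two opposite
failure modes. Providers with frankly extreme volumes or costs are easy to
find but rarely the interesting cases; *cautious* deviants hide inside the
ordinary spread of a heterogeneous provider population, where hospitals
legitimately differ by size, specialization and casemix. `drgscreen`
implements a two-step screen for exactly these cautious cases.

## Step One: local outliers among behavioral peers

The unit of analysis is the provider. From a disease cohort of Hospital
Discharge Charts (HDCs) we build, per hospital $h$, a behavioral feature
vector containing:

* $r_{ih}$ — the share of the hospital's disease-related episodes assigned
  to each disease DRG $i$ (a point on the simplex over the DRG family);
* scalar indexes: average cost and length of stay (LOS) per visit, episode
  and visit counts, *specialization* (disease episodes over all visits), the
  CC share of coded episodes, an *upcoding index*, and average cost per
  patient.

All columns are z-score standardized (constant columns dropped) because
every downstream step — principal decomposition, k-means, centroid
distances — is Euclidean and the raw features mix units.

Because the number of hospitals can be comparable to the number of
features, Step One embeds an unsupervised feature selection: **Principal
Feature Analysis (PFA)**. One PFA run computes the principal decomposition,
keeps the $q$ leading components retaining at least a fraction
`variance_retained` (default 0.90) of total variance, represents each
feature by its $q$-dimensional loading row, partitions loading rows into
$n$ groups by k-means, and keeps the feature nearest each group mean.
Because this greedy partition depends on the k-means restarts, the
selection is repeated $B$ times (default 200) with derived seeds and the
$n$ most frequently appearing features are kept — a stability-selection
argument: redundant features split appearances within their block while
genuinely independent features appear in nearly every run.

Neither $n$ (features) nor $k$ (clusters) is assumed known. A **grid
search** evaluates every pair from `n_grid` (default $\{20, 30, 40\}$) and
`k_grid` (default $\{5,\dots,8\}$), fitting k-means (`stats::kmeans`,
Hartigan–Wong, 10 random restarts under derived seeds — the restarts, not a
bespoke seeding scheme, carry the robustness of the argmax) and scoring
each cell by the **mean silhouette width**
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ with Euclidean distances. The pair
maximizing the mean silhouette wins; exact ties go to the smaller $k$, then
the smaller $n$. Feature selection can be skipped entirely
(`use_feature_selection = FALSE`), which is also a built-in robustness
check: a sound flagging should not hinge on the selection step.

Finally, each hospital's Euclidean distance to its own cluster centroid is
computed *in the standardized selected-feature space the k-means ran in*,
and hospitals strictly above the 95th percentile of that distance
distribution are flagged. The percentile uses linear interpolation between
order statistics (`stats::quantile`, type 7); with $N$ distinct distances
this flags exactly $N - \lfloor 1 + 0.95 (N-1) \rfloor$ units — 10 out
of 183. The threshold percentile is a policy trade-off (list length an
audit office can process), not an estimated quantity, and the package does
not tune it.

### Numerical conventions

* Singleton clusters contribute silhouette 0; a point whose $a$ and $b$
  are both 0 contributes 0.
* A grid cell whose clustering degenerates to an empty cluster is re-seeded
  once, then skipped with a warning; cells with $k \ge$ number of units are
  skipped.
* PFA loading rows are processed in lexicographic feature order, so the
  selection is invariant to input column order; representative and
  appearance-count ties break lexicographically.
* Same-day discharges have LOS 0; wherever LOS is a denominator it counts
  as 1 day.
* All randomness flows from one user seed through deterministic stream
  derivation, so every result reproduces exactly.

## Step Two: auditor decision support

Flagging is not an accusation; behavioral screens have high false-positive
rates, so each flagged provider is cross-examined on two fronts.

**Fraud-related indexes.** The provider's percentile position among all
providers on five variables: average cost, CC share, specialization, number
of visits, and the upcoding index. Positions use the strict-rank convention
(`fraction of the population strictly below`), which maps the population
minimum to 0 and the maximum of $N$ distinct values to $(N-1)/N$ — with 183
providers, 0.994 when printed to three decimals. The implemented upcoding
index is the provider's CC share among paired disease DRGs divided by the
population's CC share (1 = population-typical). It is a deliberately simple,
scale-free descriptive ratio, isolated in one function (`upcodingIndex()`)
so a different definition — e.g. a casemix-adjusted one — can be swapped in.
Note its limitation: a provider whose patients are genuinely sicker can
legitimately sit high on it, which is precisely why Step Two exists.

**Casemix cross-validation.** The provider's patient population is compared
with everyone else's on complexity and expensiveness variables: age, LOS,
comorbidity, total cost, cost/LOS and cost/comorbidity. Comparisons are on
the log scale with a +1 offset (LOS and comorbidity can be 0; negative
comorbidity totals from protective weights are floored at 0 before the
offset, and cost/comorbidity divides by $\max(\mathrm{CI},0)+1$). The
report returns the two distributions' log-means and quartiles plus density
overlays. The interpretive logic: a right-shifted LOS/comorbidity profile
with population-typical cost intensity suggests a genuinely complex casemix
(outlierness explained); a *left*-shifted complexity profile with
*right*-shifted cost intensity is the upcoding signature worth an auditor's
time. The package renders comparisons only — never verdicts.

Comorbidity is scored per discharge with a pluggable weight table; the
shipped default is the combined comorbidity score of Gagne et al. (2011),
20 conditions with the published integer weights. The ICD-9-CM prefix
mapping shipped with it is a simplified representative subset, stored as
editable YAML — swap in your jurisdiction's full mapping (or Charlson
weights) without touching code. Each condition counts once per discharge
across all diagnosis positions, and a patient's per-discharge scores are
summed without normalization into the patient-level index.

## The synthetic-claims generator

Administrative claims are rarely shareable, so the package ships a
generator whose output exercises every pipeline stage with known ground
truth. Its defaults are the package's reference study conditions and were
fixed as design choices, not fitted to test outcomes:

* **183 hospitals in 6 behavior groups.** Each group concentrates 70% of
  its DRG-pair mix on 4 disjoint signature pairs out of 25 CC/non-CC
  pairs; hospital mixes are Dirichlet perturbations (concentration 500)
  of the group mix. With roughly 150 disease episodes per hospital this
  puts between-group contrast on signature mix components at about 4
  within-group standard deviations — separated, but far from trivially so.
  The 25 pairs give 50 mix components plus 8 scalar indexes, so the
  default feature grid $\{20, 30, 40\}$ operates on 58 features.
* **Patients.** Ages are Normal(78, 10) clipped at 18; chronic conditions
  are Bernoulli draws per weight-table condition with age-increasing
  prevalence; LOS is lognormal with location increasing in the discharge's
  comorbidity score; cost multiplies a pair-specific tariff, a 35% CC
  premium, a sublinear LOS factor ($\mathrm{LOS}^{0.8}$) and lognormal
  noise. Each patient belongs to one hospital and contributes
  $1 + \mathrm{Pois}(0.5)$ disease episodes and $\mathrm{Pois}(0.8)$
  unrelated visits (the specialization denominator).
* **Planted deviants.** Eight *upcoders* relabel each non-CC disease
  episode to its CC pair with probability $\delta = 0.4$; by default they
  differ from their group **only** through this relabeling and its cost
  consequence, so at $\delta = 0$ they are distributionally
  indistinguishable from honest peers. Two *complex-casemix* providers
  triple their patients' condition prevalences with honest coding — the
  "justified outlier" a screen must not confuse with fraud.
* **Cautiousness is modelled, not asserted.** Hospital-level CC propensity
  is jittered (SD 0.05, linear so expected CC shares stay closed-form).
  Without this overdispersion a relabeling deviant is so many noise
  standard deviations from everyone that k-means gives the deviants their
  own cluster — the opposite of the cautious-fraudster construct, where
  deviants must remain inside their peer group and be caught as *local*
  outliers. An early design without jitter showed exactly that failure,
  and the jitter plus $\delta = 0.4$ restores the intended construct.

Closed-form expectations (`expectedProfiles()`) back the recovery tests:
an upcoder's expected CC share is
$p_{cc} + \delta\,(1 - p_{cc})$, mix components split each pair's mass by
the CC share, and expected specialization follows from the episode rates.

**What the generator does not emulate:** real DRG tariff schedules, real
ICD code frequencies, patients moving between hospitals, seasonal or
secular drift within the window, coder-level idiosyncrasies, and coding
error that is *not* directional. Green recovery tests therefore demonstrate
that the machinery finds the structure it is designed to find at realistic
separations — not that it will enjoy the same margins on any particular
real extract.

## Problem sizes used by the test suite

The packaged experiments run the full pipeline — generation, cohort
extraction, aggregation, ensemble selection, grid search, flagging — at the
default scale (183 hospitals, ~40k events) over 10 seeds, with the PFA
ensemble at $B = 50$ inside the repeated experiments and $B = 200$
(the method's default) elsewhere; a full single run takes a few seconds on
one core. Unit fixtures use smaller populations (40–60 hospitals) chosen so
that every asserted contrast exceeds its Monte-Carlo noise by a comfortable
margin under the fixed test seeds.

## Known limitations

* The upcoding index is not casemix-adjusted (see above); Step Two's
  casemix panel is the compensating control.
* Cohort extraction keeps only in-window hospitalizations of qualifying
  patients; care pathways straddling the window boundary are truncated.
* The window-membership convention is the admission date, inclusive on
  both ends.
* k-means restricts peer groups to roughly hyperspherical shapes in the
  standardized space; this is a deliberate simplicity/robustness trade-off,
  and alternative clusterers are out of scope.
* With feature selection disabled on wide data ($p \gtrsim$ units), the
  silhouette landscape flattens and the chosen $k$ is less stable.
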