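# drgscreen

Unsupervised screening of hospital providers for anomalous DRG coding
behavior ("upcoding") in administrative discharge data, with an
auditor-facing validation layer.

Hospitals are reimbursed by the Diagnosis Related Group (DRG) assigned to
each hospitalization, which creates an incentive to code patients into the
more remunerative "with complications" (CC) member of a paired DRG. The
hard cases for an audit office are not the providers with extreme volumes
or costs but the *cautious* deviants hidden inside a heterogeneous provider
population. `drgscreen` targets those, for analysts and auditors working
with Hospital Discharge Chart (HDC) tables.

## Method

**Step One — local outliers among behavioral peers.** Each provider *h* is
described by a behavioral feature vector: the relative frequency
*r<sub>ih</sub>* of each disease-related DRG *i* among its disease
episodes, plus scalar indexes (average cost and length of stay,
specialization, CC share, upcoding index, visit counts, cost per patient).
After z-score standardization, an ensemble Principal Feature Analysis
(*B* = 200 repetitions, appearance counting) selects *n* features; k-means
(10 restarts) partitions providers into *k* peer clusters; a grid search
over (*n*, *k*) — defaults {20, 30, 40} x {5, 6, 7, 8} — keeps the pair
maximizing the mean silhouette width *s(i)* = (*b* − *a*) / max(*a*, *b*).
Each provider's Euclidean distance to its own cluster centroid is computed
in the selected standardized space, and providers strictly above the 95th
percentile of that distribution (linear-interpolation convention) are
flagged: with *N* distinct distances, exactly
*N* − floor(1 + 0.95 (*N* − 1)) units — 10 of 183.

**Step Two — auditor decision support.** Each flagged provider gets (i) its
strict-rank percentile position among all providers on five fraud-related
variables (average cost, CC share, specialization, visits, upcoding index),
and (ii) a log-scale comparison of its patients' casemix (age, length of
stay, comorbidity, cost, cost/LOS, cost/comorbidity — comorbidity via the
combined comorbidity score from a pluggable weight table) against the
population. Output is descriptive comparison only, never a verdict.

A synthetic-claims generator with known behavior groups and planted
deviants (upcoders and complex-casemix providers) makes the whole pipeline
testable without restricted data; see the methods vignette
(`vignettes/upcoding-screening.Rmd`) for the model and design rationale.

## Worked example

```r
library(drgscreen)

sim      <- simulateHdc(simConfig(seed = 1))       # 183 hospitals, known truth
cohort   <- extractCohort(sim$records, simCohortConfig(sim$config))
hospitals <- buildHospitals(cohort)
result   <- screen(hospitals$features, gridConfig(pfa_runs = 200, seed = 1))
result
#> <screening_result>
#>   best (n, k): ( 40 , 6 )  mean silhouette: 0.4467
#>   flagged 10 of 183 units above the 95 th-percentile distance 5.5189
#>   outliers: H014, H021, H043, H051, H068, H085, H106, H129, H162, H167
```

The grid picked 6 peer clusters and 40 features; 10 providers lie strictly
above the 95th-percentile distance to their own cluster centroid. Against
the generator's ground truth, all 10 planted deviants are among them:

```r
truth <- sim$truth
sum(truth$hospital_id[truth$deviant_type != "none"] %in% result$outlier_ids)
#> [1] 10
```

Step Two, for the first two flagged providers:

```r
patients <- buildPatients(cohort, readWeightTable())
report   <- buildAudit(hospitals, patients, cohort, result$outlier_ids[1:2])
report$dashboard$table
#> # A tibble: 5 × 3
#>   variable        H014  H021
#>   <chr>          <dbl> <dbl>
#> 1 avg_cost       0.279 0.787
#> 2 pct_cc         0.973 0.902
#> 3 specialization 0.180 0.667
#> 4 n_visits       0.923 0.787
#> 5 upcoding_index 0.973 0.902
```

Read each cell as "fraction of providers strictly below": H014 codes CC
more often than 97% of providers while sitting at the 18th percentile of
specialization — the combination Step Two exists to surface.
`report$casemix[["H014"]]` holds the log-scale casemix summaries and
density plots.

A thin command-line wrapper over the same functions ships at
`inst/cli/upcode-screen.R` (subcommands `simulate`, `extract`, `screen`,
`audit`).

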