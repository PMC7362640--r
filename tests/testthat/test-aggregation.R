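test_that("patient summaries take age at first admission and sum CIs", {
  wt <- toy_weights()
  recs <- dplyr::bind_rows(
    make_record("E1", "P1", admission_date = "2014-01-01",
                discharge_date = "2014-01-04", age = 70L,
                diagnosis_codes = "4280;1110"),             # CI 2
    make_record("E2", "P1", admission_date = "2015-02-01",
                discharge_date = "2015-02-03", age = 71L,
                diagnosis_codes = "4280;2220"),             # CI -1
    make_record("E3", "P2", admission_date = "2014-05-01",
                discharge_date = "2014-05-06", age = 80L)
  )
  cohort <- extractCohort(recs, toy_config())
  pat <- buildPatients(cohort, wt)
  p1 <- pat[pat$patient_id == "P1", ]
  expect_equal(p1$age_first, 70L)
  expect_equal(p1$n_events, 2L)
  expect_equal(p1$total_ci, 1L)
  expect_equal(p1$total_los, 3L + 2L)
  expect_equal(p1$mean_los, 2.5)
  p2 <- pat[pat$patient_id == "P2", ]
  expect_equal(p2$mean_los, p2$total_los)   # single event
})

test_that("the DRG mix is the within-family proportion vector", {
  fam <- c("D1", "D2", "D3")
  expect_equal(drgMix(c(rep("D1", 8), rep("D2", 2)), fam),
               c(D1 = 0.8, D2 = 0.2, D3 = 0))
  expect_equal(drgMix(rep("D2", 5), fam), c(D1 = 0, D2 = 1, D3 = 0))
  expect_equal(drgMix(c("D1", "D2", "D3", "D3", "OTH"), fam),
               c(D1 = 0.25, D2 = 0.25, D3 = 0.5))  # outsiders excluded
  expect_error(drgMix(c("OTH", "OTH"), fam), "no disease-related episodes")
})

test_that("the upcoding index is the CC-share ratio against the population", {
  cfg <- toy_config()
  hosp <- c(rep("D01C", 6), rep("D01", 4))      # CC share 0.6
  pop <- c(rep("D01C", 3), rep("D01", 7))       # CC share 0.3
  expect_equal(upcodingIndex(hosp, pop, cfg), 2)
  expect_equal(upcodingIndex(pop, pop, cfg), 1)
  expect_equal(upcodingIndex(rep("D01", 5), pop, cfg), 0)
  expect_error(upcodingIndex(hosp, rep("D01", 5), cfg), "population CC share")
})

test_that("hospital profiles compute the named ratio indexes", {
  wt <- toy_weights()
  recs <- dplyr::bind_rows(
    # H1: 10 disease episodes (4 CC) among 100 visits
    purrr::map_dfr(1:10, function(i) {
      make_record(paste0("E", i), paste0("P", i), "H1",
                  drg_code = if (i <= 4) "D01C" else "D01")
    }),
    purrr::map_dfr(11:100, function(i) {   # non-disease visits of P1..P10
      make_record(paste0("E", i), paste0("P", i %% 10 + 1), "H1",
                  diagnosis_codes = "486", drg_code = "OTH1")
    }),
    make_record("E200", "P200", "H2", drg_code = "D02")
  )
  cohort <- extractCohort(recs, toy_config())
  hos <- buildHospitals(cohort)
  h1 <- hos$profiles[hos$profiles$hospital_id == "H1", ]
  expect_equal(h1$specialization, 0.10)
  expect_equal(h1$pct_cc, 0.4)
  expect_equal(h1$n_visits, 100L)
  expect_equal(h1$avg_cost, sum(recs$cost[recs$hospital_id == "H1"]) / 100)
})

test_that("a hospital with no disease-related episode is dropped with a warning", {
  recs <- dplyr::bind_rows(
    make_record("E1", "P1", "H1"),
    make_record("E2", "P2", "H3", drg_code = "D01C"),
    make_record("E3", "P1", "H2", diagnosis_codes = "486", drg_code = "OTH1")
  )
  cohort <- extractCohort(recs, toy_config())
  expect_warning(hos <- buildHospitals(cohort), "zero disease-related")
  expect_setequal(hos$profiles$hospital_id, c("H1", "H3"))
})

test_that("aggregation conserves episodes and reproduces a naive groupby oracle", {
  sim <- small_sim()
  hos <- sim$hospitals
  rec <- sim$cohort$records
  fam <- sim$cohort$config$drg_family
  expect_equal(sum(hos$profiles$n_episodes), sum(rec$drg_code %in% fam))
  # naive per-hospital oracle
  oracle <- tapply(rec$cost, rec$hospital_id, mean)
  expect_equal(hos$profiles$avg_cost,
               as.numeric(oracle[hos$profiles$hospital_id]))
  # every mix lies on the simplex over the family
  r_cols <- paste0("r_", fam)
  r <- as.matrix(hos$profiles[, r_cols])
  expect_true(all(r >= 0))
  expect_equal(unname(rowSums(r)), rep(1, nrow(r)))
  expect_true(all(hos$profiles$specialization >= 0 &
                    hos$profiles$specialization <= 1))
  expect_true(all(hos$profiles$pct_cc >= 0 & hos$profiles$pct_cc <= 1))
})

test_that("the default-scale generator yields one profile per facility", {
  sim <- simulateHdc(simConfig(mean_patients = 8, seed = 3))
  cohort <- extractCohort(sim$records, simCohortConfig(sim$config))
  hos <- buildHospitals(cohort)
  expect_equal(nrow(hos$profiles), 183L)
})

test_that("standardization yields zero-mean unit-variance columns and drops constants", {
  set.seed(5)
  vals <- cbind(a = rnorm(40, 10, 3), b = runif(40), const = rep(2, 40))
  fm <- featureMatrix(paste0("u", 1:40), colnames(vals), vals)
  expect_warning(z <- standardizeFeatures(fm), "constant")
  expect_equal(z$feature_names, c("a", "b"))
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_lt(max(abs(apply(z$values, 2, stats::sd) - 1)), 1e-9)
  expect_true(z$standardized)
})

test_that("hospital datasets round-trip through CSV + sidecar", {
  dir <- withr::local_tempdir()
  hos <- small_sim()$hospitals
  writeHospitals(hos, dir)
  back <- readHospitals(dir)
  expect_equal(back$features$feature_names, hos$features$feature_names)
  expect_equal(back$features$values, hos$features$values)
})
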