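test_that("percentile positions use the strict-rank convention", {
  pop <- c(4, 9, 2, 7)
  expect_equal(percentilePosition(2, pop), 0)          # population minimum
  expect_equal(percentilePosition(9, pop), 3 / 4)
  expect_equal(percentilePosition(5, rep(5, 10)), 0)   # all equal
  expect_error(percentilePosition(1, numeric()), "empty")
  pop183 <- sample(183)
  expect_equal(percentilePosition(183, pop183), 182 / 183)
  # printed to three decimals this is the audit table's 0.994
  expect_equal(floor(percentilePosition(183, pop183) * 1000) / 1000, 0.994)
})

test_that("percentile positions are nondecreasing and cover the rank grid", {
  set.seed(31)
  pop <- rnorm(50)
  vals <- sort(runif(10, min(pop), max(pop)))
  pos <- vapply(vals, percentilePosition, numeric(1), population = pop)
  expect_true(all(diff(pos) >= 0))
  all_pos <- sort(vapply(pop, percentilePosition, numeric(1), population = pop))
  expect_equal(all_pos, (seq_along(pop) - 1) / length(pop))  # distinct values
})

test_that("the fraud dashboard has the Table-5 shape and flags maxima at (N-1)/N", {
  sim <- small_sim()
  prof <- sim$hospitals$profiles
  ids <- prof$hospital_id[1:2]
  dash <- fraudDashboard(sim$hospitals, ids)
  expect_equal(dash$table$variable,
               c("avg_cost", "pct_cc", "specialization", "n_visits",
                 "upcoding_index"))
  expect_equal(dim(dash$table), c(5L, 3L))
  expect_true(all(as.matrix(dash$table[, -1]) >= 0 &
                    as.matrix(dash$table[, -1]) < 1))
  expect_length(dash$plots, 5L)
  expect_error(fraudDashboard(sim$hospitals, "NOPE"), "unknown outlier")

  # a unit sitting at the maximum of a variable lands at (N-1)/N
  N <- nrow(prof)
  top_id <- prof$hospital_id[which.max(prof$avg_cost)]
  dtop <- fraudDashboard(sim$hospitals, top_id)
  expect_equal(dtop$table[[top_id]][dtop$table$variable == "avg_cost"],
               (N - 1) / N)
})

test_that("a planted upcoder sits in the top decile of the coding variables", {
  sim <- small_sim()
  upcoders <- sim$sim$truth$hospital_id[sim$sim$truth$deviant_type == "upcoder"]
  dash <- fraudDashboard(sim$hospitals, upcoders)
  pos <- as.matrix(dash$table[, -1])
  rownames(pos) <- dash$table$variable
  expect_true(all(pos["pct_cc", ] >= 0.9))
  expect_true(all(pos["upcoding_index", ] >= 0.9))
})

test_that("dashboard percentiles survive a serialize/recompute round-trip", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  writeHospitals(sim$hospitals, dir)
  dash1 <- fraudDashboard(sim$hospitals, sim$hospitals$profiles$hospital_id[5])
  dash2 <- fraudDashboard(readHospitals(dir),
                          sim$hospitals$profiles$hospital_id[5])
  expect_equal(dash1$table, dash2$table)
})

test_that("casemix of a typical provider matches the population on log-means", {
  sim <- small_sim()
  truth <- sim$sim$truth
  honest <- truth$hospital_id[truth$deviant_type == "none"][1]
  pats <- buildPatients(sim$cohort, sim$weights)
  cm <- casemixComparison(honest, pats, sim$cohort, sim$weights)
  wide <- tidyr::pivot_wider(cm$summary[, c("variable", "group", "log_mean")],
                             names_from = "group", values_from = "log_mean")
  expect_lt(max(abs(wide$outlier - wide$population)), 0.25)
  expect_error(casemixComparison("NOPE", pats, sim$cohort, sim$weights),
               "no hospitalizations")
})

test_that("a complex-casemix provider shows longer stays but typical cost intensity", {
  sim <- small_sim()
  truth <- sim$sim$truth
  complex_id <- truth$hospital_id[truth$deviant_type == "complex"][1]
  pats <- buildPatients(sim$cohort, sim$weights)
  cm <- casemixComparison(complex_id, pats, sim$cohort, sim$weights)
  g <- function(v, grp) {
    cm$summary$log_mean[cm$summary$variable == v & cm$summary$group == grp]
  }
  expect_gt(g("los", "outlier"), g("los", "population"))          # right-shifted
  expect_gt(g("comorbidity", "outlier"), g("comorbidity", "population"))
  expect_lt(abs(g("cost_per_los", "outlier") - g("cost_per_los", "population")),
            0.2)
})

test_that("an upcoder treating mild patients shows short stays with high cost intensity", {
  cfg <- simConfig(n_hospitals = 60L, n_groups = 3L, n_upcoders = 3L,
                   n_complex = 0L, mean_patients = 80, delta = 0.5,
                   upcoder_ci_mult = 0.2, seed = 99L)
  sim <- simulateHdc(cfg)
  cohort <- extractCohort(sim$records, simCohortConfig(cfg))
  wt <- readWeightTable()
  pats <- buildPatients(cohort, wt)
  up <- sim$truth$hospital_id[sim$truth$deviant_type == "upcoder"][1]
  cm <- casemixComparison(up, pats, cohort, wt)
  g <- function(v, grp) {
    cm$summary$log_mean[cm$summary$variable == v & cm$summary$group == grp]
  }
  expect_lt(g("los", "outlier"), g("los", "population"))           # left-shifted
  expect_gt(g("cost_per_los", "outlier"), g("cost_per_los", "population"))
})

test_that("every hospitalization is attributed to exactly one provider", {
  sim <- small_sim()
  rec <- sim$cohort$records
  per_hosp <- table(rec$hospital_id)
  expect_equal(sum(per_hosp), nrow(rec))
  pats <- buildPatients(sim$cohort, sim$weights)
  ids <- sim$hospitals$profiles$hospital_id[1:2]
  report <- buildAudit(sim$hospitals, pats, sim$cohort, ids,
                       weights = sim$weights)
  ns <- vapply(report$casemix, function(cm) {
    cm$summary$n[cm$summary$variable == "los" & cm$summary$group == "outlier"]
  }, numeric(1))
  expect_equal(unname(ns), unname(as.numeric(per_hosp[ids])))
  dir <- withr::local_tempdir()
  writeAudit(report, dir)
  expect_true(file.exists(file.path(dir, "fraud_percentiles.csv")))
  expect_true(all(file.exists(file.path(dir, paste0("casemix_", ids, ".json")))))
})
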