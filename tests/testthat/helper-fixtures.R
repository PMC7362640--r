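# Shared fixtures, all built in code.

# A minimal valid record; override any field.
make_record <- function(event_id = "E1", patient_id = "P1", hospital_id = "H1",
                        admission_date = "2014-03-01",
                        discharge_date = "2014-03-05", age = 70L,
                        diagnosis_codes = "4280", procedure_codes = "",
                        drg_code = "D01", cost = 3000,
                        ownership = "public") {
  tibble::tibble(
    event_id = event_id, patient_id = patient_id, hospital_id = hospital_id,
    admission_date = as.Date(admission_date),
    discharge_date = as.Date(discharge_date), age = as.integer(age),
    diagnosis_codes = diagnosis_codes, procedure_codes = procedure_codes,
    drg_code = drg_code, cost = cost, ownership = ownership
  )
}

toy_config <- function(...) {
  cohortConfig(
    disease_codes = "428",
    drg_family = c("D01", "D01C", "D02", "D02C", "D03"),
    cc_drg_codes = c("D01C", "D02C"),
    window_start = "2013-01-01", window_end = "2015-12-31",
    ...
  )
}

# Tiny two-condition weight table written to a temp YAML.
toy_weights <- function() {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(c(
    "provenance: toy",
    "condA:",
    "  prefixes: ['111', '112']",
    "  weight: 2",
    "condB:",
    "  prefixes: ['222']",
    "  weight: -1"
  ), path)
  readWeightTable(path)
}

# Brute-force silhouette oracle: literal per-point double loop.
brute_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) sqrt(sum((X[i, ] - X[j, ])^2))))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      other <- which(labels == g)
      d <- mean(sapply(other, function(j) sqrt(sum((X[i, ] - X[j, ])^2))))
      b <- min(b, d)
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Small but fully structured simulation reused by aggregate/audit tests
# (cached per session; ~60 hospitals keeps tests fast).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simConfig(n_hospitals = 60L, n_groups = 3L, n_upcoders = 3L,
                       n_complex = 1L, mean_patients = 40, delta = 0.5,
                       seed = 42L)
      sim <- simulateHdc(cfg)
      cohort <- extractCohort(sim$records, simCohortConfig(cfg))
      cache <<- list(sim = sim, cohort = cohort,
                     hospitals = buildHospitals(cohort),
                     weights = readWeightTable())
    }
    cache
  }
})
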