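#' Build the patients dataset
#'
#' Aggregates a cohort at patient level: age at the chronologically first
#' hospitalization, number of events, summed comorbidity index, total and
#' mean cost and length of stay.
#'
#' @param cohort An [extractCohort()] result.
#' @param weights A [readWeightTable()] object.
#' @return Tibble with one row per qualifying patient: `patient_id`,
#'   `age_first`, `n_events`, `total_ci`, `total_cost`, `total_los`,
#'   `mean_los`.
#' @export
buildPatients <- function(cohort, weights) {
  stopifnot(inherits(cohort, "hdc_cohort"))
  rec <- cohort$records
  rec$ci <- scoreHdc(rec, weights)
  rec$los <- los_days(rec$admission_date, rec$discharge_date)
  rec |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      age_first = .data$age[which.min(.data$admission_date)],
      n_events = dplyr::n(),
      total_ci = as.integer(sum(.data$ci)),
      total_cost = sum(.data$cost),
      total_los = sum(.data$los),
      mean_los = sum(.data$los) / dplyr::n(),
      .groups = "drop"
    )
}

#' Relative DRG mix of one provider
#'
#' The behavioral signature vector: for each disease-related DRG, the share
#' of the provider's disease-related episodes assigned to it. Episodes with
#' DRGs outside the family are excluded from numerator and denominator.
#'
#' @param drg_codes DRG codes of one hospital's episodes.
#' @param drg_family Character vector of disease-related DRG codes.
#' @return Named numeric vector over `drg_family`, summing to 1.
#' @export
#' @examples
#' drgMix(c("D1","D1","D2","D3","D3","D3","D1","D1"), c("D1","D2","D3"))
drgMix <- function(drg_codes, drg_family) {
  if (length(drg_family) == 0L) stop("drg_family must be non-empty")
  inside <- drg_codes[drg_codes %in% drg_family]
  if (length(inside) == 0L) {
    stop("undefined DRG mix: no disease-related episodes")
  }
  counts <- table(factor(inside, levels = drg_family))
  r <- as.numeric(counts) / length(inside)
  names(r) <- drg_family
  r
}

#' Upcoding index of one provider
#'
#' Scale-free ratio of the provider's with-complications (CC) share among
#' CC/non-CC paired disease DRGs to the population's CC share over the same
#' DRG set. 1 means population-typical coding; values above 1 mean the
#' provider codes CC more often than the population. This descriptive ratio
#' is deliberately isolated here so a different index definition can be
#' swapped in.
#'
#' @param drg_codes DRG codes of one hospital's episodes.
#' @param population_drg_codes DRG codes of all cohort episodes.
#' @param config A [cohortConfig()]; `paired_drgs` defines the comparable DRG
#'   set (default: the whole family).
#' @return Non-negative number.
#' @export
upcodingIndex <- function(drg_codes, population_drg_codes, config) {
  paired <- config$paired_drgs
  cc <- intersect(config$cc_drg_codes, paired)
  h <- drg_codes[drg_codes %in% paired]
  pop <- population_drg_codes[population_drg_codes %in% paired]
  if (length(h) == 0L) stop("hospital has no episodes among paired DRGs")
  pop_share <- mean(pop %in% cc)
  if (pop_share == 0) stop("undefined upcoding index: population CC share is 0")
  mean(h %in% cc) / pop_share
}

hospital_feature_names <- function(drg_family) {
  c(paste0("r_", drg_family),
    "avg_cost", "avg_los", "n_episodes", "n_visits",
    "specialization", "pct_cc", "upcoding_index", "avg_cost_per_patient")
}

#' Build the hospitals dataset and its feature matrix
#'
#' Aggregates a cohort per provider into behavioral features: the relative
#' DRG mix over the disease family, average cost and length of stay per
#' visit, episode and visit counts, specialization (disease episodes among
#' all visits), CC share, upcoding index and average cost per patient.
#' Hospitals with zero disease-related episodes are dropped with a warning.
#' "Number of visits" counts hospitalizations; the unique-patient count is
#' kept alongside it in the profiles (`n_patients`) for users who prefer
#' building a custom [featureMatrix()] on that definition.
#'
#' @param cohort An [extractCohort()] result.
#' @param patients Output of [buildPatients()] (currently used for
#'   consistency checks only; all features derive from the cohort records).
#' @return List of class `hospital_profiles`: `profiles` (tibble, one row per
#'   hospital with an `r` matrix column expanded into `r_<DRG>` columns) and
#'   `features` (unstandardized [featureMatrix()]).
#' @export
buildHospitals <- function(cohort, patients = NULL) {
  stopifnot(inherits(cohort, "hdc_cohort"))
  config <- cohort$config
  rec <- cohort$records
  rec$los <- los_days(rec$admission_date, rec$discharge_date)
  rec$is_family <- rec$drg_code %in% config$drg_family

  dropped <- rec |>
    dplyr::group_by(.data$hospital_id) |>
    dplyr::summarise(n_ep = sum(.data$is_family), .groups = "drop") |>
    dplyr::filter(.data$n_ep == 0L)
  if (nrow(dropped)) {
    warning("dropping ", nrow(dropped),
            " hospital(s) with zero disease-related episodes: ",
            paste(dropped$hospital_id, collapse = ", "))
    rec <- rec[!rec$hospital_id %in% dropped$hospital_id, , drop = FALSE]
  }

  pop_family_drgs <- rec$drg_code[rec$is_family]
  base <- rec |>
    dplyr::group_by(.data$hospital_id) |>
    dplyr::summarise(
      ownership = .data$ownership[1L],
      n_visits = dplyr::n(),
      n_patients = dplyr::n_distinct(.data$patient_id),
      n_episodes = sum(.data$is_family),
      avg_cost = sum(.data$cost) / dplyr::n(),
      avg_los = sum(.data$los) / dplyr::n(),
      avg_cost_per_patient = sum(.data$cost) / dplyr::n_distinct(.data$patient_id),
      pct_cc = sum(.data$is_family &
                     .data$drg_code %in% config$cc_drg_codes) /
        sum(.data$is_family),
      .groups = "drop"
    ) |>
    dplyr::mutate(specialization = .data$n_episodes / .data$n_visits)

  by_hosp <- split(rec$drg_code[rec$is_family], rec$hospital_id[rec$is_family])
  by_hosp <- by_hosp[base$hospital_id]
  r_mat <- t(vapply(by_hosp, drgMix, numeric(length(config$drg_family)),
                    drg_family = config$drg_family))
  colnames(r_mat) <- paste0("r_", config$drg_family)
  base$upcoding_index <- vapply(
    by_hosp, upcodingIndex, numeric(1),
    population_drg_codes = pop_family_drgs, config = config
  )

  profiles <- dplyr::bind_cols(base, tibble::as_tibble(r_mat))
  feat_names <- hospital_feature_names(config$drg_family)
  values <- as.matrix(profiles[, feat_names])
  rownames(values) <- profiles$hospital_id
  structure(
    list(profiles = profiles,
         features = featureMatrix(profiles$hospital_id, feat_names, values)),
    class = "hospital_profiles"
  )
}

#' @export
print.hospital_profiles <- function(x, ...) {
  cat("<hospital_profiles>", nrow(x$profiles), "hospitals x",
      length(x$features$feature_names), "features\n")
  invisible(x)
}

#' Assemble a feature matrix
#'
#' Thin container for the hospitals-by-features numeric matrix fed to feature
#' selection and clustering.
#'
#' @param unit_ids Ordered unit (hospital) identifiers.
#' @param feature_names Ordered feature names.
#' @param values Numeric matrix, units x features; no missing values allowed.
#' @param standardized Logical flag.
#' @param center,scale Optional standardization parameters (recorded by
#'   [standardizeFeatures()]).
#' @return Object of class `feature_matrix`.
#' @export
featureMatrix <- function(unit_ids, feature_names, values,
                          standardized = FALSE, center = NULL, scale = NULL) {
  values <- as.matrix(values)
  stopifnot(length(unit_ids) == nrow(values),
            length(feature_names) == ncol(values))
  if (anyNA(values)) stop("feature matrix contains missing values")
  dimnames(values) <- list(unit_ids, feature_names)
  structure(
    list(unit_ids = as.character(unit_ids),
         feature_names = as.character(feature_names),
         values = values, standardized = isTRUE(standardized),
         center = center, scale = scale),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "units x", ncol(x$values),
      "features;", if (x$standardized) "standardized" else "raw", "\n")
  invisible(x)
}

#' Z-score standardize a feature matrix
#'
#' Centers and scales every column to mean 0, variance 1. Constant columns
#' carry no distance information and are dropped with a warning; the applied
#' centers and scales are recorded for serialization.
#'
#' @param fm A [featureMatrix()].
#' @return A standardized `feature_matrix`.
#' @export
standardizeFeatures <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$standardized) return(fm)
  sds <- apply(fm$values, 2, stats::sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(fm$feature_names[constant], collapse = ", "))
  }
  vals <- fm$values[, !constant, drop = FALSE]
  ctr <- colMeans(vals)
  scl <- sds[!constant]
  vals <- sweep(sweep(vals, 2, ctr), 2, scl, "/")
  featureMatrix(fm$unit_ids, colnames(vals), vals, standardized = TRUE,
                center = ctr, scale = scl)
}

#' Write / read the hospitals dataset (CSV + JSON sidecar)
#'
#' @param hospitals A [buildHospitals()] result.
#' @param dir Output directory; writes `hospitals.csv` plus
#'   `hospitals_meta.json` recording the feature order.
#' @return `dir`, invisibly.
#' @export
writeHospitals <- function(hospitals, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(hospitals$profiles, file.path(dir, "hospitals.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(feature_names = hospitals$features$feature_names),
    file.path(dir, "hospitals_meta.json")
  )
  invisible(dir)
}

#' @rdname writeHospitals
#' @export
readHospitals <- function(dir) {
  profiles <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "hospitals.csv"),
                    colClasses = c(hospital_id = "character"))
  )
  meta <- jsonlite::read_json(file.path(dir, "hospitals_meta.json"),
                              simplifyVector = TRUE)
  values <- as.matrix(profiles[, meta$feature_names])
  rownames(values) <- profiles$hospital_id
  structure(
    list(profiles = profiles,
         features = featureMatrix(profiles$hospital_id, meta$feature_names,
                                  values)),
    class = "hospital_profiles"
  )
}
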