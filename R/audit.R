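#' Percentile position of a value within a population
#'
#' Strict-rank convention: the fraction of population values strictly below
#' the value. The population minimum sits at 0; with N distinct values the
#' maximum sits at (N-1)/N.
#'
#' @param value A single number.
#' @param population Numeric vector containing the unit's own value.
#' @return Fraction in `[0, 1)`.
#' @export
#' @examples
#' percentilePosition(5, c(1, 2, 5, 9))  # 0.5
percentilePosition <- function(value, population) {
  if (length(population) == 0L) stop("empty population")
  sum(population < value) / length(population)
}

fraud_variables <- c("avg_cost", "pct_cc", "specialization", "n_visits",
                     "upcoding_index")

#' Fraud-variable dashboard for flagged providers
#'
#' For each flagged provider, the percentile position within the provider
#' population on the five fraud-related variables: average cost per
#' hospitalization, share of with-complications DRGs, specialization, number
#' of visits, and upcoding index. Accompanied by per-variable population
#' density plots with a vertical line per outlier.
#'
#' @param hospitals A [buildHospitals()] result.
#' @param outlier_ids Hospital ids to audit (typically
#'   `screening_result$outlier_ids`).
#' @return List of class `fraud_dashboard`: `table` (tibble, one row per
#'   variable, one column per outlier) and `plots` (named list of ggplot
#'   objects).
#' @export
fraudDashboard <- function(hospitals, outlier_ids) {
  stopifnot(inherits(hospitals, "hospital_profiles"))
  prof <- hospitals$profiles
  unknown <- setdiff(outlier_ids, prof$hospital_id)
  if (length(unknown)) {
    stop("unknown outlier id(s): ", paste(unknown, collapse = ", "))
  }
  pos <- sapply(outlier_ids, function(id) {
    row <- prof[prof$hospital_id == id, ]
    vapply(fraud_variables, function(v) {
      percentilePosition(row[[v]], prof[[v]])
    }, numeric(1))
  })
  pos <- matrix(pos, nrow = length(fraud_variables),
                dimnames = list(fraud_variables, outlier_ids))
  tbl <- dplyr::bind_cols(
    tibble::tibble(variable = fraud_variables),
    tibble::as_tibble(pos)
  )
  plots <- lapply(stats::setNames(fraud_variables, fraud_variables), function(v) {
    marks <- prof[prof$hospital_id %in% outlier_ids, ]
    ggplot2::ggplot(prof, ggplot2::aes(x = .data[[v]])) +
      ggplot2::geom_density(fill = "grey80") +
      ggplot2::geom_vline(data = marks,
                          ggplot2::aes(xintercept = .data[[v]],
                                       color = .data$hospital_id)) +
      ggplot2::labs(x = v, color = "outlier",
                    title = paste("Population distribution of", v))
  })
  structure(list(table = tbl, plots = plots), class = "fraud_dashboard")
}

#' @export
print.fraud_dashboard <- function(x, ...) {
  cat("<fraud_dashboard> percentile positions\n")
  print(x$table)
  invisible(x)
}

casemix_variables <- c("age", "los", "comorbidity", "total_cost",
                       "cost_per_los", "cost_per_comorbidity")

# Per-HDC casemix quantities. Ratio denominators are guarded: same-day stays
# count as 1 day; negative comorbidity (protective weights) is floored at 0
# before the +1 offset.
hdc_casemix <- function(records, weights) {
  ci <- scoreHdc(records, weights)
  los <- los_days(records$admission_date, records$discharge_date)
  tibble::tibble(
    hospital_id = records$hospital_id,
    patient_id = records$patient_id,
    los = los,
    comorbidity = ci,
    total_cost = records$cost,
    cost_per_los = records$cost / los_denominator(los),
    cost_per_comorbidity = records$cost / (pmax(ci, 0) + 1)
  )
}

log_offset <- function(x) log(pmax(x, 0) + 1)

#' Casemix cross-validation of one flagged provider
#'
#' Compares the provider's patient and hospitalization distributions against
#' the whole population on the complexity/expensiveness variables: age,
#' length of stay, comorbidity, total cost, cost per stay-day and cost per
#' comorbidity point. All comparisons are on the log scale with a +1 offset
#' (length of stay and comorbidity can be 0). Age is patient-level (patients
#' with at least one hospitalization at the provider, using the age at first
#' hospitalization); the remaining variables are hospitalization-level, each
#' hospitalization attributed to the hospital that registered it.
#'
#' @param outlier_id One hospital id.
#' @param patients A [buildPatients()] result.
#' @param cohort The [extractCohort()] result.
#' @param weights A [readWeightTable()] object.
#' @return List of class `casemix_comparison`: `summary` (tibble with
#'   per-variable log-means and quartiles for the provider and the
#'   population) and `plots` (named list of ggplot density overlays; the
#'   vertical lines are the two log-means).
#' @export
casemixComparison <- function(outlier_id, patients, cohort, weights) {
  stopifnot(inherits(cohort, "hdc_cohort"))
  rec <- cohort$records
  if (!any(rec$hospital_id == outlier_id)) {
    stop("no hospitalizations attributable to ", outlier_id)
  }
  hdc <- hdc_casemix(rec, weights)
  own_patients <- unique(hdc$patient_id[hdc$hospital_id == outlier_id])

  value_frames <- list(
    age = tibble::tibble(
      value = patients$age_first,
      own = patients$patient_id %in% own_patients
    )
  )
  for (v in setdiff(casemix_variables, "age")) {
    value_frames[[v]] <- tibble::tibble(
      value = hdc[[v]], own = hdc$hospital_id == outlier_id
    )
  }

  summarise_one <- function(df, group) {
    x <- log_offset(df$value[if (group == "outlier") df$own else TRUE])
    tibble::tibble(group = group, n = length(x), log_mean = mean(x),
                   q25 = stats::quantile(x, 0.25, names = FALSE),
                   median = stats::median(x),
                   q75 = stats::quantile(x, 0.75, names = FALSE))
  }
  summary <- purrr::imap(value_frames, function(df, v) {
    dplyr::bind_rows(summarise_one(df, "outlier"),
                     summarise_one(df, "population")) |>
      dplyr::mutate(variable = v, .before = 1)
  }) |> dplyr::bind_rows()

  plots <- purrr::imap(value_frames, function(df, v) {
    plot_df <- dplyr::bind_rows(
      tibble::tibble(logval = log_offset(df$value[df$own]), group = "outlier"),
      tibble::tibble(logval = log_offset(df$value), group = "population")
    )
    means <- plot_df |> dplyr::group_by(.data$group) |>
      dplyr::summarise(m = mean(.data$logval), .groups = "drop")
    ggplot2::ggplot(plot_df,
                    ggplot2::aes(x = .data$logval, fill = .data$group)) +
      ggplot2::geom_density(alpha = 0.4) +
      ggplot2::geom_vline(data = means,
                          ggplot2::aes(xintercept = .data$m,
                                       color = .data$group),
                          linetype = "dashed") +
      ggplot2::labs(x = paste0("log(", v, " + 1)"),
                    title = paste(outlier_id, "vs population:", v))
  })
  structure(list(outlier_id = outlier_id, summary = summary, plots = plots),
            class = "casemix_comparison")
}

#' @export
print.casemix_comparison <- function(x, ...) {
  cat("<casemix_comparison>", x$outlier_id, "\n")
  print(x$summary)
  invisible(x)
}

#' Full Step Two audit report
#'
#' Bundles the fraud-variable dashboard and a casemix comparison for every
#' flagged provider. The report is descriptive decision support only — it
#' renders comparisons, never fraud verdicts.
#'
#' @param hospitals A [buildHospitals()] result.
#' @param patients A [buildPatients()] result.
#' @param cohort The [extractCohort()] result.
#' @param outlier_ids Hospital ids to audit.
#' @param weights A [readWeightTable()] object.
#' @return List of class `audit_report`: `dashboard` and `casemix` (named
#'   list per outlier).
#' @export
buildAudit <- function(hospitals, patients, cohort, outlier_ids,
                       weights = readWeightTable()) {
  dashboard <- fraudDashboard(hospitals, outlier_ids)
  casemix <- lapply(stats::setNames(outlier_ids, outlier_ids),
                    casemixComparison, patients = patients, cohort = cohort,
                    weights = weights)
  structure(list(dashboard = dashboard, casemix = casemix),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  print(x$dashboard)
  cat("casemix comparisons for:",
      paste(names(x$casemix), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an audit report (CSV + JSON)
#'
#' Writes the dashboard table as `fraud_percentiles.csv` and one
#' `casemix_<id>.json` per audited provider.
#'
#' @param report A [buildAudit()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeAudit <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$dashboard$table,
                   file.path(dir, "fraud_percentiles.csv"), row.names = FALSE)
  for (id in names(report$casemix)) {
    jsonlite::write_json(report$casemix[[id]]$summary,
                         file.path(dir, paste0("casemix_", id, ".json")),
                         digits = NA)
  }
  invisible(dir)
}
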