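#' Default column mapping for hospital discharge chart (HDC) tables
#'
#' Maps the canonical record fields onto the column names found in a delimited
#' file. Supply a modified mapping to [readHdc()] when your extract uses
#' different headers.
#'
#' @param ... Named overrides, e.g. `patient_id = "pat"`.
#' @return Named character vector mapping canonical field -> file column.
#' @export
#' @examples
#' hdcSchema(cost = "reimbursement_eur")
hdcSchema <- function(...) {
  schema <- c(
    event_id = "event_id", patient_id = "patient_id",
    hospital_id = "hospital_id", admission_date = "admission_date",
    discharge_date = "discharge_date", age = "age",
    diagnosis_codes = "diagnosis_codes", procedure_codes = "procedure_codes",
    drg_code = "drg_code", cost = "cost", ownership = "ownership"
  )
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(schema))
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    schema[names(override)] <- override
  }
  schema
}

hdc_fields <- function() names(hdcSchema())

# Validates a parsed HDC tibble; returns a tibble of row-level problems.
validate_hdc <- function(records) {
  problems <- list()
  note <- function(rows, msg) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<- tibble::tibble(row = rows, problem = msg)
    }
  }
  note(which(is.na(records$admission_date)), "unparsable admission_date")
  note(which(is.na(records$discharge_date)), "unparsable discharge_date")
  note(which(is.na(records$cost) | records$cost < 0), "missing or negative cost")
  note(which(is.na(records$age) | records$age < 0), "missing or negative age")
  ok_dates <- !is.na(records$admission_date) & !is.na(records$discharge_date)
  note(
    which(ok_dates & records$discharge_date < records$admission_date),
    "discharge before admission"
  )
  empty_dx <- !nzchar(trimws(ifelse(is.na(records$diagnosis_codes), "",
                                    records$diagnosis_codes)))
  note(which(empty_dx), "empty diagnosis_codes")
  note(
    which(!records$ownership %in% c("public", "private")),
    "ownership must be 'public' or 'private'"
  )
  if (length(problems)) dplyr::arrange(dplyr::bind_rows(problems), .data$row)
  else tibble::tibble(row = integer(), problem = character())
}

#' Read a hospital discharge chart table
#'
#' Reads a delimited file of hospitalization events (one row per event) into
#' the canonical HDC tibble used throughout the package. Dates must be
#' ISO-8601 (`YYYY-MM-DD`); multiple diagnosis or procedure codes are
#' `;`-separated within one field, primary diagnosis first.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Column mapping from [hdcSchema()].
#' @param sep Field separator, default `","`.
#' @return A tibble with one row per event and the canonical columns
#'   (`event_id`, `patient_id`, `hospital_id`, `admission_date`,
#'   `discharge_date`, `age`, `diagnosis_codes`, `procedure_codes`,
#'   `drg_code`, `cost`, `ownership`). Invalid rows abort with a message
#'   naming each offending row.
#' @seealso [writeHdc()], [extractCohort()]
#' @export
readHdc <- function(path, schema = hdcSchema(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = character())
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) return(empty_hdc())
  records <- tibble::tibble(
    event_id = raw[[schema[["event_id"]]]],
    patient_id = raw[[schema[["patient_id"]]]],
    hospital_id = raw[[schema[["hospital_id"]]]],
    admission_date = as.Date(raw[[schema[["admission_date"]]]], format = "%Y-%m-%d"),
    discharge_date = as.Date(raw[[schema[["discharge_date"]]]], format = "%Y-%m-%d"),
    age = suppressWarnings(as.integer(raw[[schema[["age"]]]])),
    diagnosis_codes = raw[[schema[["diagnosis_codes"]]]],
    procedure_codes = raw[[schema[["procedure_codes"]]]],
    drg_code = raw[[schema[["drg_code"]]]],
    cost = suppressWarnings(as.numeric(raw[[schema[["cost"]]]])),
    ownership = raw[[schema[["ownership"]]]]
  )
  problems <- validate_hdc(records)
  if (nrow(problems)) {
    stop("invalid HDC rows:\n",
         paste(sprintf("  row %d: %s", problems$row, problems$problem),
               collapse = "\n"))
  }
  records
}

empty_hdc <- function() {
  tibble::tibble(
    event_id = character(), patient_id = character(), hospital_id = character(),
    admission_date = as.Date(character()), discharge_date = as.Date(character()),
    age = integer(), diagnosis_codes = character(), procedure_codes = character(),
    drg_code = character(), cost = numeric(), ownership = character()
  )
}

#' Write a hospital discharge chart table
#'
#' Inverse of [readHdc()]: any valid record tibble round-trips field-identically.
#'
#' @param records HDC tibble as returned by [readHdc()] or [simulateHdc()].
#' @param path Output file path.
#' @param sep Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
writeHdc <- function(records, path, sep = ",") {
  out <- records
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  utils::write.table(out[, hdc_fields()], path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Cohort extraction configuration
#'
#' Defines the index disease, the disease-related DRG family, its
#' with-complications (CC) subset, and the observation window used by
#' [extractCohort()].
#'
#' @param disease_codes Character vector of diagnosis-code prefixes defining
#'   the index disease (e.g. `"428"` captures all heart-failure subcodes).
#' @param drg_family Character vector of DRG codes considered disease-related.
#' @param cc_drg_codes Subset of `drg_family` reimbursed as "with
#'   complications".
#' @param window_start,window_end Window bounds (coerced with [as.Date()]);
#'   membership is judged on the admission date, inclusive on both ends.
#' @param paired_drgs Optional subset of `drg_family` forming CC/non-CC pairs,
#'   used by the upcoding index; defaults to the whole family.
#' @return An object of class `cohort_config`.
#' @export
cohortConfig <- function(disease_codes, drg_family, cc_drg_codes,
                         window_start, window_end,
                         paired_drgs = drg_family) {
  if (length(disease_codes) == 0L || !all(nzchar(disease_codes))) {
    stop("config error: disease_codes must be a non-empty set of code prefixes")
  }
  if (!all(cc_drg_codes %in% drg_family)) {
    stop("config error: cc_drg_codes must be a subset of drg_family")
  }
  if (!all(paired_drgs %in% drg_family)) {
    stop("config error: paired_drgs must be a subset of drg_family")
  }
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < window_end)) {
    stop("config error: window_start must precede window_end")
  }
  structure(
    list(disease_codes = unique(disease_codes),
         drg_family = unique(drg_family),
         cc_drg_codes = unique(cc_drg_codes),
         paired_drgs = unique(paired_drgs),
         window_start = window_start, window_end = window_end),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  disease code prefixes:", paste(x$disease_codes, collapse = ", "), "\n")
  cat("  DRG family:", length(x$drg_family), "codes (",
      length(x$cc_drg_codes), "with CC )\n")
  cat("  window:", format(x$window_start), "..", format(x$window_end), "\n")
  invisible(x)
}

# TRUE where any ;-separated diagnosis code starts with any disease prefix.
matches_disease <- function(diagnosis_codes, prefixes) {
  codes <- split_codes(diagnosis_codes)
  n_per_row <- lengths(codes)
  flat <- unlist(codes, use.names = FALSE)
  hit <- rep(FALSE, length(flat))
  for (p in prefixes) hit <- hit | startsWith(flat, p)
  row_id <- rep.int(seq_along(codes), n_per_row)
  out <- rep(FALSE, length(codes))
  if (length(row_id)) out[unique(row_id[hit])] <- TRUE
  out
}

#' Extract a disease cohort from HDC records
#'
#' A patient qualifies by having at least one hospitalization whose diagnosis
#' codes match any index-disease prefix, admitted inside the window. All
#' in-window hospitalizations of qualifying patients are retained — including
#' non-disease events, which supply the denominator of the specialization
#' index.
#'
#' @param records HDC tibble (see [readHdc()]).
#' @param config A [cohortConfig()].
#' @return An object of class `hdc_cohort`: a list with `records` (the
#'   retained events, plus logical helper columns `is_disease` and
#'   `in_window`), `qualifying_patient_ids`, and `config`.
#' @export
extractCohort <- function(records, config) {
  stopifnot(inherits(config, "cohort_config"))
  in_window <- !is.na(records$admission_date) &
    records$admission_date >= config$window_start &
    records$admission_date <= config$window_end
  is_disease <- matches_disease(records$diagnosis_codes, config$disease_codes)
  qualifying <- unique(records$patient_id[in_window & is_disease])
  keep <- in_window & records$patient_id %in% qualifying
  out <- records[keep, , drop = FALSE]
  out$is_disease <- is_disease[keep]
  out$in_window <- TRUE
  structure(
    list(records = out, qualifying_patient_ids = sort(qualifying),
         config = config),
    class = "hdc_cohort"
  )
}

#' @export
print.hdc_cohort <- function(x, ...) {
  cat("<hdc_cohort>\n")
  cat(" ", nrow(x$records), "events /", length(x$qualifying_patient_ids),
      "patients /", dplyr::n_distinct(x$records$hospital_id), "hospitals\n")
  cat("  disease events:", sum(x$records$is_disease), "\n")
  invisible(x)
}

#' Write / read a cohort (CSV + JSON sidecar)
#'
#' @param cohort An `hdc_cohort`.
#' @param dir Output directory (created if needed); writes `records.csv` and
#'   `cohort.json` (config + qualifying patient ids).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeHdc(cohort$records[, hdc_fields()], file.path(dir, "records.csv"))
  meta <- list(
    config = list(
      disease_codes = cohort$config$disease_codes,
      drg_family = cohort$config$drg_family,
      cc_drg_codes = cohort$config$cc_drg_codes,
      paired_drgs = cohort$config$paired_drgs,
      window_start = format(cohort$config$window_start),
      window_end = format(cohort$config$window_end)
    ),
    qualifying_patient_ids = cohort$qualifying_patient_ids
  )
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  config <- cohortConfig(
    disease_codes = meta$config$disease_codes,
    drg_family = meta$config$drg_family,
    cc_drg_codes = meta$config$cc_drg_codes,
    window_start = meta$config$window_start,
    window_end = meta$config$window_end,
    paired_drgs = meta$config$paired_drgs
  )
  extractCohort(readHdc(file.path(dir, "records.csv")), config)
}
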