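#' Load a comorbidity weight table
#'
#' The table maps named chronic conditions to diagnosis-code prefix sets and
#' integer weights. The package ships a default table implementing the
#' combined comorbidity score of Gagne et al. (2011, J Clin Epidemiol 64:749)
#' with a simplified ICD-9-CM prefix mapping; edit the YAML or supply your
#' own file to swap scores (e.g. Charlson weights).
#'
#' @param path YAML file with entries `{condition: {prefixes: [...], weight: int}}`
#'   and an optional top-level `provenance` string. Default: the shipped table.
#' @return An object of class `weight_table`: list with `entries` (named list
#'   of `list(prefixes, weight)`) and `provenance`.
#' @export
#' @examples
#' wt <- readWeightTable()
#' length(wt$entries)
readWeightTable <- function(path = system.file("extdata",
                                               "combined_comorbidity_score.yaml",
                                               package = "drgscreen")) {
  raw <- yaml::read_yaml(path)
  provenance <- raw$provenance %||% ""
  raw$provenance <- NULL
  if (length(raw) == 0L) stop("weight table has no conditions")
  if (anyDuplicated(names(raw))) stop("condition names must be unique")
  entries <- lapply(raw, function(e) {
    prefixes <- as.character(e$prefixes)
    if (length(prefixes) == 0L) stop("each condition needs a non-empty prefix set")
    w <- e$weight
    if (length(w) != 1L || w != round(w)) stop("weights must be single integers")
    list(prefixes = prefixes, weight = as.integer(w))
  })
  structure(list(entries = entries, provenance = provenance),
            class = "weight_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.weight_table <- function(x, ...) {
  cat("<weight_table>", length(x$entries), "conditions\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Comorbidity score of each discharge
#'
#' Scores every record: each condition of the weight table contributes its
#' weight at most once per discharge, no matter how many of its codes appear
#' or in which diagnosis position (primary and secondary positions are both
#' scanned). Unmatched codes contribute 0.
#'
#' @param records HDC tibble (any tibble with a `diagnosis_codes` column of
#'   `;`-separated codes).
#' @param weights A [readWeightTable()] object.
#' @return Integer vector of per-discharge comorbidity indexes, one per row.
#' @export
scoreHdc <- function(records, weights) {
  stopifnot(inherits(weights, "weight_table"))
  codes <- split_codes(records$diagnosis_codes)
  n_per_row <- lengths(codes)
  flat <- unlist(codes, use.names = FALSE)
  row_id <- rep.int(seq_len(nrow(records)), n_per_row)
  score <- integer(nrow(records))
  for (cond in weights$entries) {
    hit <- rep(FALSE, length(flat))
    for (p in cond$prefixes) hit <- hit | startsWith(flat, p)
    rows <- unique(row_id[hit])            # condition counts once per discharge
    score[rows] <- score[rows] + cond$weight
  }
  score
}

#' Per-patient comorbidity index
#'
#' Sums a patient's per-discharge comorbidity indexes to estimate general
#' health status; an empty vector sums to 0. No normalization by the number
#' of admissions is applied.
#'
#' @param per_hdc_scores Integer vector of per-discharge scores.
#' @return A single integer.
#' @export
patientComorbidity <- function(per_hdc_scores) {
  as.integer(sum(per_hdc_scores))
}
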