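#' Configuration for ensemble principal feature analysis
#'
#' @param n_select Number of features to select (`n`).
#' @param n_runs Ensemble repetitions (`B`), default 200.
#' @param variance_retained Fraction of total variance the leading principal
#'   subspace must retain when choosing its dimension `q`; default 0.90.
#' @param seed Integer seed; per-run seeds are derived deterministically.
#' @return Object of class `pfa_config`.
#' @export
pfaConfig <- function(n_select, n_runs = 200L, variance_retained = 0.90,
                      seed = 1L) {
  stopifnot(n_select >= 1, n_runs >= 1,
            variance_retained > 0, variance_retained <= 1)
  structure(list(n_select = as.integer(n_select), n_runs = as.integer(n_runs),
                 variance_retained = variance_retained, seed = as.integer(seed)),
            class = "pfa_config")
}

# k-means on loading rows that tolerates duplicated rows: when fewer distinct
# rows than groups exist, distinct rows are clustered instead and the caller
# pads the selection.
cluster_rows <- function(rows, k, nstart = 5L) {
  uniq <- unique(rows)
  if (nrow(uniq) <= k) {
    centers <- uniq
    assignment <- apply(rows, 1, function(x) {
      which.min(colSums((t(centers) - x)^2))
    })
    return(list(cluster = assignment, centers = centers))
  }
  km <- stats::kmeans(rows, centers = k, nstart = nstart, iter.max = 50L)
  list(cluster = km$cluster, centers = km$centers)
}

#' Single principal feature analysis run
#'
#' Principal feature analysis: compute the principal decomposition of the
#' standardized matrix, keep the `q` leading components retaining at least
#' `variance_retained` of total variance, represent each feature by its
#' q-dimensional loading row, partition loading rows into `n_select` groups
#' by k-means, and keep from each group the feature closest to the group
#' mean. The k-means restarts are the run-to-run stochasticity the ensemble
#' averages over.
#'
#' @param X A standardized [featureMatrix()].
#' @param n_select Number of features to select.
#' @param variance_retained Subspace variance fraction, default 0.90.
#' @param seed Integer seed (determinism contract: same seed, same selection).
#' @return Character vector of selected feature names (unordered set).
#' @export
pfaOnce <- function(X, n_select, variance_retained = 0.90, seed = 1L) {
  stopifnot(inherits(X, "feature_matrix"))
  if (!X$standardized) stop("PFA requires a standardized feature matrix")
  p <- ncol(X$values)
  if (n_select >= p) {
    if (n_select > p) warning("n_select exceeds feature count; selecting all")
    return(X$feature_names)
  }
  set.seed(seed)
  pc <- stats::prcomp(X$values, center = FALSE, scale. = FALSE)
  var_frac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  q <- which(var_frac >= variance_retained)[1L]
  loadings <- pc$rotation[, seq_len(q), drop = FALSE]
  # canonical (lexicographic) row order makes the selection invariant to the
  # input column order: k-means seeds initial centers by row index
  ord <- order(X$feature_names)
  loadings <- loadings[ord, , drop = FALSE]
  fnames <- X$feature_names[ord]
  cl <- cluster_rows(loadings, n_select)
  reps <- character(0)
  for (g in sort(unique(cl$cluster))) {
    members <- which(cl$cluster == g)
    center <- colMeans(loadings[members, , drop = FALSE])
    d <- sqrt(colSums((t(loadings[members, , drop = FALSE]) - center)^2))
    # tie-break: lexicographically first among equally close features
    cand <- fnames[members]
    best <- cand[order(d, cand)][1L]
    reps <- c(reps, best)
  }
  if (length(reps) < n_select) {   # duplicated loading rows collapsed groups
    pad <- setdiff(sort(X$feature_names), reps)
    reps <- c(reps, pad[seq_len(n_select - length(reps))])
  }
  reps
}

#' Ensemble principal feature analysis
#'
#' Runs [pfaOnce()] `n_runs` times with derived seeds, counts how many times
#' each feature appears, and keeps the `n_select` most frequent features.
#' Repetition stabilizes the greedy single-run selection. Ties at the
#' selection boundary are broken by higher count, then lexicographic feature
#' name.
#'
#' @param X A standardized [featureMatrix()].
#' @param config A [pfaConfig()].
#' @return Object of class `selection_result`: `selected` (ordered character
#'   vector) and `appearance_counts` (named integer vector over all features).
#' @export
pfaEnsemble <- function(X, config) {
  stopifnot(inherits(config, "pfa_config"))
  counts <- stats::setNames(integer(length(X$feature_names)), X$feature_names)
  for (b in seq_len(config$n_runs)) {
    sel <- pfaOnce(X, config$n_select, config$variance_retained,
                   seed = derive_seed(config$seed, b))
    counts[sel] <- counts[sel] + 1L
  }
  ord <- order(-counts, names(counts))
  selected <- names(counts)[ord][seq_len(min(config$n_select, length(counts)))]
  structure(list(selected = selected, appearance_counts = counts,
                 n_runs = config$n_runs),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", length(x$selected), "features over", x$n_runs,
      "runs\n")
  cat("  top:", paste(utils::head(x$selected, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON (audit trail)
#'
#' @param sel A [pfaEnsemble()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeSelection <- function(sel, path) {
  jsonlite::write_json(
    list(selected = sel$selected,
         appearance_counts = as.list(sel$appearance_counts),
         n_runs = sel$n_runs),
    path, auto_unbox = TRUE
  )
  invisible(path)
}
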