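#' Mean silhouette width of a clustering
#'
#' Standard silhouette with Euclidean distances: for point i with
#' within-cluster mean distance a(i) and smallest other-cluster mean distance
#' b(i), s(i) = (b - a) / max(a, b), averaged over all points. Points in
#' singleton clusters contribute 0 by convention, as does a point coinciding
#' with all members of its comparison (max(a, b) = 0).
#'
#' @param X Numeric matrix (units x features) or a [featureMatrix()].
#' @param labels Cluster assignment, one per row of `X`.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
meanSilhouette <- function(X, labels) {
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  labels <- as.vector(labels)
  stopifnot(nrow(X) == length(labels))
  groups <- split(seq_len(nrow(X)), labels)
  if (length(groups) < 2L) stop("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(X))
  # mean distance of every point to every cluster
  M <- vapply(groups, function(idx) rowMeans(D[, idx, drop = FALSE]),
              numeric(nrow(X)))
  sizes <- lengths(groups)
  own <- match(labels, names(groups))
  n_own <- sizes[own]
  # within-cluster mean excludes the point itself
  a <- ifelse(n_own > 1L, M[cbind(seq_len(nrow(X)), own)] * n_own / (n_own - 1L), NA)
  Mb <- M
  Mb[cbind(seq_len(nrow(X)), own)] <- Inf
  b <- apply(Mb, 1, min)
  s <- ifelse(n_own == 1L, 0,
              ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b)))
  mean(s)
}

#' Grid-search configuration for the screening step
#'
#' @param n_grid Candidate numbers of selected features, default
#'   `c(20, 30, 40)`.
#' @param k_grid Candidate numbers of clusters, default `5:8` (all >= 2).
#' @param pfa_runs Ensemble repetitions per feature count (`B`), default 200.
#' @param variance_retained Principal-subspace variance fraction for PFA.
#' @param use_feature_selection If `FALSE`, `n_grid` is ignored and all
#'   features are used (the robustness variant).
#' @param percentile Flagging percentile of the local-distance distribution,
#'   default 95.
#' @param seed Integer seed driving all stochastic stages.
#' @return Object of class `grid_config`.
#' @export
gridConfig <- function(n_grid = c(20L, 30L, 40L), k_grid = 5:8,
                       pfa_runs = 200L, variance_retained = 0.90,
                       use_feature_selection = TRUE, percentile = 95,
                       seed = 1L) {
  stopifnot(length(n_grid) >= 1, length(k_grid) >= 1, all(k_grid >= 2),
            percentile > 0, percentile < 100)
  structure(list(n_grid = as.integer(sort(unique(n_grid))),
                 k_grid = as.integer(sort(unique(k_grid))),
                 pfa_runs = as.integer(pfa_runs),
                 variance_retained = variance_retained,
                 use_feature_selection = isTRUE(use_feature_selection),
                 percentile = percentile, seed = as.integer(seed)),
            class = "grid_config")
}

# k-means with derived seed; one re-seed on failure (degenerate init), then
# NULL so the caller can skip the cell.
fit_kmeans <- function(values, k, seed) {
  for (attempt in 1:2) {
    set.seed(derive_seed(seed, attempt))
    km <- tryCatch(
      stats::kmeans(values, centers = k, nstart = 10L, iter.max = 100L),
      error = function(e) NULL
    )
    if (!is.null(km) && all(km$size > 0L)) return(km)
  }
  NULL
}

#' Silhouette-maximizing grid search over (n, k)
#'
#' For every combination of feature count `n` (via [pfaEnsemble()]) and
#' cluster count `k` (via k-means with 10 restarts), records the mean
#' silhouette width and keeps the pair attaining the maximum. Exact ties are
#' broken toward the smaller `k`, then the smaller `n`. Cells with `k` not
#' below the number of units, or whose clustering degenerates to an empty
#' cluster after one re-seed, are skipped with a warning. Deterministic under
#' `config$seed`.
#'
#' @param X A [featureMatrix()]; standardized internally if not already.
#' @param config A [gridConfig()].
#' @return Object of class `screening_fit`: `best_n`, `best_k`,
#'   `selected_features`, `labels`, `centroids`, `silhouette_mean`,
#'   `grid_table` (tibble n, k, silhouette), `selection` (the winning
#'   [pfaEnsemble()] result, or `NULL` without feature selection), `X_selected`.
#' @export
gridSearch <- function(X, config) {
  stopifnot(inherits(X, "feature_matrix"), inherits(config, "grid_config"))
  X <- standardizeFeatures(X)
  n_units <- nrow(X$values)
  p <- ncol(X$values)

  if (config$use_feature_selection) {
    n_grid <- config$n_grid
    selections <- lapply(seq_along(n_grid), function(i) {
      pfaEnsemble(X, pfaConfig(min(n_grid[i], p), n_runs = config$pfa_runs,
                               variance_retained = config$variance_retained,
                               seed = derive_seed(config$seed, i, 0)))
    })
  } else {
    n_grid <- p
    selections <- list(NULL)
  }

  rows <- list()
  fits <- list()
  for (i in seq_along(n_grid)) {
    feats <- if (is.null(selections[[i]])) X$feature_names
             else selections[[i]]$selected
    Xi <- X$values[, feats, drop = FALSE]
    for (j in seq_along(config$k_grid)) {
      k <- config$k_grid[j]
      if (k >= n_units) {
        warning("skipping grid cell (n=", n_grid[i], ", k=", k,
                "): k must be below the number of units")
        next
      }
      km <- fit_kmeans(Xi, k, derive_seed(config$seed, i, j))
      if (is.null(km)) {
        warning("skipping grid cell (n=", n_grid[i], ", k=", k,
                "): degenerate clustering")
        next
      }
      sil <- meanSilhouette(Xi, km$cluster)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = n_grid[i], k = k, silhouette = sil
      )
      fits[[paste(i, j)]] <- list(i = i, km = km, feats = feats)
    }
  }
  if (!length(rows)) stop("no valid grid cell")
  grid_table <- dplyr::bind_rows(rows)
  # argmax with tie-break: higher silhouette, then smaller k, then smaller n
  best <- grid_table[order(-grid_table$silhouette, grid_table$k, grid_table$n), ][1L, ]
  key <- paste(match(best$n, n_grid), match(best$k, config$k_grid))
  fit <- fits[[key]]
  structure(
    list(best_n = best$n, best_k = best$k,
         selected_features = fit$feats,
         labels = stats::setNames(fit$km$cluster, X$unit_ids),
         centroids = fit$km$centers,
         silhouette_mean = best$silhouette,
         grid_table = grid_table,
         selection = selections[[fit$i]],
         X_selected = X$values[, fit$feats, drop = FALSE]),
    class = "screening_fit"
  )
}

#' Euclidean distance of each unit to its own cluster centroid
#'
#' @param X_selected Numeric matrix in the clustering space (units x selected
#'   features).
#' @param labels Integer cluster assignment per unit.
#' @param centroids Numeric matrix, one row per cluster.
#' @return Named numeric vector of local distances.
#' @export
localDistances <- function(X_selected, labels, centroids) {
  X_selected <- as.matrix(X_selected)
  centroids <- as.matrix(centroids)
  if (ncol(X_selected) != ncol(centroids)) {
    stop("dimension mismatch between units and centroids")
  }
  stopifnot(nrow(X_selected) == length(labels),
            all(labels >= 1), all(labels <= nrow(centroids)))
  d <- sqrt(rowSums((X_selected - centroids[labels, , drop = FALSE])^2))
  stats::setNames(d, rownames(X_selected))
}

#' Flag locally outlying units by a percentile threshold
#'
#' The threshold is the empirical percentile of the local-distance
#' distribution, computed with linear interpolation between order statistics;
#' units strictly above it are flagged. With N distinct distances this flags
#' exactly `N - floor(1 + (p/100) * (N - 1))` units — 10 of 183 at the
#' default 95th percentile.
#'
#' @param distances Named numeric vector of local distances.
#' @param percentile Percentile in (0, 100), default 95.
#' @return List: `threshold`, `outlier_ids` (names of flagged units),
#'   `flagged` (logical vector aligned with `distances`).
#' @export
flagOutliers <- function(distances, percentile = 95) {
  if (length(distances) < 2L) stop("need at least two distances")
  threshold <- stats::quantile(distances, percentile / 100, type = 7,
                               names = FALSE)
  flagged <- distances > threshold
  list(threshold = threshold,
       outlier_ids = names(distances)[flagged],
       flagged = flagged)
}

#' Step One: screen providers for local outliers
#'
#' Composes the grid search, local-distance computation and percentile
#' flagging. Distances are measured in the same standardized selected-feature
#' space the k-means ran in. Re-running with the same seed reproduces the
#' result exactly.
#'
#' @param X A [featureMatrix()] of hospital behavioral features.
#' @param config A [gridConfig()].
#' @return Object of class `screening_result` extending the [gridSearch()]
#'   fit with `distances`, `threshold`, `outlier_ids` and `percentile`.
#' @export
screen <- function(X, config = gridConfig()) {
  fit <- gridSearch(X, config)
  d <- localDistances(fit$X_selected, fit$labels, fit$centroids)
  fl <- flagOutliers(d, config$percentile)
  structure(
    c(unclass(fit),
      list(distances = d, threshold = fl$threshold,
           outlier_ids = fl$outlier_ids, percentile = config$percentile)),
    class = c("screening_result", "screening_fit")
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result>\n")
  cat("  best (n, k): (", x$best_n, ",", x$best_k, ")  mean silhouette:",
      round(x$silhouette_mean, 4), "\n")
  cat("  flagged", length(x$outlier_ids), "of", length(x$distances),
      "units above the", x$percentile, "th-percentile distance",
      round(x$threshold, 4), "\n")
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Local-distance distribution plot with flagging threshold
#'
#' Histogram of distances to the own-cluster centroid; the dashed vertical
#' line marks the flagging threshold.
#'
#' @param result A [screen()] result.
#' @param bins Histogram bins, default 30.
#' @return A ggplot object.
#' @export
plotDistances <- function(result, bins = 30) {
  df <- tibble::tibble(distance = as.numeric(result$distances))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = result$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Local distance to own centroid", y = "Hospitals",
                  title = sprintf("Local distances (threshold = %.3f, %dth percentile)",
                                  result$threshold, round(result$percentile)))
}

#' Serialize a screening result (JSON + CSV)
#'
#' Writes `screening.json` (chosen parameters, threshold, outliers),
#' `units.csv` (per-hospital label, distance, flag) and `grid.csv`.
#'
#' @param result A [screen()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeScreening <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(best_n = result$best_n, best_k = result$best_k,
         silhouette_mean = result$silhouette_mean,
         percentile = result$percentile, threshold = result$threshold,
         selected_features = result$selected_features,
         outlier_ids = result$outlier_ids),
    file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(
    tibble::tibble(hospital_id = names(result$distances),
                   cluster = as.integer(result$labels),
                   distance = as.numeric(result$distances),
                   outlier = names(result$distances) %in% result$outlier_ids),
    file.path(dir, "units.csv"), row.names = FALSE
  )
  utils::write.csv(result$grid_table, file.path(dir, "grid.csv"),
                   row.names = FALSE)
  invisible(dir)
}
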