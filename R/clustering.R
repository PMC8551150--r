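#' Standardize a feature matrix
#'
#' Per-column z-scores across the whole dataset, so that all 14 features
#' weigh equally in the squared-Euclidean distance. The root-mean-square
#' deviation (divisor n) is used, so a two-value column (1, 3) maps to
#' (-1, 1); the divisor choice rescales every column by the same factor and
#' therefore leaves the clustering geometry unchanged. Zero-variance columns
#' are left at 0 with a warning. Invalid features have already been
#' zero-filled on the raw scale by [assemble_features()].
#'
#' @param x numeric matrix or data.frame of features.
#' @return standardized matrix with the input's dimnames.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning("zero-variance feature(s) left at 0: ",
            paste(colnames(x)[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  z[, zero] <- 0
  z
}

#' K-means with restarts (squared Euclidean)
#'
#' Lloyd's algorithm, `replicates` restarts with centers drawn as random
#' distinct rows from a dedicated RNG substream; the restart with the lowest
#' total within-cluster sum of squares wins. A restart that collapses to an
#' empty cluster is re-initialized (fresh random rows). Deterministic given
#' `seed`.
#'
#' @param x standardized feature matrix.
#' @param k number of clusters (`2 <= k <= nrow(x)`).
#' @param replicates number of restarts.
#' @param max_iter Lloyd iteration cap.
#' @param seed RNG seed for the restarts.
#' @return list with `labels`, `centroids`, `tot_withinss`.
#' @export
kmeans_fit <- function(x, k, replicates = 10, max_iter = 1000, seed = 1) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k must not exceed the number of rows")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- NULL
    for (attempt in 1:20) {
      centers <- x[sample.int(nrow(x), k), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = centers, iter.max = max_iter,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for k = ", k)
  list(labels = as.integer(best$cluster), centroids = best$centers,
       tot_withinss = best$tot.withinss)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion, normalized by
#' degrees of freedom: `(SSB / (k - 1)) / (SSW / (n - k))`. Larger is
#' better; `Inf` when all within-cluster scatter vanishes.
#'
#' @param x feature matrix.
#' @param labels integer cluster labels (each cluster non-empty, k >= 2).
#' @return the index value.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(x)
  if (k < 2) stop("Calinski-Harabasz is undefined for k = 1")
  grand <- colMeans(x)
  ssw <- 0; ssb <- 0
  for (g in seq_len(k)) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
    ssb <- ssb + nrow(xi) * sum((ci - grand)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Select the number of clusters by Calinski-Harabasz
#'
#' Fits [kmeans_fit()] for every k in `k_range`, scores each partition with
#' [calinski_harabasz()], and keeps the k with the highest score (ties go to
#' the smallest k). The full CH-vs-k curve is returned for inspection.
#'
#' @param x standardized feature matrix.
#' @param k_range candidate cluster counts (all >= 2).
#' @param seed RNG seed (one substream per k).
#' @param ... passed to [kmeans_fit()].
#' @return object of class `cluster_result`: `labels`, `centroids`,
#'   `selected_k`, `ch` (data.frame k/score), `seed`.
#' @export
select_k <- function(x, k_range = 2:10, seed = 1, ...) {
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range must be >= 2")
  fits <- vector("list", length(k_range))
  scores <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- kmeans_fit(x, k_range[i], seed = seed + k_range[i], ...)
    scores[i] <- calinski_harabasz(x, fits[[i]]$labels)
  }
  best <- which.max(scores)
  structure(list(labels = fits[[best]]$labels,
                 centroids = fits[[best]]$centroids,
                 selected_k = k_range[best],
                 ch = data.frame(k = k_range, score = scores),
                 fits = fits, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> selected k = %d (CH = %.1f)\n",
              x$selected_k, max(x$ch$score)))
  print(x$ch, row.names = FALSE)
  invisible(x)
}

#' Cluster a per-condition feature table
#'
#' Convenience wrapper: extracts the 14 feature columns from an
#' [assemble_features()] table, standardizes them, and runs [select_k()].
#'
#' @param features per-condition feature table.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed.
#' @param ... passed to [select_k()].
#' @return `cluster_result` with a `conditions` data.frame (keys + cluster
#'   label) attached.
#' @export
cluster_conditions <- function(features, k_range = 2:10, seed = 1, ...) {
  z <- standardize_features(features[feature_names()])
  res <- select_k(z, k_range = k_range, seed = seed, ...)
  res$conditions <- cbind(
    features[c("motif_id", "rs_rate", "fs_rate", "lts_rate")],
    cluster = res$labels)
  res$standardized <- z
  res
}
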