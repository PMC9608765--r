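#' Pooled shrinkage covariance for Mahalanobis distances
#'
#' Estimates a single covariance over all points and regularises it toward a
#' scaled identity: `Sigma = (1 - gamma) * S + gamma * trace(S)/d * I`. The
#' shrinkage keeps the estimate positive-definite (and hence invertible) even
#' with near-collinear feature columns.
#'
#' @param points n x d numeric matrix.
#' @param shrinkage Shrinkage weight gamma in \[0, 1\].
#' @return List with `sigma`, its inverse `inv`, and the condition number
#'   `kappa` of `sigma`.
#' @export
pooled_covariance <- function(points, shrinkage = 0.1) {
  points <- as.matrix(points)
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must be in [0, 1]", call. = FALSE)
  d <- ncol(points)
  S <- stats::cov(points)
  sigma <- (1 - shrinkage) * S + shrinkage * (sum(diag(S)) / d) * diag(d)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev))
    stop("pooled covariance is singular; increase shrinkage above 0",
         call. = FALSE)
  list(sigma = sigma, inv = solve(sigma), kappa = max(ev) / min(ev))
}

#' Mahalanobis distance between two points
#'
#' `sqrt((x - y)' Sigma^{-1} (x - y))`; with the identity matrix as
#' `inverse_covariance` this is exactly the Euclidean distance.
#'
#' @param x,y Numeric vectors of equal length.
#' @param inverse_covariance Positive-definite d x d inverse covariance.
#' @return Nonnegative scalar.
#' @export
mahalanobis_distance <- function(x, y, inverse_covariance) {
  if (length(x) != length(y))
    stop("x and y must have the same dimension", call. = FALSE)
  d <- x - y
  sqrt(max(0, drop(t(d) %*% inverse_covariance %*% d)))
}

# full pairwise distance matrix under the chosen metric
pairwise_distances <- function(points, metric = c("euclidean", "mahalanobis"),
                               shrinkage = 0.1) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (metric == "mahalanobis") {
    pc <- pooled_covariance(points, shrinkage)
    # whitening: with Sigma = R'R (Cholesky), ||R^{-T}(x-y)|| is the
    # Mahalanobis distance, so Euclidean distance on X R^{-1} matches it
    points <- points %*% solve(chol(pc$sigma))
  }
  as.matrix(stats::dist(points))
}

#' Per-point silhouette values
#'
#' For point i in cluster C_I, `a_i` is its mean distance to the other
#' members of C_I (divisor `|C_I| - 1`) and `b_i` the smallest mean distance
#' to the points of any other cluster; the silhouette is
#' `s_i = (b_i - a_i) / max(a_i, b_i)`, with `s_i = 0` for members of
#' singleton clusters. Values lie in \[-1, 1\]; positive values mean the
#' point sits closer to its own cluster than to any other.
#'
#' @param points n x d numeric matrix (by convention, per-window MAV vectors
#'   with one dimension per sEMG channel).
#' @param labels Cluster (posture) label per row.
#' @param metric `"mahalanobis"` (pooled shrinkage covariance) or
#'   `"euclidean"`.
#' @param shrinkage Covariance shrinkage for the Mahalanobis metric.
#' @param D Optional precomputed n x n distance matrix overriding `metric`.
#' @return List with per-point `a`, `b`, `s`, per-cluster mean silhouettes
#'   `cluster_means`, and the cluster sizes.
#' @export
silhouette_values <- function(points, labels,
                              metric = c("mahalanobis", "euclidean"),
                              shrinkage = 0.1, D = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(D)) {
    if (nrow(as.matrix(points)) != n)
      stop("points and labels disagree in length", call. = FALSE)
    D <- pairwise_distances(points, match.arg(metric), shrinkage)
  }
  clusters <- unique(labels)
  if (length(clusters) < 2L)
    stop("silhouette needs >= 2 clusters (b_i is a minimum over *other* ",
         "clusters)", call. = FALSE)
  sizes <- table(labels)[clusters]
  # column sums of D over each cluster, n x K
  sums <- vapply(clusters, function(cl)
    rowSums(D[, labels == cl, drop = FALSE]), numeric(n))
  own <- match(labels, clusters)
  idx <- cbind(seq_len(n), own)
  a <- sums[idx] / pmax(1L, as.integer(sizes[own]) - 1L)
  mean_to <- sweep(sums, 2L, as.numeric(sizes), `/`)
  mean_to[idx] <- Inf
  b <- apply(mean_to, 1L, min)
  s <- ifelse(as.integer(sizes[own]) == 1L, 0, (b - a) / pmax(a, b))
  s[is.nan(s)] <- 0  # a = b = 0: point indistinguishable from both clusters
  cm <- vapply(clusters, function(cl) mean(s[labels == cl]), numeric(1))
  list(a = a, b = b, s = s, cluster_means = cm,
       sizes = as.integer(sizes), clusters = clusters)
}

#' Silhouette coefficient of a labeled point set
#'
#' The cluster-quality statistic used for tracking training-induced
#' variability reduction: per-point silhouettes are averaged within each
#' posture cluster and the coefficient is the maximum of those per-cluster
#' means. The conventional all-point mean silhouette is reported alongside as
#' a secondary statistic.
#'
#' @inheritParams silhouette_values
#' @return Object of class `silhouette_report`: `SC` (max per-cluster mean),
#'   `mean_s` (all-point mean), `cluster_means`, per-point `a`, `b`, `s`,
#'   `metric` and `shrinkage`.
#' @export
silhouette_coefficient <- function(points, labels,
                                   metric = c("mahalanobis", "euclidean"),
                                   shrinkage = 0.1, D = NULL) {
  metric <- match.arg(metric)
  sv <- silhouette_values(points, labels, metric, shrinkage, D)
  structure(c(sv, list(SC = max(sv$cluster_means), mean_s = mean(sv$s),
                       metric = metric, shrinkage = shrinkage)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("<silhouette_report> SC = %.4f (max of %d cluster means; %s)\n",
              x$SC, length(x$cluster_means), x$metric))
  cat(sprintf("  all-point mean silhouette: %.4f\n", x$mean_s))
  invisible(x)
}

#' Per-window MAV point set for cluster analysis
#'
#' Extracts the MAV columns of a feature matrix as the point cloud fed to the
#' silhouette and embedding analyses (one dimension per channel), with the
#' posture labels.
#'
#' @param features A `semg_features` object.
#' @return List with `points` (windows x channels matrix) and `labels`.
#' @export
mav_point_set <- function(features) {
  stopifnot(inherits(features, "semg_features"))
  cols <- grep("\\.MAV$", colnames(features$x))
  list(points = features$x[, cols, drop = FALSE], labels = features$posture)
}

#' Two-dimensional t-SNE embedding of a point set
#'
#' Nonlinear 2-D visualisation of the multichannel point cloud, delegated to
#' a standard t-distributed stochastic neighbour embedding implementation.
#' Deterministic given the seed; coordinates are centred at the origin.
#'
#' @param points n x d numeric matrix.
#' @param perplexity t-SNE perplexity; requires `n > 3 * perplexity + 1`.
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return Object of class `semg_embedding`: `coords` (n x 2), `perplexity`,
#'   `seed`, and the final KL divergence `kl`.
#' @export
embed_2d <- function(points, perplexity = 30, seed = 1L, max_iter = 500L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= 3 * perplexity + 1)
    stop("perplexity too large: need n > 3 * perplexity + 1 = ",
         3 * perplexity + 1, " points, got ", n, call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(points, dims = 2, perplexity = perplexity,
                      max_iter = as.integer(max_iter), pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  coords <- sweep(fit$Y, 2L, colMeans(fit$Y))
  structure(list(coords = coords, perplexity = perplexity, seed = seed,
                 kl = utils::tail(fit$itercosts, 1L)),
            class = "semg_embedding")
}

#' @export
print.semg_embedding <- function(x, ...) {
  cat(sprintf("<semg_embedding> %d points, perplexity %g, KL %.4f\n",
              nrow(x$coords), x$perplexity, x$kl))
  invisible(x)
}
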