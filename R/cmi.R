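#' k-nearest-neighbour mutual information estimate
#'
#' Kraskov-Stoegbauer-Grassberger (algorithm 1) estimator of `I(X;Y)` in
#' nats, using the Chebyshev norm.  The raw estimate can be slightly
#' negative on independent data; callers that feed ratios clamp at zero via
#' `clamp = TRUE`.
#'
#' @param x,y numeric vectors or matrices (rows = points) with equal numbers
#'   of points; at least 50 points.
#' @param k neighbour count; must satisfy `k < n/10`.
#' @param clamp if `TRUE`, negative raw estimates are clamped to 0.
#' @param jitter amplitude of seeded uniform jitter added to break ties in
#'   neighbour distances (use for quantized/discretized signals); 0 disables.
#' @param jitter_seed seed for the jitter stream.
#' @return the estimate in nats.
#' @export
estimate_mi <- function(x, y, k = 4L, clamp = FALSE,
                        jitter = 0, jitter_seed = 1L) {
  p <- prep_clouds(list(x, y), k, jitter, jitter_seed)
  v <- .mi_knn_cpp(p[[1]], p[[2]], as.integer(k))
  if (clamp) max(v, 0) else v
}

#' k-nearest-neighbour conditional mutual information estimate
#'
#' Frenzel-Pompe extension of the KSG estimator: `I(X;Y|Z)` in nats.  A
#' zero-column `z` reduces exactly to [estimate_mi()].
#'
#' @inheritParams estimate_mi
#' @param z conditioning variable, a numeric vector or matrix; may have zero
#'   columns.
#' @return the estimate in nats.
#' @export
estimate_cmi <- function(x, y, z, k = 4L, clamp = FALSE,
                         jitter = 0, jitter_seed = 1L) {
  z <- as_cloud(z)
  if (ncol(z) == 0L)
    return(estimate_mi(x, y, k = k, clamp = clamp,
                       jitter = jitter, jitter_seed = jitter_seed))
  p <- prep_clouds(list(x, y, z), k, jitter, jitter_seed)
  v <- .cmi_knn_cpp(p[[1]], p[[2]], p[[3]], as.integer(k))
  if (clamp) max(v, 0) else v
}

as_cloud <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), 0L, 0L))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

prep_clouds <- function(clouds, k, jitter, jitter_seed) {
  clouds <- lapply(clouds, as_cloud)
  n <- unique(vapply(clouds, nrow, 0L))
  if (length(n) != 1L)
    stop("point clouds have mismatched numbers of points", call. = FALSE)
  if (n < 50L)
    stop("at least 50 points are required (got ", n, ")", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of points", call. = FALSE)
  if (k >= n / 10)
    stop("k must be below n/10 for a meaningful estimate", call. = FALSE)
  for (cl in clouds) if (any(!is.finite(cl)))
    stop("point cloud contains NaN/Inf", call. = FALSE)
  if (jitter > 0) {
    clouds <- with_seed(jitter_seed, lapply(clouds, function(cl) {
      cl + matrix(runif(length(cl), -jitter, jitter), nrow(cl), ncol(cl))
    }))
  }
  clouds
}
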