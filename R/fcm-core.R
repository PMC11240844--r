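#' Seeded random initial fuzzy partition
#'
#' Draws a c x N matrix of positive uniform variates and normalizes each
#' pixel's column to sum to one, giving a valid random fuzzy partition.
#'
#' @param n_pixels Number of pixels N.
#' @param n_clusters Number of clusters c (must satisfy c <= N).
#' @param seed Optional integer seed; the same seed reproduces the matrix.
#' @return A c x N membership matrix with unit column sums.
#' @export
initialize_partition <- function(n_pixels, n_clusters, seed = NULL) {
  if (n_clusters < 1L) stop("n_clusters must be >= 1", call. = FALSE)
  if (n_clusters > n_pixels)
    stop("more clusters than pixels", call. = FALSE)
  if (n_clusters == 1L) return(matrix(1, 1L, n_pixels))
  u <- local_seed(seed, matrix(stats::runif(n_clusters * n_pixels, min = .Machine$double.eps),
                               n_clusters, n_pixels))
  sweep(u, 2L, colSums(u), "/")
}

#' Fuzzy C-means membership update
#'
#' Computes the FCM membership degrees
#' \deqn{\mu_{ik} = 1 / \sum_j (d_{ik} / d_{jk})^{2/(m-1)}}
#' with d the absolute difference between pixel intensity and cluster center.
#' A pixel at zero distance from one or more centers receives crisp
#' membership 1 on the first such cluster (by index) and 0 elsewhere.
#'
#' @param pixels Numeric vector of pixel intensities (row-major flattened).
#' @param centers Numeric vector of cluster centers.
#' @param m Fuzzifier, > 1.
#' @return A c x N membership matrix with unit column sums.
#' @export
#' @examples
#' fcm_membership(0.25, c(0, 1), m = 2)  # c(0.9, 0.1)
fcm_membership <- function(pixels, centers, m = 2) {
  check_fuzzifier(m)
  if (any(!is.finite(centers))) stop("centers must be finite", call. = FALSE)
  d <- abs(outer(centers, pixels, "-"))
  pw <- d^(-2 / (m - 1))
  u <- sweep(pw, 2L, colSums(pw), "/")
  zero_cols <- which(colSums(d == 0) > 0L)
  if (length(zero_cols)) {
    first_zero <- apply(d[, zero_cols, drop = FALSE] == 0, 2L, which.max)
    u[, zero_cols] <- 0
    u[cbind(first_zero, zero_cols)] <- 1
  }
  u
}

#' Weighted-mean cluster center update
#'
#' Each center is the weighted mean of the pixel intensities with weights
#' w^m; the same functional form serves the plain FCM centers, the csFCM
#' "new" centers, and the csIFCM joint centers (with the role-appropriate
#' membership matrix as weights).
#'
#' @param pixels Numeric vector of intensities.
#' @param weights c x N membership matrix.
#' @param m Fuzzifier, > 1.
#' @param prev Optional previous centers; a cluster whose weights are all
#'   zero keeps its previous center (with a warning) instead of failing.
#' @return Numeric vector of c centers, each within the range of `pixels`.
#' @export
update_centers <- function(pixels, weights, m = 2, prev = NULL) {
  check_fuzzifier(m)
  if (ncol(weights) != length(pixels))
    stop("weights and pixels disagree on N", call. = FALSE)
  wm <- weights^m
  den <- rowSums(wm)
  centers <- as.vector(wm %*% pixels) / den
  dead <- den == 0
  if (any(dead)) {
    if (is.null(prev))
      stop("cluster with all-zero weights and no previous center", call. = FALSE)
    warning("degenerate cluster: center held at previous value", call. = FALSE)
    centers[dead] <- prev[dead]
  }
  centers
}

#' Fuzzy C-means objective function
#'
#' \deqn{J = \sum_i \sum_k \mu_{ik}^m \, d(x_k, v_i)^2}
#'
#' @inheritParams update_centers
#' @param membership c x N membership matrix satisfying the unit column-sum
#'   constraint.
#' @param centers Numeric vector of c centers.
#' @return A single non-negative number.
#' @export
fcm_objective <- function(pixels, membership, centers, m = 2) {
  check_fuzzifier(m)
  if (nrow(membership) != length(centers) ||
      ncol(membership) != length(pixels))
    stop("shape mismatch between pixels, membership and centers", call. = FALSE)
  d2 <- (outer(centers, pixels, "-"))^2
  sum(membership^m * d2)
}

check_fuzzifier <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 1)
    stop("fuzzifier m must be a single number > 1", call. = FALSE)
  invisible(m)
}
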