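#' Clustering configuration
#'
#' Bundles every hyperparameter of the four segmentation algorithms.
#' Defaults follow common practice for fuzzy segmentation of brain MR
#' slices: four tissue classes, fuzzifier m = 2, membership weights
#' p = 1 / q = 2, Yager parameter alpha = 0.85, a 3x3 conditioning window,
#' and termination when the monitored membership matrix changes by at most
#' 1e-5 between iterations.
#'
#' @param algorithm One of "fcm", "ifcm", "csfcm", "csifcm".
#' @param n_clusters Number of clusters c >= 1.
#' @param m Fuzzifier, > 1.
#' @param p,q Non-negative exponents weighting the primary (intuitionistic
#'   or plain) and secondary (spatially conditioned) membership matrices.
#' @param alpha Yager complement parameter in (0, 1]; controls the amount of
#'   hesitation. Ignored by fcm/csfcm.
#' @param window Odd side length of the square conditioning window; ignored
#'   by fcm/ifcm.
#' @param epsilon Convergence tolerance on the maximum absolute change of the
#'   monitored membership matrix.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param seed Optional integer seed for the random initial partition.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(algorithm = c("csifcm", "fcm", "ifcm", "csfcm"),
                              n_clusters = 4L, m = 2, p = 1, q = 2,
                              alpha = 0.85, window = 3L, epsilon = 1e-5,
                              max_iter = 100L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (n_clusters < 1L) stop("n_clusters must be >= 1", call. = FALSE)
  check_fuzzifier(m)
  if (p < 0 || q < 0 || (p == 0 && q == 0))
    stop("p and q must be non-negative and not both zero", call. = FALSE)
  check_alpha(alpha)
  check_window(window)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(algorithm = algorithm, n_clusters = as.integer(n_clusters),
                 m = m, p = p, q = q, alpha = alpha,
                 window = as.integer(window), epsilon = epsilon,
                 max_iter = as.integer(max_iter), seed = seed),
            class = "clustering_config")
}

#' @export
print.clustering_config <- function(x, ...) {
  cat("<clustering_config> ", x$algorithm, "\n", sep = "")
  cat("  c = ", x$n_clusters, ", m = ", x$m, ", p = ", x$p, ", q = ", x$q,
      ", alpha = ", x$alpha, ", window = ", x$window, "\n", sep = "")
  cat("  epsilon = ", x$epsilon, ", max_iter = ", x$max_iter,
      ", seed = ", if (is.null(x$seed)) "NULL" else x$seed, "\n", sep = "")
  invisible(x)
}
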