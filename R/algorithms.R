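#' Segment an image with one of the four fuzzy clustering algorithms
#'
#' Dispatches on `config$algorithm` to [run_fcm()], [run_ifcm()],
#' [run_csfcm()] or [run_csifcm()]. The image must already be normalized to
#' [0, 1] (see [normalize_intensities()]).
#'
#' @param image Numeric matrix with intensities in [0, 1].
#' @param config A [clustering_config()].
#' @param init Optional c x N initial membership matrix (unit column sums);
#'   by default a seeded random partition is drawn.
#' @return A `segmentation_result` object.
#' @export
segment_image <- function(image, config = clustering_config(), init = NULL) {
  driver <- switch(config$algorithm,
                   fcm = run_fcm, ifcm = run_ifcm,
                   csfcm = run_csfcm, csifcm = run_csifcm)
  driver(image, config, init = init)
}

#' Plain fuzzy C-means segmentation
#'
#' Alternates the FCM membership and center updates until the largest
#' absolute change of the membership matrix drops to `epsilon` or `max_iter`
#' is reached. The objective J is non-increasing along the iterations.
#'
#' @inheritParams segment_image
#' @return A `segmentation_result`.
#' @export
run_fcm <- function(image, config = clustering_config(algorithm = "fcm"),
                    init = NULL) {
  run_driver(image, config, init, "fcm")
}

#' Intuitionistic fuzzy C-means segmentation
#'
#' Each iteration transforms the FCM membership mu through the Yager
#' complement: non-membership lambda, hesitation pi = 1 - mu - lambda, and
#' intuitionistic membership mu* = mu + pi, renormalized per pixel; centers
#' are then recomputed from mu*. At alpha = 1 the hesitation vanishes and
#' the algorithm coincides with plain FCM.
#'
#' @inheritParams segment_image
#' @return A `segmentation_result`.
#' @export
run_ifcm <- function(image, config = clustering_config(algorithm = "ifcm"),
                     init = NULL) {
  run_driver(image, config, init, "ifcm")
}

#' Conditional spatial fuzzy C-means segmentation
#'
#' Each iteration computes the FCM membership mu, conditions it on the
#' neighborhood (h = windowed mean of mu, u = h mu), forms the weighted
#' membership z proportional to mu^p u^q, and updates the centers from z.
#' Terminates when z stops changing (max absolute change <= epsilon).
#'
#' @inheritParams segment_image
#' @return A `segmentation_result`.
#' @export
run_csfcm <- function(image, config = clustering_config(algorithm = "csfcm"),
                      init = NULL) {
  run_driver(image, config, init, "csfcm")
}

#' Conditional spatial intuitionistic fuzzy C-means segmentation
#'
#' The combined algorithm: per iteration, from the current joint centers g,
#' compute the FCM membership mu (distance ratios), the conditional spatial
#' membership u* = h mu (h = windowed mean of mu), the Yager non-membership
#' lambda(u*) and hesitation pi = 1 - u* - lambda, the intuitionistic
#' membership mu* = mu + pi (capped at 1), the weighted intuitionistic
#' membership w proportional to mu*^p u*^q, and finally the joint centers g
#' from w. Terminates when w stops changing. At alpha = 1 the procedure
#' reproduces csFCM exactly; with window 1 and alpha = 1 its labels agree
#' with FCM's on well-separated images.
#'
#' @inheritParams segment_image
#' @return A `segmentation_result`.
#' @export
run_csifcm <- function(image, config = clustering_config(algorithm = "csifcm"),
                       init = NULL) {
  run_driver(image, config, init, "csifcm")
}

# Shared alternating-optimization scaffold for the four drivers.
run_driver <- function(image, config, init, algorithm) {
  image <- as_image_grid(image)
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("image must be normalized to [0, 1]; see normalize_intensities()",
         call. = FALSE)
  stopifnot(config$algorithm == algorithm)
  dims <- dim(image)
  x <- flatten_pixels(image)
  n <- length(x)
  c_ <- config$n_clusters
  m <- config$m

  if (is.null(init)) {
    prev <- initialize_partition(n, c_, config$seed)
  } else {
    stopifnot(nrow(init) == c_, ncol(init) == n)
    prev <- init
  }
  centers <- update_centers(x, prev, m)

  iters <- 0L
  converged <- FALSE
  trace <- vector("list", config$max_iter)
  current <- prev

  for (it in seq_len(config$max_iter)) {
    mu <- fcm_membership(x, centers, m)
    current <- switch(
      algorithm,
      fcm = mu,
      ifcm = {
        lam <- yager_nonmembership(mu, config$alpha)
        mustar <- mu + hesitation_degree(mu, lam)
        sweep(mustar, 2L, colSums(mustar), "/")
      },
      csfcm = {
        h <- spatial_condition(mu, dims, config$window)
        weighted_membership(mu, h * mu, config$p, config$q)
      },
      csifcm = {
        h <- spatial_condition(mu, dims, config$window)
        ustar <- h * mu
        lam <- yager_nonmembership(ustar, config$alpha)
        mustar <- pmin(mu + hesitation_degree(ustar, lam), 1)
        weighted_membership(mustar, ustar, config$p, config$q)
      })
    centers <- update_centers(x, current, m, prev = centers)
    delta <- max(abs(current - prev))
    obj <- fcm_objective(x, current, centers, m)
    trace[[it]] <- c(iteration = it, max_delta = delta, objective = obj)
    prev <- current
    iters <- it
    if (delta <= config$epsilon) { converged <- TRUE; break }
  }

  trace <- tibble::as_tibble(do.call(rbind, trace[seq_len(iters)]))
  labels <- unflatten_pixels(defuzzify(current), dims)
  structure(list(algorithm = algorithm,
                 membership = current,
                 centers = centers,
                 labels = labels,
                 n_iterations = iters,
                 converged = converged,
                 trace = trace,
                 config = config,
                 dim = dims),
            class = "segmentation_result")
}

#' Defuzzify a membership matrix to crisp labels
#'
#' Per-pixel argmax over clusters; ties go to the lowest cluster index.
#'
#' @param membership c x N membership matrix.
#' @return Integer vector of labels in 1..c.
#' @export
defuzzify <- function(membership) {
  max.col(t(membership), ties.method = "first")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", x$algorithm,
      " (", x$dim[1L], "x", x$dim[2L], " image, c = ",
      length(x$centers), ")\n", sep = "")
  cat("  centers: ", paste(signif(sort(x$centers), 4), collapse = ", "),
      "\n", sep = "")
  cat("  ", x$n_iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged",
      " (last max delta ", signif(utils::tail(x$trace$max_delta, 1), 3),
      ")\n", sep = "")
  invisible(x)
}
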