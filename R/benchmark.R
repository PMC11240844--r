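#' Phantom segmentation benchmark
#'
#' Reproduces the noisy head-phantom experiment end to end: generate the
#' Shepp-Logan phantom with quantized ground truth, corrupt it with
#' zero-mean Gaussian noise, segment it with each requested algorithm over
#' several seeds, match clusters to ground truth and collect per-segment and
#' overall metrics. Each seed draws its own noise realization and random
#' initial partition; a given seed uses the same noisy image for every
#' algorithm, so algorithms are compared like for like.
#'
#' @param noise_variance Gaussian noise variance on the [0, 1] scale
#'   (default 0.01).
#' @param seeds Integer vector of run seeds (default 1:10).
#' @param size Phantom side length (default 256).
#' @param algorithms Character vector among "fcm", "ifcm", "csfcm",
#'   "csifcm".
#' @param n_segments Number of classes/clusters (default 4).
#' @param ... Further arguments passed to [clustering_config()] (m, p, q,
#'   alpha, window, epsilon, max_iter).
#' @return A `phantom_benchmark` object: list with `runs` (tibble, one row
#'   per algorithm x seed x segment), `overall` (one row per algorithm x
#'   seed), and `summary` (mean and sd of overall accuracy per algorithm).
#' @export
benchmark_phantom <- function(noise_variance = 0.01, seeds = 1:10,
                              size = 256L,
                              algorithms = c("fcm", "ifcm", "csfcm", "csifcm"),
                              n_segments = 4L, ...) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  ph <- generate_phantom(size, n_segments = n_segments)
  runs <- list(); overall <- list()
  for (s in seeds) {
    noisy <- add_gaussian_noise(ph$image, noise_variance, seed = s)
    for (alg in algorithms) {
      cfg <- clustering_config(algorithm = alg, n_clusters = n_segments,
                               seed = s, ...)
      res <- segment_image(noisy, cfg)
      ev <- evaluate_segmentation(res, ph$labels, n_clusters = n_segments)
      runs[[length(runs) + 1L]] <- dplyr::mutate(
        ev$per_segment, algorithm = alg, seed = s, .before = 1L)
      overall[[length(overall) + 1L]] <- tibble::tibble(
        algorithm = alg, seed = s,
        overall_accuracy = ev$overall_accuracy,
        n_iterations = res$n_iterations, converged = res$converged)
    }
  }
  overall <- dplyr::bind_rows(overall)
  summary <- dplyr::summarise(
    dplyr::group_by(overall, .data$algorithm),
    mean_accuracy = mean(.data$overall_accuracy),
    sd_accuracy = stats::sd(.data$overall_accuracy),
    n_runs = dplyr::n(), .groups = "drop")
  structure(list(runs = dplyr::bind_rows(runs), overall = overall,
                 summary = summary,
                 noise_variance = noise_variance, size = size,
                 seeds = seeds),
            class = "phantom_benchmark")
}

#' @export
print.phantom_benchmark <- function(x, ...) {
  cat("<phantom_benchmark> ", x$size, "x", x$size,
      " phantom, noise variance ", x$noise_variance, ", ",
      length(x$seeds), " seed(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Grid sweep of the membership weights p and q
#'
#' Segments a noisy synthetic image with csIFCM (or another algorithm) for
#' every (p, q) pair of a grid, averaging overall accuracy over seeds, and
#' reports the best cell. By default the input is a noisy phantom; pass
#' `image`/`true_labels` to sweep on other data.
#'
#' @param p_values,q_values Numeric grids (non-empty).
#' @param seeds Integer vector of seeds.
#' @param algorithm Algorithm to sweep (default "csifcm").
#' @param image,true_labels Optional normalized image and ground-truth label
#'   map; by default a 128x128 noisy phantom (variance 0.01) is generated.
#' @param noise_variance Noise used for the default phantom input.
#' @param size Side length of the default phantom input.
#' @param ... Further [clustering_config()] arguments.
#' @return A tibble with columns p, q, mean_accuracy, sd_accuracy, plus the
#'   attribute `best` (the argmax row).
#' @export
sweep_pq <- function(p_values = 1:3, q_values = 1:3, seeds = 1:3,
                     algorithm = "csifcm", image = NULL, true_labels = NULL,
                     noise_variance = 0.01, size = 128L, ...) {
  if (length(p_values) == 0L || length(q_values) == 0L)
    stop("p and q grids must be non-empty", call. = FALSE)
  if (is.null(image)) {
    ph <- generate_phantom(size)
    image <- ph$image; true_labels <- ph$labels
  }
  n_segments <- max(true_labels)
  cells <- list()
  for (p in p_values) for (q in q_values) {
    accs <- vapply(seeds, function(s) {
      noisy <- if (noise_variance > 0)
        add_gaussian_noise(image, noise_variance, seed = s) else image
      cfg <- clustering_config(algorithm = algorithm,
                               n_clusters = n_segments,
                               p = p, q = q, seed = s, ...)
      ev <- evaluate_segmentation(segment_image(noisy, cfg), true_labels,
                                  n_clusters = n_segments)
      ev$overall_accuracy
    }, numeric(1))
    cells[[length(cells) + 1L]] <- tibble::tibble(
      p = p, q = q, mean_accuracy = mean(accs),
      sd_accuracy = stats::sd(accs))
  }
  grid <- dplyr::bind_rows(cells)
  attr(grid, "best") <- grid[which.max(grid$mean_accuracy), ]
  grid
}
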