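#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the iteration trace of a segmentation
#'
#' @param x A `segmentation_result`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `iteration`, `max_delta`
#'   (largest absolute change of the monitored membership matrix) and
#'   `objective` (the FCM-style cost of the monitored membership).
#' @export
tidy.segmentation_result <- function(x, ...) {
  x$trace
}

#' One-row summary of a segmentation
#'
#' @param x A `segmentation_result`.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, number of clusters, iterations,
#'   convergence flag, final max delta and the sorted cluster centers as a
#'   list column.
#' @export
glance.segmentation_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_clusters = length(x$centers),
                 n_iterations = x$n_iterations,
                 converged = x$converged,
                 final_delta = utils::tail(x$trace$max_delta, 1L),
                 centers = list(sort(x$centers)))
}

#' Per-segment metrics of an evaluation as a tibble
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-segment tibble (Dice similarity, fpr, fnr, tpr,
#'   fpr_rate per ground-truth segment).
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_segment
}

#' One-row summary of an evaluation
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A one-row tibble with overall accuracy and mean per-segment Dice.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 mean_similarity = mean(x$per_segment$similarity, na.rm = TRUE),
                 n_segments = nrow(x$per_segment))
}

#' Per-run results of a phantom benchmark as a tibble
#'
#' @param x A `phantom_benchmark`.
#' @param ... Unused.
#' @return The long per-segment tibble (algorithm x seed x segment).
#' @export
tidy.phantom_benchmark <- function(x, ...) {
  x$runs
}

#' Per-algorithm summary of a phantom benchmark
#'
#' @param x A `phantom_benchmark`.
#' @param ... Unused.
#' @return A tibble with mean and sd of overall accuracy per algorithm.
#' @export
glance.phantom_benchmark <- function(x, ...) {
  x$summary
}
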