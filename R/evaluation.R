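#' Optimal one-to-one matching of predicted clusters to ground-truth segments
#'
#' Clustering output has arbitrary label order, so before any accuracy
#' metric the predicted clusters are matched to the ground-truth segments by
#' maximizing the total overlap of the c x c contingency table (optimal
#' assignment, not greedy). Differing numbers of labels are handled by
#' padding with empty segments.
#'
#' @param pred_labels Integer vector/matrix of predicted labels (1-based).
#' @param true_labels Integer vector/matrix of ground-truth labels (1-based).
#' @param n_clusters Number of clusters/segments; defaults to the largest
#'   label seen in either map.
#' @return Integer vector `mapping` with `mapping[i]` = ground-truth segment
#'   assigned to predicted cluster i.
#' @export
match_clusters <- function(pred_labels, true_labels, n_clusters = NULL) {
  pred <- as.vector(pred_labels); truth <- as.vector(true_labels)
  if (length(pred) != length(truth))
    stop("label maps differ in length", call. = FALSE)
  if (is.null(n_clusters)) n_clusters <- max(pred, truth)
  tab <- table(factor(pred, levels = seq_len(n_clusters)),
               factor(truth, levels = seq_len(n_clusters)))
  assignment_max(unclass(tab))
}

# Maximize total benefit over one-to-one assignments (rows -> columns).
assignment_max <- function(benefit) {
  match <- hungarian_min(max(benefit) - benefit)
  match
}

# Hungarian algorithm (Kuhn-Munkres, O(n^3) potential formulation) for the
# square minimum-cost assignment problem. Returns match[row] = column.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)  # index 1 = virtual column
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) match[p[j + 1L]] <- j
  match
}

#' Overlap metrics for one segment
#'
#' Given the ground-truth pixel set S1 and predicted pixel set S2 of a
#' segment, returns
#' \deqn{fpr = (|S2| - |S1 \cap S2|)/|S1|, \quad
#'       fnr = (|S1| - |S1 \cap S2|)/|S1|, \quad
#'       \rho = 2|S1 \cap S2|/(|S1| + |S2|)}
#' rho is the Dice similarity index in [0, 1]; fpr is NOT clipped at 1 (a
#' grossly over-segmented prediction can exceed 1).
#'
#' @param truth Logical vector: pixel belongs to the ground-truth segment.
#' @param pred Logical vector: pixel belongs to the predicted segment.
#' @return Named list with `similarity`, `fpr`, `fnr`, and `undefined`
#'   (TRUE when the ground-truth segment is empty, in which case the three
#'   ratios are NA).
#' @export
segment_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  s1 <- sum(truth); s2 <- sum(pred); inter <- sum(truth & pred)
  if (s1 == 0L)
    return(list(similarity = NA_real_, fpr = NA_real_, fnr = NA_real_,
                undefined = TRUE))
  list(similarity = 2 * inter / (s1 + s2),
       fpr = (s2 - inter) / s1,
       fnr = (s1 - inter) / s1,
       undefined = FALSE)
}

#' True/false positive rates for one segment
#'
#' TP = |S1 n S2|, FP = |S2 - S1|; TPR = TP / |S1|. The false positive rate
#' divides FP by the number of negative pixels N = total - |S1| by default;
#' `fpr_denominator = "positives"` divides by |S1| instead (in which case it
#' coincides with the overlap fpr of [segment_metrics()]).
#'
#' @inheritParams segment_metrics
#' @param fpr_denominator Either "negatives" (default) or "positives".
#' @return Named list with `tpr`, `fpr_rate`, and `undefined` flags.
#' @export
tpr_fpr <- function(truth, pred, fpr_denominator = c("negatives", "positives")) {
  fpr_denominator <- match.arg(fpr_denominator)
  stopifnot(length(truth) == length(pred))
  s1 <- sum(truth)
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  tpr <- if (s1 == 0L) NA_real_ else tp / s1
  den <- if (fpr_denominator == "negatives") length(truth) - s1 else s1
  fpr_rate <- if (den == 0L) NA_real_ else fp / den
  list(tpr = tpr, fpr_rate = fpr_rate,
       undefined = s1 == 0L || den == 0L)
}

#' Overall segmentation accuracy after label matching
#'
#' The proportion of pixels whose mapped predicted label equals the
#' ground-truth label.
#'
#' @inheritParams match_clusters
#' @param mapping Cluster-to-segment mapping from [match_clusters()].
#' @return A single number in [0, 1].
#' @export
overall_accuracy <- function(pred_labels, true_labels, mapping) {
  pred <- as.vector(pred_labels); truth <- as.vector(true_labels)
  mean(mapping[pred] == truth)
}

#' Evaluate a segmentation against a ground-truth label map
#'
#' Matches predicted clusters to ground-truth segments by optimal
#' assignment, then computes per-segment Dice similarity, false
#' positive/negative ratios and TPR/FPR (one-vs-rest), plus the overall
#' segmentation accuracy over the full label map.
#'
#' @param pred Either a `segmentation_result` or an integer label
#'   vector/matrix.
#' @param true_labels Integer ground-truth label vector/matrix (1-based).
#' @param n_clusters Number of segments; defaults to the largest label seen.
#' @param fpr_denominator Passed to [tpr_fpr()].
#' @return An `evaluation_report`: list with `per_segment` (a tibble with one
#'   row per ground-truth segment), `overall_accuracy`, and `mapping`.
#' @export
evaluate_segmentation <- function(pred, true_labels, n_clusters = NULL,
                                  fpr_denominator = c("negatives", "positives")) {
  fpr_denominator <- match.arg(fpr_denominator)
  if (inherits(pred, "segmentation_result")) pred <- pred$labels
  pred <- as.vector(pred); truth <- as.vector(true_labels)
  if (is.null(n_clusters)) n_clusters <- max(pred, truth)
  mapping <- match_clusters(pred, truth, n_clusters)
  mapped <- mapping[pred]
  rows <- lapply(seq_len(n_clusters), function(s) {
    t_mask <- truth == s
    p_mask <- mapped == s
    sm <- segment_metrics(t_mask, p_mask)
    tf <- tpr_fpr(t_mask, p_mask, fpr_denominator)
    tibble::tibble(segment = s,
                   n_true = sum(t_mask), n_pred = sum(p_mask),
                   similarity = sm$similarity, fpr = sm$fpr, fnr = sm$fnr,
                   tpr = tf$tpr, fpr_rate = tf$fpr_rate,
                   undefined = sm$undefined)
  })
  structure(list(per_segment = dplyr::bind_rows(rows),
                 overall_accuracy = overall_accuracy(pred, truth, mapping),
                 mapping = mapping,
                 fpr_denominator = fpr_denominator),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> overall segmentation accuracy: ",
      sprintf("%.4f", x$overall_accuracy), "\n", sep = "")
  print(x$per_segment)
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per segment plus an overall row, mirroring the usual
#' similarity / false-positive-ratio / true-positive-ratio / overall-accuracy
#' table layout.
#'
#' @param report An `evaluation_report`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  per <- report$per_segment
  per$overall_accuracy <- c(report$overall_accuracy,
                            rep(NA_real_, nrow(per) - 1L))
  utils::write.csv(per, path, row.names = FALSE)
  invisible(path)
}
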