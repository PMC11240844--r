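#' Generate a piecewise-constant synthetic MRI slice
#'
#' A stand-in for a real T1-weighted axial slice: an elliptical "head" of
#' concentric tissue rings with the given class mean intensities, optionally
#' shaded by a smooth multiplicative bias field (intensity inhomogeneity)
#' and corrupted by additive Gaussian noise. The ground truth is the label
#' map before any corruption. Class 1 is the background outside the head;
#' classes 2..c are equal-area concentric rings from the rim inwards.
#'
#' @param size Side length in pixels.
#' @param class_means Strictly increasing intensities in [0, 1], one per
#'   class; the number of classes c is `length(class_means)`.
#' @param noise_variance Variance of the additive Gaussian noise on the
#'   [0, 1] scale (0 = none).
#' @param bias_amplitude Amplitude A in [0, 0.5) of the multiplicative bias
#'   field 1 + A * s(r, c), where s is a smooth low-frequency surface in
#'   [-1, 1] (0 = none).
#' @param seed Optional integer seed (noise reproducibility).
#' @return A list with `image` (matrix in [0, 1]), `labels` (integer matrix
#'   of ground-truth classes), and `clean` (the uncorrupted image).
#' @export
generate_synthetic_mri <- function(size = 128L,
                                   class_means = c(0.05, 0.35, 0.65, 0.95),
                                   noise_variance = 0.02,
                                   bias_amplitude = 0,
                                   seed = NULL) {
  c_ <- length(class_means)
  if (c_ < 2L) stop("need at least two classes", call. = FALSE)
  if (is.unsorted(class_means, strictly = TRUE) ||
      any(class_means < 0 | class_means > 1))
    stop("class_means must be strictly increasing within [0, 1]", call. = FALSE)
  if (bias_amplitude < 0 || bias_amplitude >= 0.5)
    stop("bias_amplitude must lie in [0, 0.5)", call. = FALSE)
  sep <- min(diff(class_means))
  if (noise_variance > 0 && sep < 2 * sqrt(noise_variance) - 1e-9)
    warning("class mean separation below 2 standard deviations of the noise; ",
            "classes will overlap substantially", call. = FALSE)

  ticks <- (seq_len(size) - 1 - (size - 1) / 2) / ((size - 1) / 2)
  xg <- matrix(ticks, size, size, byrow = TRUE)
  yg <- matrix(rev(ticks), size, size)
  rho <- sqrt((xg / 0.85)^2 + (yg / 0.92)^2)
  # ring boundaries chosen for equal areas of the c - 1 head classes
  cuts <- sqrt((c_ - seq(1L, c_ - 1L)) / (c_ - 1L))  # 1 = rim, decreasing
  labels <- matrix(1L, size, size)
  for (j in seq_len(c_ - 1L)) labels[rho <= cuts[j]] <- j + 1L
  clean <- matrix(class_means[labels], size, size)

  img <- clean
  if (bias_amplitude > 0) {
    u <- matrix(seq_len(size) / (size + 1), size, size, byrow = TRUE)
    v <- matrix(seq_len(size) / (size + 1), size, size)
    surface <- 2 * sin(pi * u) * sin(pi * v) - 1
    img <- pmin(pmax(img * (1 + bias_amplitude * surface), 0), 1)
  }
  if (noise_variance > 0)
    img <- add_gaussian_noise(img, noise_variance, seed = seed)
  list(image = img, labels = labels, clean = clean)
}
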