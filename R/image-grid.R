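#' Coerce an object to a 2-D grayscale image grid
#'
#' An image grid is a plain numeric matrix of pixel intensities (rows = image
#' rows, columns = image columns). Multi-channel arrays (e.g. RGB read from
#' PNG) are reduced to grayscale by the usual luminance weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is dropped.
#'
#' @param x A numeric matrix, or a 3-D numeric array with 2--4 channels in the
#'   third dimension.
#' @return A numeric matrix of intensities.
#' @export
as_image_grid <- function(x) {
  if (is.matrix(x) && is.numeric(x)) {
    if (length(x) == 0L) stop("image must be non-empty", call. = FALSE)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L && is.numeric(x)) {
    nch <- dim(x)[3L]
    if (nch == 1L) return(x[, , 1L])
    if (nch %in% c(2L, 4L)) x <- x[, , -nch, drop = FALSE]  # drop alpha
    if (dim(x)[3L] == 1L) return(x[, , 1L])
    wts <- c(0.299, 0.587, 0.114)
    return(x[, , 1L] * wts[1L] + x[, , 2L] * wts[2L] + x[, , 3L] * wts[3L])
  }
  stop("cannot interpret input as a 2-D grayscale image", call. = FALSE)
}

#' Read a 2-D grayscale image from disk
#'
#' PNG images are read via the png package; TIFF via the tiff package and
#' NIfTI (.nii / .nii.gz) via RNifti, from which a single axial slice is
#' extracted. Multi-channel images are reduced to grayscale.
#'
#' @param path Path to a PNG, TIFF or NIfTI file.
#' @param slice For NIfTI volumes, index of the slice along the third
#'   dimension (default 1).
#' @return A numeric matrix of raw intensities.
#' @export
read_image <- function(path, slice = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    return(as_image_grid(png::readPNG(path)))
  }
  if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
    return(as_image_grid(tiff::readTIFF(path)))
  }
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("the 'RNifti' package is required to read NIfTI images", call. = FALSE)
    vol <- RNifti::readNifti(path)
    a <- as.array(vol)
    if (length(dim(a)) == 2L) return(a)
    if (slice < 1L || slice > dim(a)[3L])
      stop("slice index out of range", call. = FALSE)
    return(a[, , slice])
  }
  stop("unsupported image format: ", path, call. = FALSE)
}

#' Write a normalized image or an integer label map as PNG
#'
#' Label maps are spread over the gray range so that distinct labels are
#' visually distinct; intensity images must already lie in [0, 1].
#'
#' @param x Numeric matrix in [0, 1], or integer label matrix.
#' @param path Output file path (PNG).
#' @param labels Logical; treat `x` as a label map.
#' @return The path, invisibly.
#' @export
write_image <- function(x, path, labels = FALSE) {
  m <- as_image_grid(x)
  if (labels) {
    lv <- sort(unique(as.vector(m)))
    m <- matrix(match(m, lv) - 1L, nrow(m), ncol(m)) / max(1L, length(lv) - 1L)
  }
  if (any(m < 0 | m > 1)) stop("intensities must lie in [0, 1]", call. = FALSE)
  png::writePNG(m, path)
  invisible(path)
}

#' Min-max normalize image intensities to [0, 1]
#'
#' Applies the affine map (x - min) / (max - min). A constant image (zero
#' dynamic range) maps to all zeros.
#'
#' @param image Numeric matrix (or coercible via [as_image_grid()]).
#' @return Numeric matrix with values in [0, 1].
#' @export
#' @examples
#' normalize_intensities(matrix(c(2, 4, 10), 1))
normalize_intensities <- function(image) {
  m <- as_image_grid(image)
  if (anyNA(m)) stop("image contains missing values", call. = FALSE)
  rng <- range(m)
  if (rng[1L] == rng[2L]) return(array(0, dim(m)))
  (m - rng[1L]) / (rng[2L] - rng[1L])
}

#' Add zero-mean Gaussian noise to a normalized image
#'
#' Noise of the given variance is drawn independently per pixel and the result
#' is clipped back to [0, 1]. With the same seed the output is reproducible
#' bit-for-bit; the caller's RNG state is left untouched.
#'
#' @param image Numeric matrix with values in [0, 1].
#' @param variance Noise variance on the normalized intensity scale
#'   (so 0.01 means standard deviation 0.1). Must be >= 0.
#' @param seed Optional integer seed.
#' @param clip Clip the noisy image back to [0, 1] (default TRUE).
#' @return Numeric matrix of the same shape.
#' @export
add_gaussian_noise <- function(image, variance, seed = NULL, clip = TRUE) {
  m <- as_image_grid(image)
  if (!is.numeric(variance) || length(variance) != 1L || is.na(variance) ||
      variance < 0)
    stop("variance must be a single non-negative number", call. = FALSE)
  if (variance == 0) return(m)
  noisy <- m + local_seed(seed, matrix(
    stats::rnorm(length(m), mean = 0, sd = sqrt(variance)), nrow(m), ncol(m)))
  if (clip) noisy <- pmin(pmax(noisy, 0), 1)
  noisy
}

#' Flatten an image to the row-major pixel vector used by the clustering core
#'
#' Pixel k (1-based) is the pixel at row r, column c with
#' k = (r - 1) * width + c.
#'
#' @param image Numeric matrix.
#' @return Numeric vector of length height * width.
#' @export
flatten_pixels <- function(image) {
  as.vector(t(as_image_grid(image)))
}

#' Reshape a row-major pixel vector back to an image matrix
#'
#' @param x Vector of length prod(dim).
#' @param dim Integer vector c(height, width).
#' @return A matrix of shape `dim`.
#' @export
unflatten_pixels <- function(x, dim) {
  stopifnot(length(x) == prod(dim))
  matrix(x, dim[1L], dim[2L], byrow = TRUE)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
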