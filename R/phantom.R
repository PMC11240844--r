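#' Ellipse table of the Shepp-Logan head phantom
#'
#' The ten superposed ellipses of the classic head phantom. The "modified"
#' variant (the default returned by the usual phantom generators) raises the
#' contrast of the internal features; the "original" variant uses the
#' historical low-contrast intensities. Columns: additive `intensity`,
#' semi-axes `a` (x) and `b` (y), center `x0`/`y0`, rotation `phi` in
#' degrees, all on the unit square [-1, 1]^2.
#'
#' @param variant "modified" (default) or "original".
#' @return A tibble with one row per ellipse.
#' @export
shepp_logan_ellipses <- function(variant = c("modified", "original")) {
  variant <- match.arg(variant)
  a  <- c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023)
  b  <- c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046)
  x0 <- c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06)
  y0 <- c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605)
  phi <- c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  intensity <- if (variant == "modified")
    c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  else
    c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  tibble::tibble(intensity = intensity, a = a, b = b, x0 = x0, y0 = y0,
                 phi = phi)
}

#' Render a sum-of-ellipses image on a square grid
#'
#' Pixel centers are placed on the usual phantom grid: coordinate
#' x_j = ((j-1) - (n-1)/2) / ((n-1)/2) for column j, and y decreasing from
#' +1 (top row) to -1 (bottom row). Each ellipse adds its intensity to every
#' pixel whose center falls inside it.
#'
#' @param size Grid side length n.
#' @param ellipses Tibble/data.frame as returned by [shepp_logan_ellipses()].
#' @return A size x size numeric matrix of composite intensities.
#' @export
render_ellipses <- function(size, ellipses) {
  ticks <- (seq_len(size) - 1 - (size - 1) / 2) / ((size - 1) / 2)
  xg <- matrix(ticks, size, size, byrow = TRUE)
  yg <- matrix(rev(ticks), size, size)
  img <- matrix(0, size, size)
  for (e in seq_len(nrow(ellipses))) {
    dx <- xg - ellipses$x0[e]
    dy <- yg - ellipses$y0[e]
    ang <- ellipses$phi[e] * pi / 180
    xr <- dx * cos(ang) + dy * sin(ang)
    yr <- dy * cos(ang) - dx * sin(ang)
    inside <- (xr / ellipses$a[e])^2 + (yr / ellipses$b[e])^2 <= 1
    img[inside] <- img[inside] + ellipses$intensity[e]
  }
  img
}

#' Generate the Shepp-Logan head phantom with quantized ground-truth labels
#'
#' Renders the ten-ellipse head phantom on a size x size grid, min-max
#' normalizes it to [0, 1], and derives a deterministic ground-truth label
#' map by grouping the distinct composite intensity levels into
#' `n_segments` classes (exact 1-D natural-breaks partition of the level
#' values). For the modified variant with 4 segments this yields background
#' (plus the ventricles, whose composite intensity equals the background's),
#' brain tissue, the small bright internal ellipses, and the skull shell.
#'
#' @param size Side length in pixels (>= 32).
#' @param n_segments Number of ground-truth classes (default 4).
#' @param variant Ellipse intensity table, "modified" (default) or
#'   "original".
#' @return A list with `image` (normalized matrix), `labels` (integer matrix,
#'   1..n_segments ordered by increasing intensity), and `levels` (tibble of
#'   distinct composite levels with their class).
#' @export
generate_phantom <- function(size = 256L, n_segments = 4L,
                             variant = c("modified", "original")) {
  if (size < 32L) stop("size must be >= 32", call. = FALSE)
  variant <- match.arg(variant)
  composite <- render_ellipses(size, shepp_logan_ellipses(variant))
  lv <- sort(unique(round(as.vector(composite), 9)))
  if (length(lv) < n_segments)
    stop("fewer distinct intensity levels than requested segments",
         call. = FALSE)
  counts <- tabulate(match(round(as.vector(composite), 9), lv),
                     nbins = length(lv))
  grp <- natural_breaks(lv, n_segments, weights = counts)
  labels <- matrix(grp[match(round(composite, 9), lv)], size, size)
  list(image = normalize_intensities(composite),
       labels = labels,
       levels = tibble::tibble(level = lv, class = grp))
}

# Exact minimum within-group (weighted) sum-of-squares partition of sorted
# values into k contiguous groups (dynamic programming over the few distinct
# levels). Weights are the pixel counts of each level, so that populous
# intensity levels are not merged to save a near-empty one.
natural_breaks <- function(values, k, weights = rep(1, length(values))) {
  n <- length(values)
  stopifnot(k >= 1L, k <= n, length(weights) == n)
  css <- function(i, j) {           # cost of one group values[i..j]
    v <- values[i:j]; w <- weights[i:j]
    mu <- sum(w * v) / sum(w)
    sum(w * (v - mu)^2)
  }
  cost <- matrix(Inf, n, k)
  split <- matrix(0L, n, k)
  for (i in seq_len(n)) cost[i, 1L] <- css(1L, i)
  if (k > 1L) for (g in 2L:k) {
    for (i in g:n) {
      for (s in (g - 1L):(i - 1L)) {
        val <- cost[s, g - 1L] + css(s + 1L, i)
        if (val < cost[i, g]) { cost[i, g] <- val; split[i, g] <- s }
      }
    }
  }
  breaks <- integer(k + 1L); breaks[k + 1L] <- n
  i <- n
  if (k > 1L) for (g in k:2L) { i <- split[i, g]; breaks[g] <- i }
  grp <- integer(n)
  for (g in seq_len(k)) grp[(breaks[g] + 1L):breaks[g + 1L]] <- g
  grp
}
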