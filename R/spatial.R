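#' Neighborhood conditioning of a membership matrix
#'
#' For every cluster and pixel, replaces the membership by its arithmetic
#' mean over a square window centred on the pixel:
#' \deqn{h_{ik} = \sum_{j \in N_{x_k}} \mu_{ij} / R}
#' where R is the number of pixels of the window that fall inside the image
#' (the window shrinks at the borders; there is no padding).
#'
#' @param membership c x N matrix, pixels in row-major order.
#' @param image_dim Integer vector c(height, width) with height * width = N.
#' @param window Odd window side length (1, 3, 5, ...). Window 1 returns the
#'   input unchanged.
#' @return A c x N matrix of conditioned memberships in [0, 1].
#' @export
spatial_condition <- function(membership, image_dim, window = 3L) {
  check_window(window)
  n <- ncol(membership)
  if (prod(image_dim) != n)
    stop("image_dim inconsistent with number of pixels", call. = FALSE)
  if (window == 1L) return(membership)
  out <- membership
  for (i in seq_len(nrow(membership))) {
    img <- unflatten_pixels(membership[i, ], image_dim)
    out[i, ] <- flatten_pixels(box_window_mean(img, window))
  }
  # the summed-area table can overshoot [0, 1] by a few ulp
  pmin(pmax(out, 0), 1)
}

#' Conditional spatial membership
#'
#' The FCM distance-ratio membership rescaled by the conditional variable h:
#' \deqn{u^*_{ik} = h_{ik} \, \mu_{ik}}
#' where mu is the plain FCM membership of the pixel. With h identically 1
#' this reduces to plain FCM membership. Column sums are at most 1.
#'
#' @inheritParams fcm_membership
#' @param h c x N matrix of conditioning values in [0, 1] (typically the
#'   output of [spatial_condition()]).
#' @return A c x N matrix with entries in [0, 1].
#' @export
conditional_membership <- function(pixels, centers, h, m = 2) {
  mu <- fcm_membership(pixels, centers, m)
  if (!all(dim(h) == dim(mu)))
    stop("h has the wrong shape", call. = FALSE)
  if (any(h < 0 | h > 1)) stop("h must lie in [0, 1]", call. = FALSE)
  h * mu
}

# Box-filter mean with shrinking window at the borders, via a summed-area
# table: O(N) regardless of window size.
box_window_mean <- function(mat, window) {
  if (window == 1L) return(mat)
  r <- (window - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(mat, 2L, cumsum), 1L, cumsum))
  lo_r <- pmax(seq_len(nr) - r, 1L); hi_r <- pmin(seq_len(nr) + r, nr)
  lo_c <- pmax(seq_len(nc) - r, 1L); hi_c <- pmin(seq_len(nc) + r, nc)
  sums <- S[hi_r + 1L, hi_c + 1L, drop = FALSE] -
    S[lo_r, hi_c + 1L, drop = FALSE] -
    S[hi_r + 1L, lo_c, drop = FALSE] +
    S[lo_r, lo_c, drop = FALSE]
  counts <- outer(hi_r - lo_r + 1L, hi_c - lo_c + 1L)
  sums / counts
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1L || window %% 2L != 1L)
    stop("window must be an odd positive integer", call. = FALSE)
  invisible(as.integer(window))
}
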