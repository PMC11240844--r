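# Independent brute-force oracles: explicit per-pixel loops, no shared code
# with the vectorized implementations they check.

oracle_fcm_membership <- function(pixels, centers, m) {
  c_ <- length(centers); n <- length(pixels)
  u <- matrix(0, c_, n)
  for (k in seq_len(n)) {
    d <- abs(pixels[k] - centers)
    if (any(d == 0)) {
      u[which(d == 0)[1L], k] <- 1
    } else {
      for (i in seq_len(c_)) {
        u[i, k] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
      }
    }
  }
  u
}

oracle_fcm_objective <- function(pixels, membership, centers, m) {
  total <- 0
  for (i in seq_along(centers)) {
    for (k in seq_along(pixels)) {
      total <- total + membership[i, k]^m * (pixels[k] - centers[i])^2
    }
  }
  total
}

oracle_spatial_condition <- function(membership, dims, window) {
  r <- (window - 1) / 2
  out <- membership
  for (i in seq_len(nrow(membership))) {
    M <- matrix(membership[i, ], dims[1L], dims[2L], byrow = TRUE)
    H <- M
    for (rr in seq_len(dims[1L])) {
      for (cc in seq_len(dims[2L])) {
        rs <- max(1, rr - r):min(dims[1L], rr + r)
        cs <- max(1, cc - r):min(dims[2L], cc + r)
        H[rr, cc] <- mean(M[rs, cs])
      }
    }
    out[i, ] <- as.vector(t(H))
  }
  out
}

oracle_weighted_membership <- function(primary, secondary, p, q) {
  w <- primary
  for (k in seq_len(ncol(primary))) {
    prod_k <- numeric(nrow(primary))
    for (i in seq_len(nrow(primary))) {
      prod_k[i] <- primary[i, k]^p * secondary[i, k]^q
    }
    if (sum(prod_k) == 0) prod_k <- rep(1, nrow(primary))
    w[, k] <- prod_k / sum(prod_k)
  }
  w
}

# All permutations of a vector (for brute-force assignment checks).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

oracle_best_assignment <- function(benefit) {
  n <- nrow(benefit)
  best <- -Inf; best_p <- NULL
  for (p in all_perms(seq_len(n))) {
    s <- sum(benefit[cbind(seq_len(n), p)])
    if (s > best) { best <- s; best_p <- p }
  }
  list(total = best, mapping = best_p)
}

# A two-block step image: left half intensity `lo`, right half `hi`.
two_block_image <- function(nr = 16L, nc = 16L, lo = 0, hi = 1) {
  cbind(matrix(lo, nr, nc %/% 2L), matrix(hi, nr, nc - nc %/% 2L))
}

two_block_labels <- function(nr = 16L, nc = 16L) {
  cbind(matrix(1L, nr, nc %/% 2L), matrix(2L, nr, nc - nc %/% 2L))
}
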