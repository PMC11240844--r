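#' Yager non-membership degrees
#'
#' The Yager fuzzy-complement generator
#' \deqn{\lambda = (1 - u^\alpha)^{1/\alpha}}
#' applied elementwise. At alpha = 1 this is the standard complement
#' 1 - u. Alpha is restricted to (0, 1], which guarantees
#' \eqn{\lambda \le 1 - u} and hence a non-negative hesitation degree, so the
#' intuitionistic constraint \eqn{0 \le u + \lambda \le 1} always holds.
#'
#' @param u Numeric vector/matrix of membership degrees in [0, 1].
#' @param alpha Complement parameter in (0, 1].
#' @return Non-membership degrees, same shape as `u`, in [0, 1].
#' @export
#' @examples
#' yager_nonmembership(0.25, 0.5)  # (1 - 0.5)^2 = 0.25
yager_nonmembership <- function(u, alpha) {
  check_alpha(alpha)
  if (any(u < 0 | u > 1)) stop("memberships must lie in [0, 1]", call. = FALSE)
  if (alpha == 1) return(1 - u)
  lam <- (1 - u^alpha)^(1 / alpha)
  pmin(pmax(lam, 0), 1)
}

#' Hesitation degrees of an intuitionistic fuzzy set
#'
#' \deqn{\pi = 1 - u - \lambda}
#' which is non-negative whenever the non-membership comes from a Yager
#' complement with alpha in (0, 1]. The three degrees then satisfy
#' u + lambda + pi = 1 exactly.
#'
#' @param u Membership degrees in [0, 1].
#' @param lam Non-membership degrees in [0, 1], with u + lam <= 1.
#' @return Hesitation degrees, same shape as `u`.
#' @export
hesitation_degree <- function(u, lam) {
  if (any(dim(u) != dim(lam)) || length(u) != length(lam))
    stop("u and lam must have the same shape", call. = FALSE)
  p <- 1 - u - lam
  if (any(p < -1e-12))
    stop("u + lambda exceeds 1: not a valid intuitionistic pair", call. = FALSE)
  p
}

#' Intuitionistic membership degrees
#'
#' Adds the hesitation degree to the membership degree:
#' \deqn{\mu^* = u + \pi = 1 - \lambda.}
#' With matched inputs this is monotone non-decreasing in u and never below
#' u; at alpha = 1 (where pi = 0) it collapses back to u.
#'
#' @param u Membership degrees.
#' @param pi_deg Hesitation degrees.
#' @return Intuitionistic membership degrees, same shape as `u`.
#' @export
intuitionistic_membership <- function(u, pi_deg) {
  if (length(u) != length(pi_deg))
    stop("u and pi_deg must have the same shape", call. = FALSE)
  u + pi_deg
}

#' Weighted (normalized) membership from two membership matrices
#'
#' \deqn{w_{ik} = a_{ik}^p b_{ik}^q / \sum_i a_{ik}^p b_{ik}^q}
#' The same form serves csFCM (a = plain FCM membership mu, b = conditional
#' membership u) and csIFCM (a = intuitionistic membership mu*, b =
#' conditional spatial membership u*). A pixel whose products vanish on
#' every cluster falls back to the uniform column 1/c (with a warning).
#'
#' @param primary c x N matrix (exponent p).
#' @param secondary c x N matrix (exponent q).
#' @param p,q Non-negative weights, not both zero.
#' @return A c x N matrix with unit column sums.
#' @export
#' @examples
#' weighted_membership(cbind(c(0.75, 0.30)), cbind(c(0.45, 0.10)), 1, 2)
weighted_membership <- function(primary, secondary, p = 1, q = 2) {
  if (!all(dim(primary) == dim(secondary)))
    stop("membership matrices must have the same shape", call. = FALSE)
  if (p < 0 || q < 0 || (p == 0 && q == 0))
    stop("p and q must be non-negative and not both zero", call. = FALSE)
  raw <- primary^p * secondary^q
  tot <- colSums(raw)
  dead <- which(tot == 0)
  if (length(dead)) {
    warning(length(dead), " pixel(s) with all-zero weighted products; ",
            "using uniform membership for them", call. = FALSE)
    raw[, dead] <- 1
    tot[dead] <- nrow(raw)
  }
  sweep(raw, 2L, tot, "/")
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single number in (0, 1]", call. = FALSE)
  if (alpha > 1)
    stop("alpha > 1 would give negative hesitation degrees; ",
         "alpha is restricted to (0, 1]", call. = FALSE)
  invisible(alpha)
}
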