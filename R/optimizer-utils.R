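# Small pieces of the optimiser exposed on their own: the soft-thresholding
# operator and the Fisher-scoring working quantities. The coordinate sweeps
# themselves live in the compiled engine.

#' Soft-thresholding operator
#'
#' \eqn{S(a,b) = a - b} if \eqn{a > 0, b < |a|}; \eqn{a + b} if
#' \eqn{a < 0, b < |a|}; 0 otherwise. Vectorised over `a`.
#'
#' @param a numeric vector.
#' @param b non-negative threshold (scalar or vector recycled against `a`).
#' @export
soft_threshold <- function(a, b) {
  if (any(b < 0)) stop("threshold must be non-negative", call. = FALSE)
  sign(a) * pmax(abs(a) - b, 0)
}

#' Fisher-scoring working responses and weights
#'
#' Linearises the multinomial likelihood at the current parameters:
#' \deqn{k_{ig} = \theta_{g0} + x_i^T B\theta_g +
#'   (z_{ig} - \pi_g)/(\pi_g(1-\pi_g)), \qquad
#'   \zeta_{ig} = \pi_g(1-\pi_g),}
#' with probabilities clipped to `[clip, 1 - clip]` so both quantities stay
#' finite.
#'
#' @inheritParams log_likelihood
#' @param clip probability clipping bound.
#' @return list with n x G matrices `K` (working responses), `zeta`
#'   (weights, in (0, 1/4]) and `P` (clipped probabilities).
#' @export
working_quantities <- function(X, Z, B, Theta, theta0, clip = 1e-10) {
  X <- .as_row_matrix(X); Z <- .as_row_matrix(Z)
  eta <- sweep((X %*% B) %*% t(as.matrix(Theta)), 2, -as.numeric(theta0))
  m <- apply(eta, 1, max)
  P <- exp(eta - m)
  P <- P / rowSums(P)
  P <- pmin(pmax(P, clip), 1 - clip)
  zeta <- P * (1 - P)
  K <- eta + (Z - P) / zeta
  list(K = K, zeta = zeta, P = P)
}
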