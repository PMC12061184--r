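# Pure model functions: class probabilities, log-likelihood, network
# residual sum of squares, penalties and the full objective. No optimisation
# logic lives here.

.check_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
  invisible(x)
}

.as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Build a class indicator matrix from labels
#'
#' Converts a factor (or character/integer vector) of class labels into the
#' n x G zero/one indicator matrix used throughout the package. Each row has
#' exactly one 1.
#'
#' @param labels factor or vector of class labels; a matrix that already is
#'   an indicator matrix is validated and returned unchanged.
#' @param class_names optional character vector fixing the class order;
#'   defaults to the factor levels.
#' @return n x G indicator matrix with `class_names` as column names.
#' @export
make_class_indicator <- function(labels, class_names = NULL) {
  if (is.matrix(labels)) {
    Z <- labels
    if (any(Z != 0 & Z != 1) || any(abs(rowSums(Z) - 1) > 1e-12))
      stop("indicator matrix rows must be 0/1 and sum to 1", call. = FALSE)
    if (!is.null(class_names)) colnames(Z) <- class_names
    return(Z)
  }
  f <- if (is.factor(labels)) labels else factor(labels)
  if (!is.null(class_names)) f <- factor(as.character(f), levels = class_names)
  if (anyNA(f)) stop("labels contain values outside class_names", call. = FALSE)
  lv <- levels(f)
  Z <- matrix(0, length(f), length(lv), dimnames = list(NULL, lv))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Multinomial class probabilities from a network-based classifier
#'
#' Computes the softmax probabilities
#' \deqn{\pi_g(x) = \exp(\theta_{g0} + x^T B \theta_g) /
#'   \sum_h \exp(\theta_{h0} + x^T B \theta_h)}
#' where `B` is the p x k regulator-to-target network and `theta_g` the gth
#' row of `Theta`. Computed with max-subtraction for overflow safety; the
#' returned probabilities are clipped to `[clip, 1 - clip]` and renormalised.
#'
#' @param X numeric matrix (n x p) of regulator expression, or a length-p
#'   vector for a single sample.
#' @param B p x k network coefficient matrix.
#' @param Theta G x k classifier coefficient matrix.
#' @param theta0 length-G intercept vector.
#' @param clip lower clipping bound for probabilities.
#' @return n x G matrix of class probabilities; rows sum to 1.
#' @export
class_probabilities <- function(X, B, Theta, theta0, clip = 1e-10) {
  X <- .as_row_matrix(X)
  B <- as.matrix(B)
  Theta <- as.matrix(Theta)
  theta0 <- as.numeric(theta0)
  if (ncol(X) != nrow(B)) stop("ncol(X) must equal nrow(B)", call. = FALSE)
  if (ncol(B) != ncol(Theta)) stop("ncol(B) must equal ncol(Theta)", call. = FALSE)
  if (length(theta0) != nrow(Theta))
    stop("length(theta0) must equal nrow(Theta)", call. = FALSE)
  .check_finite(X, "X"); .check_finite(B, "B")
  .check_finite(Theta, "Theta"); .check_finite(theta0, "theta0")
  eta <- sweep((X %*% B) %*% t(Theta), 2, -theta0)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  P <- pmin(pmax(P, clip), 1 - clip)
  P / rowSums(P)
}

#' Log-likelihood of the network-based multinomial model
#'
#' Evaluates
#' \deqn{\sum_i \left( \sum_g z_{ig}(\theta_{g0} + x_i^T B \theta_g)
#'   - \log \sum_g \exp(\theta_{g0} + x_i^T B \theta_g) \right),}
#' which is the log of a categorical probability and therefore always
#' non-positive.
#'
#' @inheritParams class_probabilities
#' @param Z n x G class indicator matrix (see [make_class_indicator()]).
#' @return scalar log-likelihood (<= 0).
#' @export
log_likelihood <- function(X, Z, B, Theta, theta0) {
  X <- .as_row_matrix(X); Z <- .as_row_matrix(Z)
  if (nrow(X) != nrow(Z)) stop("X and Z must have the same rows", call. = FALSE)
  if (ncol(Z) != nrow(as.matrix(Theta)))
    stop("ncol(Z) must equal nrow(Theta)", call. = FALSE)
  eta <- sweep((X %*% B) %*% t(Theta), 2, -as.numeric(theta0))
  m <- apply(eta, 1, max)
  lse <- m + log(rowSums(exp(eta - m)))
  sum(Z * eta) - sum(lse)
}

#' Network estimation error
#'
#' The residual sum of squares of the network regressions,
#' \eqn{\frac12 \sum_j \sum_i (y_{ij} - x_i^T \beta_j)^2}.
#'
#' @inheritParams class_probabilities
#' @param Y n x k target-gene expression matrix.
#' @return non-negative scalar.
#' @export
network_rss <- function(X, Y, B) {
  X <- .as_row_matrix(X); Y <- .as_row_matrix(Y); B <- as.matrix(B)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows", call. = FALSE)
  if (ncol(X) != nrow(B) || ncol(Y) != ncol(B))
    stop("B must be ncol(X) x ncol(Y)", call. = FALSE)
  0.5 * sum((Y - X %*% B)^2)
}

#' Penalty term of the joint objective
#'
#' \deqn{\lambda_1 \sum_j \|\beta_j\|_1 + \frac{\lambda_2}{2}\sum_j
#'   \|\beta_j\|_2^2 + \lambda_3 \sum_g \|\theta_g\|_1 +
#'   \frac{\lambda_4}{2} \sum_g \theta_g^T L^s_g \theta_g}
#'
#' @inheritParams class_probabilities
#' @param lambda1,lambda2 non-negative lasso and ridge penalties on the
#'   network coefficients.
#' @param lambda3,lambda4 non-negative lasso and Laplacian penalties on the
#'   classifier coefficients.
#' @param Ls optional list of G sign-adjusted Laplacian matrices (k x k), one
#'   per class; when `NULL` the Laplacian term is taken as zero.
#' @return non-negative scalar (when each `Ls` entry is positive
#'   semidefinite).
#' @export
penalty_value <- function(B, Theta, lambda1, lambda2, lambda3, lambda4,
                          Ls = NULL) {
  if (any(c(lambda1, lambda2, lambda3, lambda4) < 0))
    stop("penalty parameters must be non-negative", call. = FALSE)
  B <- as.matrix(B); Theta <- as.matrix(Theta)
  pen <- lambda1 * sum(abs(B)) + lambda2 / 2 * sum(B^2) +
    lambda3 * sum(abs(Theta))
  if (!is.null(Ls) && lambda4 > 0) {
    if (length(Ls) != nrow(Theta))
      stop("Ls must have one matrix per class", call. = FALSE)
    for (g in seq_len(nrow(Theta))) {
      tg <- Theta[g, ]
      pen <- pen + lambda4 / 2 * drop(tg %*% Ls[[g]] %*% tg)
    }
  }
  pen
}

#' Full objective of the joint network/classifier model
#'
#' The negative log-likelihood plus network residual sum of squares plus
#' penalties; the quantity the optimiser must not increase across cycles.
#'
#' @inheritParams penalty_value
#' @inheritParams log_likelihood
#' @param Y n x k target-gene expression matrix.
#' @return scalar objective value.
#' @export
gnmc_objective <- function(X, Y, Z, B, Theta, theta0, lambda1, lambda2,
                           lambda3, lambda4, Ls = NULL) {
  -log_likelihood(X, Z, B, Theta, theta0) + network_rss(X, Y, B) +
    penalty_value(B, Theta, lambda1, lambda2, lambda3, lambda4, Ls)
}
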