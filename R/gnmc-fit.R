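# The user-facing fitting interface around the compiled coordinate-descent
# engine, plus the S3 methods of the fitted-model class.

#' Control parameters for the fitting engine
#'
#' @param max_cycles maximum number of outer cycles (working-response
#'   refresh + full coordinate sweeps).
#' @param tol relative objective-change convergence tolerance.
#' @param standardize centre and scale the columns of X and Y to unit
#'   variance before fitting (coefficients are reported on the standardized
#'   scale; see `coef(..., rescale = TRUE)`).
#' @param clip probability clipping bound used in the working quantities.
#' @return list of class `gnmc_control`.
#' @export
gnmc_control <- function(max_cycles = 100, tol = 1e-5, standardize = TRUE,
                         clip = 1e-10) {
  stopifnot(max_cycles >= 1, tol > 0, clip > 0, clip < 0.5)
  structure(list(max_cycles = as.integer(max_cycles), tol = tol,
                 standardize = standardize, clip = clip),
            class = "gnmc_control")
}

.standardize_cols <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(M = sweep(sweep(M, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

.is_square_geneset <- function(X, Y, y_missing) {
  if (y_missing) return(TRUE)
  if (ncol(X) != ncol(Y)) return(FALSE)
  cx <- colnames(X); cy <- colnames(Y)
  if (!is.null(cx) && !is.null(cy)) return(identical(cx, cy))
  isTRUE(all.equal(X, Y, check.attributes = FALSE))
}

# Shared engine wrapper. `update` toggles which parameter blocks move;
# initial values default to B = 0, Theta = 0, theta0 = centred log class
# frequencies.
.gnmc_engine <- function(X, Y, Z, lambda1, lambda2, lambda3, lambda4,
                         control, square, update_B = TRUE,
                         update_theta = TRUE, update_intercept = TRUE,
                         B_init = NULL, Theta_init = NULL,
                         theta0_init = NULL) {
  n <- nrow(X); p <- ncol(X); k <- ncol(Y); G <- ncol(Z)
  if (is.null(B_init)) B_init <- matrix(0, p, k)
  if (is.null(Theta_init)) Theta_init <- matrix(0, G, k)
  if (is.null(theta0_init)) {
    lf <- log(pmax(colMeans(Z), 1e-10))
    theta0_init <- lf - mean(lf)
  }
  gnmc_fit_cpp(X, Y, Z, lambda1, lambda2, lambda3, lambda4,
               B_init, Theta_init, as.numeric(theta0_init),
               control$max_cycles, control$tol, control$clip,
               update_B, update_theta, update_intercept,
               square, square)
}

#' Fit the joint network / multi-class classifier model
#'
#' Estimates the regulator-to-target network `B` (p x k) and the multinomial
#' classifier (`Theta`, `theta0`) jointly by minimising
#' \deqn{-\ell\ell(B,\Theta) + \frac12\|Y - XB\|_F^2
#'   + \lambda_1\sum_j\|\beta_j\|_1 + \frac{\lambda_2}2\sum_j\|\beta_j\|_2^2
#'   + \lambda_3\sum_g\|\theta_g\|_1
#'   + \frac{\lambda_4}2\sum_g\theta_g^T L^s_g\theta_g}
#' with Fisher-scoring working responses and cyclic coordinate descent with
#' soft-thresholding. The classifier features are the network-transformed
#' expressions \eqn{x^T B}.
#'
#' When `Y` is omitted (or the target genes coincide with the regulator
#' genes) the model is fitted in the square case: self-regulation
#' coefficients \eqn{\beta_{jj}} are frozen at zero and the graph Laplacian
#' penalty (`lambda4`) is active, with edge weights recomputed from the
#' current `B` at every cycle. In the rectangular case (disjoint regulator
#' and target sets) no target-target edges exist, so the Laplacian penalty
#' is structurally zero.
#'
#' Each outer cycle ends with a step-halving acceptance check against the
#' exact objective, so the recorded `objective_trace` is non-increasing; a
#' cycle in which no damped step decreases the objective stops the fit with
#' `converged = FALSE` and a warning.
#'
#' @param X n x p matrix of regulator expression (samples x genes).
#' @param labels length-n factor of class labels, or an n x G indicator
#'   matrix.
#' @param Y n x k matrix of target-gene expression; defaults to `X` (square
#'   case).
#' @param lambda1,lambda2 lasso and ridge penalties on the network
#'   coefficients (non-negative).
#' @param lambda3,lambda4 lasso and Laplacian penalties on the classifier
#'   coefficients (non-negative).
#' @param control a [gnmc_control()] list.
#' @return an object of class `gnmc` with components `B`, `Theta`, `theta0`,
#'   `lambda`, `objective_trace`, `converged`, `n_cycles`, `status`, the
#'   standardization parameters and the (standardized) training data.
#' @seealso [gnmc_select()] to choose the penalties by BIC, [predict.gnmc()].
#' @examples
#' sim <- simulate_scenario(scenario = 1, n_tf = 10, n = 60, seed = 1)
#' fit <- gnmc(sim$X, sim$labels, sim$Y, lambda1 = 5, lambda3 = 2)
#' table(predict(fit, sim$X), sim$labels)
#' @export
gnmc <- function(X, labels, Y = NULL, lambda1 = 0, lambda2 = 0, lambda3 = 0,
                 lambda4 = 0, control = gnmc_control()) {
  cl <- match.call()
  X <- as.matrix(X)
  y_missing <- is.null(Y)
  if (y_missing) Y <- X
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same samples")
  if (nrow(X) < 2) stop("need at least two samples")
  .check_finite(X, "X"); .check_finite(Y, "Y")
  if (any(c(lambda1, lambda2, lambda3, lambda4) < 0))
    stop("penalty parameters must be non-negative")
  Z <- make_class_indicator(labels)
  if (nrow(Z) != nrow(X)) stop("labels must have one entry per sample")
  square <- .is_square_geneset(X, Y, y_missing)

  if (control$standardize) {
    sx <- .standardize_cols(X); sy <- .standardize_cols(Y)
  } else {
    sx <- list(M = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    sy <- list(M = Y, center = rep(0, ncol(Y)), scale = rep(1, ncol(Y)))
  }

  res <- .gnmc_engine(sx$M, sy$M, Z, lambda1, lambda2, lambda3, lambda4,
                      control, square)
  out <- .new_gnmc(res, cl, X, Y, Z, sx, sy, square,
                   list(lambda1 = lambda1, lambda2 = lambda2,
                        lambda3 = lambda3, lambda4 = lambda4), control)
  if (!out$converged)
    warning("gnmc did not converge (status: ", out$status, ")", call. = FALSE)
  out
}

.new_gnmc <- function(res, call, X, Y, Z, sx, sy, square, lambda, control,
                      subclass = character()) {
  B <- res$B
  dimnames(B) <- list(colnames(X), colnames(Y))
  Theta <- res$Theta
  dimnames(Theta) <- list(colnames(Z), colnames(Y))
  theta0 <- as.numeric(res$theta0)
  names(theta0) <- colnames(Z)
  structure(list(
    call = call, B = B, Theta = Theta, theta0 = theta0, lambda = lambda,
    objective_trace = as.numeric(res$objective_trace),
    objective = res$objective, converged = res$converged,
    status = res$status, n_cycles = res$n_cycles, square = square,
    class_names = colnames(Z), regulator_ids = colnames(X),
    target_ids = colnames(Y), n = nrow(X),
    x_center = sx$center, x_scale = sx$scale,
    y_center = sy$center, y_scale = sy$scale,
    Xs = sx$M, Ys = sy$M, Z = Z, control = control),
    class = c(subclass, "gnmc"))
}

.standardize_new <- function(object, newdata) {
  newdata <- .as_row_matrix(newdata)
  if (ncol(newdata) != length(object$x_center))
    stop("newdata must have ", length(object$x_center), " columns")
  sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
}

#' Predict classes or probabilities from a fitted model
#'
#' @param object a fitted `gnmc` object.
#' @param newdata matrix of regulator expression on the original scale
#'   (samples x p); standardization parameters from the fit are applied.
#' @param type `"class"` for the argmax-probability label (ties broken
#'   towards the lowest class index) or `"prob"` for the probability matrix.
#' @param ... unused.
#' @return factor of predicted classes, or an n x G probability matrix.
#' @export
predict.gnmc <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Xs <- .standardize_new(object, newdata)
  P <- class_probabilities(Xs, object$B, object$Theta, object$theta0,
                           clip = object$control$clip)
  colnames(P) <- object$class_names
  if (type == "prob") return(P)
  idx <- max.col(P, ties.method = "first")
  factor(object$class_names[idx], levels = object$class_names)
}

#' @export
fitted.gnmc <- function(object, ...) {
  P <- class_probabilities(object$Xs, object$B, object$Theta, object$theta0,
                           clip = object$control$clip)
  colnames(P) <- object$class_names
  P
}

#' Network regression residuals (standardized scale)
#' @param object a fitted `gnmc` object.
#' @param ... unused.
#' @export
residuals.gnmc <- function(object, ...) {
  object$Ys - object$Xs %*% object$B
}

#' Extract coefficients from a fitted model
#'
#' @param object a fitted `gnmc` object.
#' @param type `"network"` for the p x k matrix B, `"classifier"` for the
#'   G x k matrix Theta, `"intercepts"` for theta0.
#' @param rescale return network coefficients on the original expression
#'   scale (undoing the column standardization of X and Y).
#' @param ... unused.
#' @export
coef.gnmc <- function(object, type = c("network", "classifier", "intercepts"),
                      rescale = FALSE, ...) {
  type <- match.arg(type)
  switch(type,
    network = {
      B <- object$B
      if (rescale)
        B <- B * outer(1 / object$x_scale, object$y_scale)
      B
    },
    classifier = object$Theta,
    intercepts = object$theta0)
}

#' @export
print.gnmc <- function(x, ...) {
  cat("Joint network / multinomial classifier fit (gnmc)\n")
  cat(sprintf("  %d samples, %d regulators -> %d targets, %d classes%s\n",
              x$n, nrow(x$B), ncol(x$B), length(x$theta0),
              if (x$square) " (square gene set)" else ""))
  cat(sprintf("  lambda: l1=%g l2=%g l3=%g l4=%g\n", x$lambda$lambda1,
              x$lambda$lambda2, x$lambda$lambda3, x$lambda$lambda4))
  cat(sprintf("  %d cycles, %s; objective %.6g\n", x$n_cycles,
              if (x$converged) "converged" else paste0("NOT converged (",
                                                       x$status, ")"),
              x$objective))
  cat(sprintf("  nonzero: B %d/%d, Theta %d/%d\n",
              sum(abs(x$B) > 1e-8), length(x$B),
              sum(abs(x$Theta) > 1e-8), length(x$Theta)))
  invisible(x)
}

#' @export
summary.gnmc <- function(object, ...) {
  pred <- predict(object, .unstandardize(object))
  truth <- factor(object$class_names[max.col(object$Z)],
                  levels = object$class_names)
  structure(list(fit = object,
                 train_accuracy = mean(pred == truth),
                 class_counts = colSums(object$Z),
                 nnz_B = sum(abs(object$B) > 1e-8),
                 nnz_Theta = sum(abs(object$Theta) > 1e-8)),
            class = "summary.gnmc")
}

.unstandardize <- function(object) {
  sweep(sweep(object$Xs, 2, object$x_scale, "*"), 2, -object$x_center)
}

#' @export
print.summary.gnmc <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  cat("  class counts:", paste(names(x$class_counts), x$class_counts,
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Plot a fitted model
#'
#' `type = "trace"` plots the objective per outer cycle; `type = "network"`
#' plots the thresholded undirected weight graph of the fitted network
#' (square case; requires the igraph package).
#'
#' @param x a fitted `gnmc` object.
#' @param type plot type.
#' @param threshold minimum edge weight shown in the network plot.
#' @param ... passed to the underlying plot function.
#' @export
plot.gnmc <- function(x, type = c("trace", "network"), threshold = 0.5, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    plot(seq_along(x$objective_trace), x$objective_trace, type = "b",
         xlab = "outer cycle", ylab = "objective", ...)
    return(invisible(x))
  }
  if (!x$square)
    stop("network plot requires the square case (regulators == targets)")
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the network plot requires the 'igraph' package")
  W <- edge_weights(x$B)
  W[W <= threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  igraph::plot.igraph(g, ...)
  invisible(x)
}
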