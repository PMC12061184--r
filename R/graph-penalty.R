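# Weighted graph, degrees, normalised Laplacian and per-class sign-adjusted
# Laplacian derived from the current network estimate B. These drive the
# lambda4 smoothing penalty on the classifier coefficients.

#' Edge weights of the estimated gene network
#'
#' For a square network over a common gene set, the (undirected) weight of
#' the edge between genes i and j averages the two directed effects:
#' \eqn{w_{ij} = (|\beta_{ij}| + |\beta_{ji}|)/2}. Self-weights are set to 0:
#' an edge of a gene with itself contributes no smoothing between distinct
#' coefficients.
#'
#' @param B square k x k network coefficient matrix (regulators = targets).
#' @return symmetric non-negative k x k weight matrix with zero diagonal.
#' @export
edge_weights <- function(B) {
  B <- as.matrix(B)
  if (nrow(B) != ncol(B))
    stop("edge weights are only defined for a square network ",
         "(regulator set == target set)", call. = FALSE)
  W <- (abs(B) + abs(t(B))) / 2
  diag(W) <- 0
  W
}

#' Normalised graph Laplacian
#'
#' \eqn{L_{ii} = 1} when gene i has positive degree (0 otherwise) and
#' \eqn{L_{ij} = -w_{ij}/\sqrt{d_i d_j}} for edges, where
#' \eqn{d_i = \sum_j w_{ij}}. Symmetric positive semidefinite with
#' eigenvalues in [0, 2]; rows/columns of isolated genes are zero.
#'
#' @param W symmetric non-negative weight matrix with zero diagonal
#'   (see [edge_weights()]).
#' @return k x k normalised Laplacian.
#' @export
normalized_laplacian <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > 1e-10)
    stop("W must be a symmetric matrix", call. = FALSE)
  if (any(W < 0)) stop("W must be non-negative", call. = FALSE)
  d <- rowSums(W)
  k <- nrow(W)
  L <- matrix(0, k, k)
  pos <- d > 0
  diag(L) <- as.numeric(pos)
  if (any(pos)) {
    sq <- sqrt(d)
    off <- outer(pos, pos) & W != 0
    off[cbind(seq_len(k), seq_len(k))] <- FALSE
    L[off] <- -(W / outer(sq, sq))[off]
  }
  L
}

#' Sign-adjusted Laplacian
#'
#' Conjugates the normalised Laplacian by the diagonal of coefficient signs,
#' \eqn{L^s = S^T L S} with \eqn{S = \mathrm{diag}(\mathrm{sgn}(\theta_g))},
#' so the smoothing penalty acts on coefficient magnitudes regardless of
#' sign. `sgn(0)` is taken as +1, which keeps S invertible and leaves the
#' quadratic form unchanged at zero coordinates.
#'
#' @param L normalised Laplacian from [normalized_laplacian()].
#' @param theta_g length-k classifier coefficient vector for one class.
#' @return k x k matrix, elementwise `L * s %o% s`.
#' @export
sign_adjusted_laplacian <- function(L, theta_g) {
  L <- as.matrix(L)
  theta_g <- as.numeric(theta_g)
  if (length(theta_g) != nrow(L))
    stop("theta_g must have one entry per gene", call. = FALSE)
  s <- ifelse(theta_g < 0, -1, 1)
  L * tcrossprod(s)
}

#' Pairwise-difference form of the Laplacian penalty
#'
#' Evaluates \eqn{\sum_{q<j} w_{qj} (|\theta_{gq}|/\sqrt{d_q} -
#' |\theta_{gj}|/\sqrt{d_j})^2}, the smoothness-between-neighbours reading of
#' the penalty. On a graph with zero self-weights and positive degrees this
#' equals \eqn{\theta_g^T L^s \theta_g} exactly; it is exposed mainly as an
#' independent check of that identity.
#'
#' @param theta_g length-k coefficient vector.
#' @param W symmetric weight matrix with zero diagonal.
#' @param d degree vector; defaults to `rowSums(W)`.
#' @return non-negative scalar.
#' @export
laplacian_quadratic <- function(theta_g, W, d = rowSums(W)) {
  W <- as.matrix(W)
  a <- abs(as.numeric(theta_g))
  if (length(a) != nrow(W)) stop("theta_g/W dimension mismatch", call. = FALSE)
  r <- ifelse(d > 0, a / sqrt(pmax(d, .Machine$double.eps)), 0)
  tot <- 0
  idx <- which(W != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(idx) > 0)
    tot <- sum(W[idx] * (r[idx[, 1]] - r[idx[, 2]])^2)
  tot
}
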