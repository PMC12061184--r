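# Independent scalar-loop oracles used across the tests. These deliberately
# avoid the package's vectorised/compiled code paths: everything is written
# as plain elementwise loops over the model formulas.

rand_instance <- function(n = 8, p = 3, k = 4, G = 3, seed = 1,
                          sparse = FALSE) {
  set.seed(seed)
  B <- matrix(rnorm(p * k), p, k)
  Theta <- matrix(rnorm(G * k), G, k)
  if (sparse) {
    B[sample(length(B), floor(length(B) / 2))] <- 0
    Theta[sample(length(Theta), floor(length(Theta) / 2))] <- 0
  }
  z <- sample.int(G, n, replace = TRUE)
  Z <- matrix(0, n, G)
  Z[cbind(seq_len(n), z)] <- 1
  list(X = matrix(rnorm(n * p), n, p), Y = matrix(rnorm(n * k), n, k),
       Z = Z, labels = factor(z, levels = seq_len(G)),
       B = B, Theta = Theta, theta0 = rnorm(G))
}

# class probabilities by direct scalar evaluation of the softmax
oracle_probs <- function(x, B, Theta, theta0) {
  G <- nrow(Theta)
  eta <- numeric(G)
  for (g in seq_len(G)) {
    s <- theta0[g]
    for (j in seq_len(ncol(B))) {
      xb <- 0
      for (l in seq_len(nrow(B))) xb <- xb + x[l] * B[l, j]
      s <- s + xb * Theta[g, j]
    }
    eta[g] <- s
  }
  e <- exp(eta - max(eta))
  e / sum(e)
}

oracle_rss <- function(X, Y, B) {
  tot <- 0
  for (j in seq_len(ncol(Y))) for (i in seq_len(nrow(Y))) {
    fit <- 0
    for (l in seq_len(ncol(X))) fit <- fit + X[i, l] * B[l, j]
    tot <- tot + (Y[i, j] - fit)^2
  }
  tot / 2
}

oracle_penalty <- function(B, Theta, l1, l2, l3, l4, Ls = NULL) {
  tot <- 0
  for (v in B) tot <- tot + l1 * abs(v) + l2 / 2 * v^2
  for (v in Theta) tot <- tot + l3 * abs(v)
  if (!is.null(Ls)) {
    for (g in seq_len(nrow(Theta))) {
      for (q in seq_len(ncol(Theta))) for (j in seq_len(ncol(Theta)))
        tot <- tot + l4 / 2 * Theta[g, q] * Ls[[g]][q, j] * Theta[g, j]
    }
  }
  tot
}

oracle_edge_weights <- function(B) {
  k <- ncol(B)
  W <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) W[i, j] <- (abs(B[i, j]) + abs(B[j, i])) / 2
  }
  W
}

# working quantities by scalar loops (clipped probabilities)
oracle_working <- function(X, Z, B, Theta, theta0, clip = 1e-10) {
  n <- nrow(X); G <- nrow(Theta)
  K <- zeta <- P <- matrix(0, n, G)
  for (i in seq_len(n)) {
    pr <- oracle_probs(X[i, ], B, Theta, theta0)
    pr <- pmin(pmax(pr, clip), 1 - clip)
    for (g in seq_len(G)) {
      eta_ig <- theta0[g] + sum((X[i, ] %*% B) * Theta[g, ])
      P[i, g] <- pr[g]
      zeta[i, g] <- pr[g] * (1 - pr[g])
      K[i, g] <- eta_ig + (Z[i, g] - pr[g]) / zeta[i, g]
    }
  }
  list(K = K, zeta = zeta, P = P)
}

# One full outer cycle of the coordinate updates, written directly from the
# update formulas with explicit partial residuals (no incremental
# bookkeeping). Sweep order matches the engine: beta by target j then
# regulator l; theta by class g then target j; intercepts last. The working
# quantities (K, zeta) and the graph matrices are frozen at the cycle start.
oracle_cycle <- function(X, Y, Z, B, Theta, theta0, l1, l2, l3, l4,
                         square = FALSE, clip = 1e-10) {
  n <- nrow(X); p <- ncol(X); k <- ncol(Y); G <- ncol(Z)
  wq <- oracle_working(X, Z, B, Theta, theta0, clip)
  K <- wq$K; zeta <- wq$zeta
  Ls_list <- NULL
  if (square && l4 > 0) {
    W <- oracle_edge_weights(B)
    L <- normalized_laplacian(W)
    Ls_list <- lapply(seq_len(G), function(g)
      sign_adjusted_laplacian(L, Theta[g, ]))
  }
  st <- function(a, b) if (b >= abs(a)) 0 else a - sign(a) * b

  eta_partial <- function(i, g, drop_j = NULL, drop_l = NULL) {
    # linear predictor excluding the (drop_j, drop_l) beta coordinate or,
    # when drop_l is NULL, the whole theta_{g,drop_j} term
    s <- theta0[g]
    for (j in seq_len(k)) {
      if (is.null(drop_l) && !is.null(drop_j) && j == drop_j) next
      for (l in seq_len(p)) {
        if (!is.null(drop_l) && j == drop_j && l == drop_l) next
        s <- s + Theta[g, j] * B[l, j] * X[i, l]
      }
    }
    s
  }

  for (j in seq_len(k)) for (l in seq_len(p)) {
    if (square && l == j) next
    num <- 0
    for (g in seq_len(G)) {
      acc <- 0
      for (i in seq_len(n)) {
        kjl <- eta_partial(i, g, drop_j = j, drop_l = l)
        acc <- acc + X[i, l] * zeta[i, g] * (K[i, g] - kjl)
      }
      num <- num + Theta[g, j] * acc
    }
    for (i in seq_len(n)) {
      yl <- sum(B[-l, j] * X[i, -l])
      num <- num + X[i, l] * (Y[i, j] - yl)
    }
    den <- sum(X[, l]^2) + l2
    for (g in seq_len(G)) den <- den + Theta[g, j]^2 * sum(zeta[, g] * X[, l]^2)
    B[l, j] <- if (den > 0) st(num, l1) / den else 0
  }

  for (g in seq_len(G)) {
    Ls <- if (!is.null(Ls_list)) Ls_list[[g]] else NULL
    for (j in seq_len(k)) {
      f <- as.numeric(X %*% B[, j])
      num <- 0
      for (i in seq_len(n)) {
        kj <- eta_partial(i, g, drop_j = j, drop_l = NULL)
        num <- num + zeta[i, g] * (K[i, g] - kj) * f[i]
      }
      den <- sum(zeta[, g] * f^2)
      if (!is.null(Ls)) {
        num <- num - l4 * sum(Theta[g, -j] * Ls[-j, j])
        den <- den + l4 * Ls[j, j]
      }
      Theta[g, j] <- if (den > 0) st(num, l3) / den else 0
    }
  }

  for (g in seq_len(G)) {
    acc <- 0
    for (i in seq_len(n)) {
      fit <- 0
      for (j in seq_len(k)) fit <- fit + Theta[g, j] * sum(B[, j] * X[i, ])
      acc <- acc + zeta[i, g] * (K[i, g] - fit)
    }
    theta0[g] <- acc / sum(zeta[, g])
  }

  list(B = B, Theta = Theta, theta0 = theta0)
}

# penalized working-least-squares surrogate at frozen working quantities
surrogate_value <- function(X, Y, Z, B, Theta, theta0, K, zeta,
                            l1, l2, l3, l4, Ls_list = NULL) {
  eta <- sweep((X %*% B) %*% t(Theta), 2, -theta0)
  0.5 * sum(zeta * (K - eta)^2) + oracle_rss(X, Y, B) +
    oracle_penalty(B, Theta, l1, l2, l3, l4, Ls_list)
}
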