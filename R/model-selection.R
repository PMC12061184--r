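# Validation-set BIC selection of the four regularisation parameters over a
# grid, with stratified splitting utilities.

#' Default regularisation grid
#'
#' The objective uses raw (unscaled) sums over samples, so penalties that
#' actually threshold must grow with the training-set size: a null
#' coordinate's score is O(sqrt(n)). The default grid is therefore expressed
#' in multiples of `n`: lasso penalties span `n * {0.02, ..., 0.5}` (from
#' nearly-unpenalised to aggressive selection) and the quadratic penalties
#' `n * {0, 0.01, 0.1}`. When `graph = FALSE` (rectangular regulator/target
#' sets, where the target-gene graph is empty and the Laplacian penalty is
#' structurally zero) the lambda4 grid collapses to 0.
#'
#' @param n training-set size the grid is scaled by.
#' @param graph is the graph Laplacian penalty active (square gene set)?
#' @return named list of candidate values for lambda1..lambda4.
#' @export
gnmc_grid <- function(n, graph = TRUE) {
  list(lambda1 = n * c(0.02, 0.05, 0.1, 0.2, 0.5),
       lambda2 = n * c(0, 0.01, 0.1),
       lambda3 = n * c(0.02, 0.05, 0.1, 0.2, 0.5),
       lambda4 = if (graph) n * c(0, 0.01, 0.1) else 0)
}

#' Stratified split of samples into partitions
#'
#' Splits sample indices into `length(fractions)` partitions, stratified by
#' class so every class appears in every partition (requires at least
#' `length(fractions)` members per class). Uses the current RNG state.
#'
#' @param labels factor of class labels.
#' @param fractions partition fractions summing to 1, e.g. `c(.8, .1, .1)`.
#' @return list of integer index vectors, named `train`, `validation`,
#'   `test` for up to three partitions.
#' @export
stratified_split <- function(labels, fractions = c(0.8, 0.1, 0.1)) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  f <- factor(labels)
  np <- length(fractions)
  parts <- vector("list", np)
  # global partition targets (largest-remainder rounding of the totals)
  target <- diff(round(cumsum(c(0, fractions)) * length(f)))
  alloc <- rep(0, np)
  for (lv in levels(f)) {
    idx <- sample(which(f == lv))
    m <- length(idx)
    if (m < np) stop("class ", lv, " has fewer samples than partitions")
    cnt <- pmax(floor(fractions * m), 1)
    while (sum(cnt) > m) {
      j <- which.max(cnt)
      cnt[j] <- cnt[j] - 1
    }
    # hand out the remainder to the partitions furthest below their
    # global target, so the partition totals match the fractions exactly
    while (sum(cnt) < m) {
      j <- which.max((target - (alloc + cnt)) / pmax(target, 1))
      cnt[j] <- cnt[j] + 1
    }
    alloc <- alloc + cnt
    at <- 0
    for (j in seq_len(np)) {
      parts[[j]] <- c(parts[[j]], idx[at + seq_len(cnt[j])])
      at <- at + cnt[j]
    }
  }
  parts <- lapply(parts, sort)
  names(parts) <- c("train", "validation", "test")[seq_len(min(np, 3))]
  parts
}

#' Validation-set BIC of a fitted model
#'
#' \deqn{\mathrm{BIC} = -2\,\ell\ell_{vl}(\hat\theta_0^{tr}, \hat B^{tr},
#'   \hat\Theta^{tr}) + \log(n_{vl})\,\mathrm{df}}
#' where the log-likelihood is evaluated on the validation samples with the
#' training-set estimates and df is the number of nonzero entries of
#' `Theta` (entries with absolute value below `1e-8` count as zero; `B` does
#' not enter the df).
#'
#' @param object a fitted `gnmc` object (trained on the training split
#'   only).
#' @param newdata validation regulator expression matrix (original scale).
#' @param labels validation class labels.
#' @return list with components `bic`, `deviance` (the -2 log-likelihood
#'   term) and `df`.
#' @export
gnmc_bic <- function(object, newdata, labels) {
  newdata <- .as_row_matrix(newdata)
  if (nrow(newdata) < 1) stop("empty validation set", call. = FALSE)
  Z <- make_class_indicator(labels, class_names = object$class_names)
  if (nrow(Z) != nrow(newdata))
    stop("labels must match the validation samples", call. = FALSE)
  Xs <- .standardize_new(object, newdata)
  dev <- -2 * log_likelihood(Xs, Z, object$B, object$Theta, object$theta0)
  df <- sum(abs(object$Theta) > 1e-8)
  list(bic = dev + log(nrow(Z)) * df, deviance = dev, df = df)
}

#' Select regularisation parameters by validation BIC
#'
#' Fits the model on the training split for every point of the lambda grid,
#' scores each fit with [gnmc_bic()] on the validation split, and returns
#' the argmin fit. BIC ties (within 1e-9) are broken towards the largest
#' total penalty, i.e. the sparser model.
#'
#' @inheritParams gnmc
#' @param grid named list of candidate values for lambda1..lambda4; default
#'   [gnmc_grid()] scaled by the training-set size.
#' @param split list with integer index vectors `train` and `validation`
#'   into the rows of `X`; by default a stratified 7:1 carve-out.
#' @return object of class `gnmc_select`: list with the winning `fit`, its
#'   `lambda`, the full `bic_table` (one row per grid point) and the
#'   `split`.
#' @export
gnmc_select <- function(X, labels, Y = NULL, grid = NULL, split = NULL,
                        control = gnmc_control()) {
  X <- as.matrix(X)
  y_missing <- is.null(Y)
  Yfull <- if (y_missing) X else as.matrix(Y)
  square <- .is_square_geneset(X, Yfull, y_missing)
  f <- factor(labels)
  if (is.null(split)) {
    parts <- stratified_split(f, c(7, 1) / 8)
    split <- list(train = parts$train, validation = parts$validation)
  }
  tr <- split$train; vl <- split$validation
  if (length(intersect(tr, vl)) > 0) stop("train/validation overlap")
  if (is.null(grid)) grid <- gnmc_grid(length(tr), graph = square)
  gp <- expand.grid(lambda1 = grid$lambda1, lambda2 = grid$lambda2,
                    lambda3 = grid$lambda3, lambda4 = grid$lambda4,
                    KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(gp))
  stats <- matrix(NA_real_, nrow(gp), 3,
                  dimnames = list(NULL, c("bic", "deviance", "df")))
  errs <- character(nrow(gp))
  for (i in seq_len(nrow(gp))) {
    fit <- tryCatch(
      suppressWarnings(gnmc(X[tr, , drop = FALSE], f[tr],
                            Y = if (y_missing) NULL else Yfull[tr, , drop = FALSE],
                            lambda1 = gp$lambda1[i], lambda2 = gp$lambda2[i],
                            lambda3 = gp$lambda3[i], lambda4 = gp$lambda4[i],
                            control = control)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errs[i] <- conditionMessage(fit)
      next
    }
    fits[[i]] <- fit
    b <- gnmc_bic(fit, X[vl, , drop = FALSE], f[vl])
    stats[i, ] <- c(b$bic, b$deviance, b$df)
  }
  if (all(is.na(stats[, "bic"])))
    stop("all grid fits failed:\n",
         paste(unique(errs[errs != ""]), collapse = "\n"))
  best <- which(stats[, "bic"] <= min(stats[, "bic"], na.rm = TRUE) + 1e-9)
  if (length(best) > 1) {
    tot <- rowSums(gp[best, , drop = FALSE])
    best <- best[which.max(tot)]
  }
  structure(list(fit = fits[[best]],
                 lambda = as.list(gp[best, ]),
                 bic_table = cbind(gp, stats),
                 best_index = best, split = split),
            class = "gnmc_select")
}

#' @export
print.gnmc_select <- function(x, ...) {
  cat("BIC selection over", nrow(x$bic_table), "lambda combinations\n")
  cat(sprintf("  selected: l1=%g l2=%g l3=%g l4=%g (BIC %.3f, df %d)\n",
              x$lambda$lambda1, x$lambda$lambda2, x$lambda$lambda3,
              x$lambda$lambda4, x$bic_table[x$best_index, "bic"],
              as.integer(x$bic_table[x$best_index, "df"])))
  print(x$fit)
  invisible(x)
}

#' @export
predict.gnmc_select <- function(object, newdata, ...) {
  predict(object$fit, newdata, ...)
}

#' @export
coef.gnmc_select <- function(object, ...) coef(object$fit, ...)
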