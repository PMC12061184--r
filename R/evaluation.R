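# Classification and support-recovery metrics, the pre-estimated-network
# baseline, and the real-data interpretation workflow mechanics (variance
# filter, per-class network re-estimation, ANOVA screen).

#' Multi-class classification accuracy
#'
#' @param truth,predicted vectors of equal length (factors or characters).
#' @return fraction of exact matches, in [0, 1].
#' @export
classification_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  mean(as.character(truth) == as.character(predicted))
}

#' Support-recovery metrics (TPR / TNR / average)
#'
#' Compares the sparsity pattern of an estimated coefficient array to the
#' truth: TPR is the fraction of truly nonzero entries estimated nonzero,
#' TNR the fraction of truly zero entries estimated zero, and `average`
#' their mean. Entries with absolute value below `tol` count as zero.
#'
#' @param true_coef,estimated_coef arrays of identical shape.
#' @param tol zero threshold.
#' @return list with `tpr`, `tnr`, `average` (`tpr` is `NA` when the truth
#'   has no nonzero entries).
#' @export
selection_metrics <- function(true_coef, estimated_coef, tol = 1e-8) {
  if (!identical(dim(true_coef), dim(estimated_coef)) &&
      length(true_coef) != length(estimated_coef))
    stop("coefficient arrays must have the same shape", call. = FALSE)
  ts <- abs(true_coef) > tol
  es <- abs(estimated_coef) > tol
  tpr <- if (any(ts)) sum(ts & es) / sum(ts) else NA_real_
  tnr <- if (any(!ts)) sum(!ts & !es) / sum(!ts) else NA_real_
  list(tpr = tpr, tnr = tnr, average = mean(c(tpr, tnr)))
}

#' Pre-estimated-network baseline (prNW)
#'
#' Two-stage baseline: stage 1 estimates the network by per-target
#' lasso/ridge regression of Y on X only (the classifier coefficients are
#' frozen at zero, so stage 1 never sees the labels); stage 2 fits the
#' penalized multinomial classifier on the network-transformed features
#' with the network frozen. Unlike [gnmc()], the network is never revisited
#' in the light of classification error.
#'
#' @inheritParams gnmc
#' @return object of class `c("prnw", "gnmc")`; `$stage1_trace` holds the
#'   stage-1 objective trace.
#' @export
prnw <- function(X, labels, Y = NULL, lambda1 = 0, lambda2 = 0, lambda3 = 0,
                 lambda4 = 0, control = gnmc_control()) {
  cl <- match.call()
  X <- as.matrix(X)
  y_missing <- is.null(Y)
  if (y_missing) Y <- X
  Y <- as.matrix(Y)
  Z <- make_class_indicator(labels)
  square <- .is_square_geneset(X, Y, y_missing)
  if (control$standardize) {
    sx <- .standardize_cols(X); sy <- .standardize_cols(Y)
  } else {
    sx <- list(M = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    sy <- list(M = Y, center = rep(0, ncol(Y)), scale = rep(1, ncol(Y)))
  }
  s1 <- .gnmc_engine(sx$M, sy$M, Z, lambda1, lambda2, 0, 0, control, square,
                     update_theta = FALSE, update_intercept = FALSE)
  s2 <- .gnmc_engine(sx$M, sy$M, Z, lambda1, lambda2, lambda3, lambda4,
                     control, square, update_B = FALSE, B_init = s1$B)
  out <- .new_gnmc(s2, cl, X, Y, Z, sx, sy, square,
                   list(lambda1 = lambda1, lambda2 = lambda2,
                        lambda3 = lambda3, lambda4 = lambda4), control,
                   subclass = "prnw")
  out$stage1_trace <- as.numeric(s1$objective_trace)
  if (!out$converged)
    warning("prnw stage 2 did not converge (status: ", out$status, ")",
            call. = FALSE)
  out
}

# BIC selection for prNW: stage-1 fits are label-free and depend only on
# (lambda1, lambda2), so they are cached across the grid.
prnw_select <- function(X, labels, Y = NULL, grid = NULL, split = NULL,
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
  if (is.null(grid)) grid <- gnmc_grid(length(tr), graph = square)
  Xtr <- X[tr, , drop = FALSE]; Ytr <- Yfull[tr, , drop = FALSE]
  Ztr <- make_class_indicator(f[tr])
  if (control$standardize) {
    sx <- .standardize_cols(Xtr); sy <- .standardize_cols(Ytr)
  } else {
    sx <- list(M = Xtr, center = rep(0, ncol(Xtr)), scale = rep(1, ncol(Xtr)))
    sy <- list(M = Ytr, center = rep(0, ncol(Ytr)), scale = rep(1, ncol(Ytr)))
  }
  net_grid <- expand.grid(lambda1 = grid$lambda1, lambda2 = grid$lambda2,
                          KEEP.OUT.ATTRS = FALSE)
  cls_grid <- expand.grid(lambda3 = grid$lambda3, lambda4 = grid$lambda4,
                          KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  rows <- list()
  for (i in seq_len(nrow(net_grid))) {
    s1 <- .gnmc_engine(sx$M, sy$M, Ztr, net_grid$lambda1[i],
                       net_grid$lambda2[i], 0, 0, control, square,
                       update_theta = FALSE, update_intercept = FALSE)
    for (j in seq_len(nrow(cls_grid))) {
      s2 <- .gnmc_engine(sx$M, sy$M, Ztr, net_grid$lambda1[i],
                         net_grid$lambda2[i], cls_grid$lambda3[j],
                         cls_grid$lambda4[j], control, square,
                         update_B = FALSE, B_init = s1$B)
      lam <- list(lambda1 = net_grid$lambda1[i], lambda2 = net_grid$lambda2[i],
                  lambda3 = cls_grid$lambda3[j], lambda4 = cls_grid$lambda4[j])
      fit <- .new_gnmc(s2, sys.call(), Xtr, Ytr, Ztr, sx, sy, square, lam,
                       control, subclass = "prnw")
      b <- gnmc_bic(fit, X[vl, , drop = FALSE], f[vl])
      rows[[length(rows) + 1]] <- c(unlist(lam), bic = b$bic,
                                    deviance = b$deviance, df = b$df)
      tot <- sum(unlist(lam))
      if (is.null(best) || b$bic < best$bic - 1e-9 ||
          (abs(b$bic - best$bic) <= 1e-9 && tot > best$tot)) {
        best <- list(fit = fit, lambda = lam, bic = b$bic, tot = tot)
      }
    }
  }
  structure(list(fit = best$fit, lambda = best$lambda,
                 bic_table = as.data.frame(do.call(rbind, rows)),
                 split = split),
            class = c("prnw_select", "gnmc_select"))
}

#' Keep the most variable genes
#'
#' Retains the `top_n` columns with the highest sample variance, breaking
#' ties deterministically by gene id; column order of the input is
#' preserved.
#'
#' @param expression samples x genes numeric matrix with column names.
#' @param top_n number of genes to keep.
#' @export
variance_filter <- function(expression, top_n) {
  expression <- as.matrix(expression)
  if (top_n > ncol(expression))
    stop("top_n exceeds the number of genes", call. = FALSE)
  v <- apply(expression, 2, var)
  ids <- colnames(expression)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(expression)))
  keep <- order(-v, ids)[seq_len(top_n)]
  expression[, sort(keep), drop = FALSE]
}

#' Per-class network re-estimation and common edges
#'
#' Re-estimates the gene network separately on the samples of each class
#' (network regression term only, classifier frozen), keeps directed edges
#' with |coefficient| exceeding `threshold`, and reports the per-class edge
#' sets, their pairwise intersections and the edges common to all classes.
#' Coefficients are on the standardized within-class scale. Classes with
#' fewer than 3 samples are skipped with a warning.
#'
#' @param X samples x genes expression matrix (square gene set: the same
#'   genes act as regulators and targets; self-edges are excluded).
#' @param labels class labels.
#' @param lambda1,lambda2 network penalties; `lambda1 = NULL` defaults to
#'   `0.1 * n_c` for each class of size `n_c`.
#' @param threshold minimum absolute coefficient for a reported edge.
#' @param control a [gnmc_control()] list.
#' @return object of class `gnmc_networks`: list with `per_class` (named
#'   list of data frames `regulator`, `target`, `weight`), `pairwise`
#'   (common edges of each class pair) and `common` (edges present in every
#'   class network).
#' @export
class_networks <- function(X, labels, lambda1 = NULL, lambda2 = 0,
                           threshold = 0.5, control = gnmc_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("gene", seq_len(ncol(X)))
  f <- factor(labels)
  per_class <- list()
  for (lv in levels(f)) {
    idx <- which(f == lv)
    if (length(idx) < 3) {
      warning("class ", lv, " has fewer than 3 samples; skipped",
              call. = FALSE)
      next
    }
    Xc <- X[idx, , drop = FALSE]
    l1 <- if (is.null(lambda1)) 0.1 * length(idx) else lambda1
    sx <- .standardize_cols(Xc)
    Zc <- matrix(1, length(idx), 1)  # single pseudo-class; classifier frozen
    s1 <- .gnmc_engine(sx$M, sx$M, Zc, l1, lambda2, 0, 0, control,
                       square = TRUE, update_theta = FALSE,
                       update_intercept = FALSE)
    B <- s1$B
    dimnames(B) <- list(colnames(X), colnames(X))
    hit <- which(abs(B) > threshold, arr.ind = TRUE)
    per_class[[lv]] <- data.frame(
      regulator = rownames(B)[hit[, 1]],
      target = colnames(B)[hit[, 2]],
      weight = B[hit],
      stringsAsFactors = FALSE)
  }
  key <- function(df) paste(df$regulator, df$target, sep = "\r")
  classes <- names(per_class)
  pairwise <- list()
  if (length(classes) >= 2) {
    for (a in seq_along(classes)) for (b in seq_along(classes)) {
      if (a < b) {
        ka <- key(per_class[[a]])
        shared <- per_class[[a]][ka %in% key(per_class[[b]]),
                                 c("regulator", "target")]
        pairwise[[paste(classes[a], classes[b], sep = ":")]] <- shared
      }
    }
  }
  common <- if (length(per_class) > 0) {
    keys <- Reduce(intersect, lapply(per_class, key))
    df <- per_class[[1]][key(per_class[[1]]) %in% keys,
                         c("regulator", "target")]
    rownames(df) <- NULL
    df
  } else data.frame(regulator = character(), target = character())
  structure(list(per_class = per_class, pairwise = pairwise, common = common,
                 threshold = threshold),
            class = "gnmc_networks")
}

#' @export
print.gnmc_networks <- function(x, ...) {
  cat("Per-class gene networks (|coef| >", x$threshold, ")\n")
  for (nm in names(x$per_class))
    cat(sprintf("  %s: %d edges\n", nm, nrow(x$per_class[[nm]])))
  cat(sprintf("  common to all classes: %d edges\n", nrow(x$common)))
  invisible(x)
}

#' One-way ANOVA screen for differential expression
#'
#' Classic one-way ANOVA (equal-variance F test) of each gene's expression
#' across the classes, with no multiplicity correction. Genes with zero
#' within-class variance get `p = 0` and are flagged as degenerate.
#'
#' @param expression samples x genes matrix.
#' @param labels class labels (at least two classes with two or more
#'   samples each).
#' @param selected optional character vector (or logical/integer index) of
#'   genes of interest; when given, the fraction of genes with p < 0.05 is
#'   reported separately for the selected set and its complement.
#' @return list with `table` (gene, F, p, degenerate) and
#'   `significant_fraction` (named vector; `total`, plus `selected` /
#'   `complement` when `selected` is given).
#' @export
anova_screen <- function(expression, labels, selected = NULL) {
  expression <- as.matrix(expression)
  f <- factor(labels)
  if (nlevels(f) < 2 || min(tabulate(f)) < 2)
    stop("need >= 2 classes with >= 2 samples each", call. = FALSE)
  ids <- colnames(expression)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(expression)))
  res <- vapply(seq_len(ncol(expression)), function(j) {
    x <- expression[, j]
    wvar <- tapply(x, f, var)
    if (all(wvar < .Machine$double.eps, na.rm = TRUE)) {
      if (var(x) < .Machine$double.eps) return(c(NA_real_, NA_real_, 1))
      return(c(Inf, 0, 1))
    }
    ft <- oneway.test(x ~ f, var.equal = TRUE)
    c(unname(ft$statistic), unname(ft$p.value), 0)
  }, numeric(3))
  tab <- data.frame(gene = ids, F = res[1, ], p = res[2, ],
                    degenerate = res[3, ] == 1, stringsAsFactors = FALSE)
  frac <- c(total = mean(tab$p < 0.05, na.rm = TRUE))
  if (!is.null(selected)) {
    sel <- if (is.character(selected)) tab$gene %in% selected else {
      tmp <- rep(FALSE, nrow(tab)); tmp[selected] <- TRUE; tmp
    }
    frac <- c(selected = mean(tab$p[sel] < 0.05, na.rm = TRUE),
              complement = mean(tab$p[!sel] < 0.05, na.rm = TRUE), frac)
  }
  list(table = tab, significant_fraction = frac)
}
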