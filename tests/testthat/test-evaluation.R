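test_that("classification accuracy counts exact matches", {
  expect_equal(classification_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(classification_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(classification_accuracy(c(1, 2, 3, 1), c(1, 2, 3, 2)), 0.75)
  expect_error(classification_accuracy(1:3, 1:4), "equal length")
})

test_that("selection metrics match their definitions and the loop count", {
  truth <- matrix(c(1, 0, -2, 0, 0, 3), 2, 3)
  expect_equal(selection_metrics(truth, truth),
               list(tpr = 1, tnr = 1, average = 1))
  m <- selection_metrics(truth, matrix(0, 2, 3))
  expect_equal(m$tpr, 0)
  expect_equal(m$tnr, 1)
  expect_equal(m$average, 0.5)
  # no true nonzeros: TPR undefined
  expect_true(is.na(selection_metrics(matrix(0, 2, 2),
                                      matrix(1, 2, 2))$tpr))

  set.seed(41)
  tr <- matrix(rnorm(40) * (runif(40) < 0.4), 8, 5)
  es <- matrix(rnorm(40) * (runif(40) < 0.5), 8, 5)
  got <- selection_metrics(tr, es)
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(tr)) {
    if (tr[i] != 0 && es[i] != 0) tp <- tp + 1
    if (tr[i] != 0 && es[i] == 0) fn <- fn + 1
    if (tr[i] == 0 && es[i] == 0) tn <- tn + 1
    if (tr[i] == 0 && es[i] != 0) fp <- fp + 1
  }
  expect_equal(got$tpr, tp / (tp + fn))
  expect_equal(got$tnr, tn / (tn + fp))

  # symmetric under a simultaneous permutation
  perm <- sample(40)
  expect_equal(selection_metrics(tr[perm], es[perm]), got)
})

test_that("prNW's network stage never sees the labels", {
  inst <- rand_instance(n = 30, p = 4, k = 6, G = 3, seed = 43)
  f1 <- suppressWarnings(prnw(inst$X, inst$labels, inst$Y, lambda1 = 3,
                              lambda3 = 1))
  shuffled <- inst$labels[sample(30)]
  f2 <- suppressWarnings(prnw(inst$X, shuffled, inst$Y, lambda1 = 3,
                              lambda3 = 1))
  expect_identical(f1$B, f2$B)
})

test_that("prNW with a huge classifier penalty is the majority-class rule", {
  inst <- rand_instance(n = 30, p = 4, k = 6, G = 3, seed = 44)
  lab <- factor(rep(c("a", "a", "b", "c", "a"), 6))
  fit <- prnw(inst$X, lab, inst$Y, lambda1 = 3, lambda3 = 1e7)
  expect_true(all(predict(fit, inst$X) == "a"))
})

test_that("the joint fit attains an objective no worse than prNW's at
           shared penalties", {
  # labels depend on X directly while Y is pure noise: the joint model can
  # adapt B to the classification signal, prNW cannot
  set.seed(45)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(rnorm(n * 4), n, 4)
  lab <- factor(ifelse(X[, 1] + X[, 2] > 0, "u", "v"))
  lam <- list(lambda1 = 1, lambda2 = 0, lambda3 = 0.5, lambda4 = 0)
  fg <- suppressWarnings(gnmc(X, lab, Y, lam$lambda1, lam$lambda2,
                              lam$lambda3, lam$lambda4))
  fp <- suppressWarnings(prnw(X, lab, Y, lam$lambda1, lam$lambda2,
                              lam$lambda3, lam$lambda4))
  expect_lte(fg$objective, fp$objective + 1e-6)
})

test_that("variance filter keeps the most variable genes deterministically", {
  M <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(0, 10, -10, 0),
             d = c(5, 5, 5.1, 5), e = c(1, 2, 3, 5))
  expect_equal(variance_filter(M, 5), M)
  expect_equal(colnames(variance_filter(M, 2)), c("c", "e"))
  # constant gene never selected while alternatives remain
  expect_false("a" %in% colnames(variance_filter(M, 4)))
  # deterministic tie-break by gene id
  M2 <- cbind(z = c(0, 1), y = c(0, 1), x = c(0, 2))
  expect_equal(colnames(variance_filter(M2, 2)), c("y", "x"))
  expect_error(variance_filter(M, 6), "top_n")
})

test_that("per-class networks recover planted shared and private edges", {
  set.seed(46)
  n_per <- 60
  genes <- paste0("g", 1:12)
  make_class <- function(extra_from, extra_to) {
    X <- matrix(rnorm(n_per * 12), n_per, 12, dimnames = list(NULL, genes))
    # shared planted edge g1 -> g2 in every class
    X[, 2] <- 0.9 * X[, 1] + 0.3 * rnorm(n_per)
    # class-private edge
    X[, extra_to] <- 0.9 * X[, extra_from] + 0.3 * rnorm(n_per)
    X
  }
  X <- rbind(make_class(3, 4), make_class(5, 6), make_class(7, 8))
  lab <- factor(rep(c("A", "B", "C"), each = n_per))
  nets <- class_networks(X, lab, threshold = 0.5)
  key <- function(df) paste(df$regulator, df$target)
  expect_true("g1 g2" %in% key(nets$per_class$A))
  expect_true("g3 g4" %in% key(nets$per_class$A))
  expect_false("g5 g6" %in% key(nets$per_class$A))
  expect_true("g5 g6" %in% key(nets$per_class$B))
  expect_true("g7 g8" %in% key(nets$per_class$C))
  # the planted shared edge is common to all three networks (and its
  # reverse direction may be too); no class-private edge is
  common <- key(nets$common)
  expect_true("g1 g2" %in% common)
  expect_true(all(common %in% c("g1 g2", "g2 g1")))
  # common edges are contained in every per-class edge set
  for (nm in names(nets$per_class))
    expect_true(all(common %in% key(nets$per_class[[nm]])))
})

test_that("per-class networks honour thresholds and degenerate inputs", {
  set.seed(47)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  lab <- factor(rep(c("A", "B"), each = 10))
  nets <- class_networks(X, lab, threshold = Inf)
  expect_equal(nrow(nets$per_class$A), 0)
  expect_equal(nrow(nets$common), 0)
  # identical per-class data: identical edge sets, intersection = each set
  X2 <- rbind(X[1:10, ], X[1:10, ])
  nets2 <- class_networks(X2, lab, threshold = 0.3)
  expect_equal(nets2$per_class$A, nets2$per_class$B)
  expect_equal(nrow(nets2$common), nrow(nets2$per_class$A))
  # a class with fewer than 3 samples is skipped with a warning
  lab3 <- factor(c(rep("A", 18), "B", "B"))
  expect_warning(n3 <- class_networks(X, lab3, threshold = 0.5),
                 "fewer than 3")
  expect_equal(names(n3$per_class), "A")
})

test_that("the ANOVA screen matches closed-form expectations", {
  set.seed(48)
  # planted effect: means (0, 0, 5), sd 1, n = 30 per class
  lab <- factor(rep(1:3, each = 30))
  x <- rnorm(90) + c(0, 0, 5)[as.integer(lab)]
  M <- cbind(planted = x, null = rnorm(90))
  res <- anova_screen(M, lab, selected = "planted")
  expect_gt(res$table$F[1], 10)
  expect_lt(res$table$p[1], 1e-6)
  expect_equal(unname(res$significant_fraction["selected"]), 1)
  # permuting the labels destroys the planted significance
  resp <- anova_screen(M[, "planted", drop = FALSE], sample(lab))
  expect_gt(resp$table$p[1], 1e-6)
  # agreement with stats::aov on the planted gene
  a <- anova(aov(x ~ lab))
  expect_equal(res$table$F[1], a[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$table$p[1], a[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("the ANOVA screen is calibrated under the null", {
  set.seed(49)
  lab <- factor(rep(1:3, each = 20))
  M <- matrix(rnorm(60 * 300), 60, 300)
  res <- anova_screen(M, lab)
  expect_gt(unname(res$significant_fraction["total"]), 0.01)
  expect_lt(unname(res$significant_fraction["total"]), 0.12)
  # zero within-class variance is flagged
  Md <- cbind(flat = rep(c(0, 1, 2), each = 20), M[, 1])
  resd <- anova_screen(Md, lab)
  expect_true(resd$table$degenerate[1])
  expect_equal(resd$table$p[1], 0)
})
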