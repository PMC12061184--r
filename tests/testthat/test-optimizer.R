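test_that("soft-thresholding follows its branch table", {
  expect_equal(soft_threshold(2, 1), 1)
  expect_equal(soft_threshold(-2, 1), -1)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(1, 1), 0)  # b >= |a|
  expect_equal(soft_threshold(c(3, -3, 0), 2), c(1, -1, 0))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("working quantities match hand evaluation and the loop oracle", {
  # zero parameters, two classes: pi = 1/2, zeta = 1/4, K = +-2
  X <- matrix(rnorm(8), 4, 2)
  Z <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  wq <- working_quantities(X, Z, matrix(0, 2, 3), matrix(0, 2, 3), c(0, 0))
  expect_equal(wq$zeta, matrix(0.25, 4, 2))
  expect_equal(wq$K, matrix(c(2, 2, -2, -2, -2, -2, 2, 2), 4, 2))

  # extreme parameters: clipping keeps everything finite
  wq2 <- working_quantities(matrix(100, 1, 1), matrix(c(1, 0), 1),
                            matrix(10), matrix(c(10, -10), 2, 1), c(0, 0))
  expect_true(all(is.finite(wq2$K)))
  expect_true(all(wq2$zeta >= 1e-10 * (1 - 1e-10) - 1e-16))
  expect_true(all(wq2$zeta <= 0.25))

  inst <- rand_instance(n = 6, p = 3, k = 4, G = 3, seed = 8)
  got <- working_quantities(inst$X, inst$Z, inst$B, inst$Theta, inst$theta0)
  want <- oracle_working(inst$X, inst$Z, inst$B, inst$Theta, inst$theta0)
  expect_equal(got$K, want$K, tolerance = 1e-8)
  expect_equal(got$zeta, want$zeta, tolerance = 1e-10)
})

test_that("one engine cycle reproduces the formula-level reference sweep", {
  for (case in list(list(seed = 1, square = FALSE, p = 3, k = 4,
                         lam = c(0.5, 0.2, 0.3, 0)),
                    list(seed = 2, square = TRUE, p = 4, k = 4,
                         lam = c(0.4, 0.1, 0.2, 0.6)),
                    list(seed = 3, square = FALSE, p = 2, k = 5,
                         lam = c(0, 0, 0, 0)))) {
    inst <- rand_instance(n = 12, p = case$p, k = case$k, G = 3,
                          seed = case$seed)
    lam <- case$lam
    G <- 3
    lf <- log(pmax(colMeans(inst$Z), 1e-10))
    th0 <- lf - mean(lf)
    res <- gnmc:::.gnmc_engine(
      inst$X, inst$Y, inst$Z, lam[1], lam[2], lam[3], lam[4],
      gnmc_control(max_cycles = 1, tol = 1e-15, standardize = FALSE),
      square = case$square)
    ref <- oracle_cycle(inst$X, inst$Y, inst$Z,
                        matrix(0, case$p, case$k), matrix(0, G, case$k),
                        th0, lam[1], lam[2], lam[3], lam[4],
                        square = case$square)
    expect_equal(res$B, ref$B, tolerance = 1e-8)
    expect_equal(res$Theta, ref$Theta, tolerance = 1e-8)
    expect_equal(as.numeric(res$theta0), as.numeric(ref$theta0),
                 tolerance = 1e-8)
  }
})

test_that("the objective trace is non-increasing across outer cycles", {
  for (seed in 1:20) {
    set.seed(seed)
    square <- seed %% 2 == 0
    p <- if (square) 5 else 3
    k <- 5
    inst <- rand_instance(n = 25, p = p, k = k, G = 3, seed = seed + 100)
    lam <- runif(4, 0, 3)
    fit <- suppressWarnings(gnmc(
      inst$X, inst$labels, if (square) NULL else inst$Y,
      lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
      lambda4 = lam[4],
      control = gnmc_control(max_cycles = 40, tol = 1e-9)))
    tr <- fit$objective_trace
    if (length(tr) > 1)
      expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("fully penalized limit reduces to the majority-class predictor", {
  inst <- rand_instance(n = 30, p = 3, k = 4, G = 3, seed = 42)
  lab <- factor(rep(c(1, 1, 1, 2, 3), 6))
  fit <- gnmc(inst$X, lab, inst$Y, lambda1 = 1e6, lambda2 = 1e6,
              lambda3 = 1e6, lambda4 = 1e6)
  expect_equal(unname(fit$B), matrix(0, 3, 4))
  expect_equal(unname(fit$Theta), matrix(0, 3, 4))
  pred <- predict(fit, inst$X)
  expect_true(all(pred == "1"))  # majority class
})

test_that("a separable two-class toy is fit to perfect training accuracy", {
  set.seed(7)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  B_true <- diag(2)
  Y <- X %*% B_true + 0.1 * matrix(rnorm(n * 2), n, 2)
  lab <- factor(ifelse(X[, 1] > 0, "pos", "neg"))
  fit <- gnmc(X, lab, Y, lambda1 = 0.1, lambda3 = 0.1,
              control = gnmc_control(max_cycles = 200, tol = 1e-8))
  expect_equal(mean(predict(fit, X) == lab), 1.0)
})

test_that("with Theta frozen at zero the network stage is a reference lasso", {
  set.seed(9)
  n <- 40; p <- 6; k <- 3
  X <- matrix(rnorm(n * p), n, p)
  B_true <- matrix(0, p, k)
  B_true[cbind(1:3, 1:3)] <- c(1, -1.5, 0.8)
  Y <- X %*% B_true + matrix(rnorm(n * k), n, k)
  l1 <- 8
  # stage-1 of the pre-estimated-network baseline is exactly the
  # lasso-penalized network regression (Theta and intercepts frozen)
  fit <- prnw(X, factor(rep(1:2, n / 2)), Y, lambda1 = l1, lambda3 = 1e6,
              control = gnmc_control(standardize = FALSE, max_cycles = 500,
                                     tol = 1e-12))
  for (j in 1:k) {
    ref <- glmnet::glmnet(X, Y[, j], lambda = c(5, 2, 1, l1 / n) ,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
    bj <- as.numeric(coef(ref, s = l1 / n, exact = TRUE, x = X,
                          y = Y[, j]))[-1]
    expect_equal(unname(fit$B[, j]), bj, tolerance = 1e-4)
  }
})

test_that("converged coordinates are fixed points of one more update", {
  inst <- rand_instance(n = 30, p = 4, k = 5, G = 3, seed = 17)
  fit <- gnmc(inst$X, inst$labels, inst$Y, lambda1 = 2, lambda3 = 1,
              control = gnmc_control(max_cycles = 500, tol = 1e-13,
                                     standardize = FALSE))
  expect_true(fit$converged)
  again <- gnmc:::.gnmc_engine(
    inst$X, fit$Ys, fit$Z, 2, 0, 1, 0,
    gnmc_control(max_cycles = 1, tol = 1e-15, standardize = FALSE),
    square = FALSE, B_init = fit$B, Theta_init = fit$Theta,
    theta0_init = fit$theta0)
  expect_lt(max(abs(again$B - fit$B)), 1e-6)
  expect_lt(max(abs(again$Theta - fit$Theta)), 1e-6)
})

test_that("prediction ties break towards the lowest class index", {
  obj <- structure(list(
    B = matrix(0, 2, 3), Theta = matrix(0, 3, 3), theta0 = rep(0, 3),
    class_names = c("a", "b", "c"),
    x_center = c(0, 0), x_scale = c(1, 1),
    control = gnmc_control()), class = "gnmc")
  pred <- predict(obj, matrix(rnorm(10), 5, 2))
  expect_true(all(pred == "a"))
  P <- predict(obj, matrix(rnorm(10), 5, 2), type = "prob")
  expect_equal(unname(P), matrix(1 / 3, 5, 3), tolerance = 1e-12)
})

test_that("predict probabilities delegate to class_probabilities", {
  inst <- rand_instance(n = 15, p = 3, k = 4, G = 3, seed = 21)
  fit <- suppressWarnings(gnmc(inst$X, inst$labels, inst$Y, lambda1 = 1,
                               lambda3 = 1))
  Xnew <- matrix(rnorm(9), 3, 3)
  Xs <- sweep(sweep(Xnew, 2, fit$x_center), 2, fit$x_scale, "/")
  expect_equal(unname(predict(fit, Xnew, type = "prob")),
               unname(class_probabilities(Xs, fit$B, fit$Theta,
                                          fit$theta0)))
})
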