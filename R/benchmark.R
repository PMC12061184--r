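# Replicated Monte-Carlo evaluation harness: simulate, tune by BIC, fit,
# score on the held-out test partition; mirrors the layout of the accuracy
# and support-recovery tables.

# glmnet-based expression-level baselines (lasso: alpha = 1, elastic net:
# alpha = 0.5) on the target-gene expression matrix. Lambda is chosen on
# the validation split by deviance + log(n_vl) * df, the same criterion
# used for the network-based models.
.expression_baseline <- function(sim, alpha) {
  tr <- sim$split$train; vl <- sim$split$validation; te <- sim$split$test
  fit <- glmnet::glmnet(sim$Y[tr, , drop = FALSE], sim$labels[tr],
                        family = "multinomial", alpha = alpha,
                        nlambda = 50)
  Pv <- predict(fit, sim$Y[vl, , drop = FALSE], type = "response")
  Zv <- sim$Z[vl, , drop = FALSE]
  ns <- dim(Pv)[3]
  crit <- numeric(ns)
  for (s in seq_len(ns)) {
    pr <- pmin(pmax(Pv[, , s], 1e-10), 1 - 1e-10)
    dev <- -2 * sum(Zv * log(pr))
    cf <- coef(fit, s = fit$lambda[s])
    df <- sum(vapply(cf, function(m) sum(abs(m[-1, 1]) > 1e-8), numeric(1)))
    crit[s] <- dev + log(length(vl)) * df
  }
  s_best <- fit$lambda[which.min(crit)]
  pred <- predict(fit, sim$Y[te, , drop = FALSE], s = s_best, type = "class")
  cf <- coef(fit, s = s_best)
  support <- do.call(rbind, lapply(cf, function(m) as.numeric(m[-1, 1])))
  th <- selection_metrics(sim$true_Theta, support)
  list(accuracy = classification_accuracy(sim$labels[te], pred),
       theta = th)
}

.fit_and_score <- function(sim, method, grid, control) {
  tr <- sim$split$train; vl <- sim$split$validation; te <- sim$split$test
  split <- list(train = tr, validation = vl)
  if (method %in% c("gnmc", "prnw")) {
    sel <- if (method == "gnmc") {
      gnmc_select(sim$X, sim$labels, Y = sim$Y, grid = grid, split = split,
                  control = control)
    } else {
      prnw_select(sim$X, sim$labels, Y = sim$Y, grid = grid, split = split,
                  control = control)
    }
    pred <- predict(sel, sim$X[te, , drop = FALSE])
    th <- selection_metrics(sim$true_Theta, sel$fit$Theta)
    bb <- selection_metrics(sim$true_B, sel$fit$B)
    data.frame(method = method,
               accuracy = classification_accuracy(sim$labels[te], pred),
               theta_tpr = th$tpr, theta_tnr = th$tnr,
               theta_avg = th$average,
               b_tpr = bb$tpr, b_tnr = bb$tnr, b_avg = bb$average,
               lambda1 = sel$lambda$lambda1, lambda2 = sel$lambda$lambda2,
               lambda3 = sel$lambda$lambda3, lambda4 = sel$lambda$lambda4,
               stringsAsFactors = FALSE)
  } else {
    alpha <- if (method == "la") 1 else 0.5
    r <- .expression_baseline(sim, alpha)
    data.frame(method = method, accuracy = r$accuracy,
               theta_tpr = r$theta$tpr, theta_tnr = r$theta$tnr,
               theta_avg = r$theta$average,
               b_tpr = NA_real_, b_tnr = NA_real_, b_avg = NA_real_,
               lambda1 = NA_real_, lambda2 = NA_real_, lambda3 = NA_real_,
               lambda4 = NA_real_, stringsAsFactors = FALSE)
  }
}

#' Replicated benchmark of a simulation scenario
#'
#' For each replicate: simulate a dataset, select the penalties by
#' validation BIC, fit on the training split, and score test-set accuracy
#' plus support recovery of the classifier coefficients and (for the
#' network-based methods) of the network edges. All methods see the
#' identical simulated replicate (paired design). Per-replicate failures
#' are recorded and excluded from the means.
#'
#' @inheritParams simulate_scenario
#' @param methods subset of `"gnmc"` (the joint model), `"prnw"`
#'   (pre-estimated-network baseline), `"la"`, `"ela"` (expression-level
#'   lasso / elastic net via glmnet).
#' @param n_replicates number of Monte-Carlo replicates.
#' @param grid lambda grid for the network-based methods; default
#'   [gnmc_grid()].
#' @param control a [gnmc_control()] list.
#' @return object of class `gnmc_benchmark`: list with `replicates` (one
#'   row per replicate x method), `summary` (means by method), `failures`.
#' @export
run_benchmark <- function(scenario = 1,
                          mode = c("activators", "activators_inhibitors"),
                          n_tf = 10,
                          methods = c("gnmc", "prnw", "ela", "la"),
                          n_replicates = 10, n = 150, seed = 1,
                          grid = NULL, control = gnmc_control()) {
  mode <- match.arg(mode)
  methods <- match.arg(methods, c("gnmc", "prnw", "ela", "la"),
                       several.ok = TRUE)
  rows <- list()
  failures <- list()
  for (r in seq_len(n_replicates)) {
    sim <- simulate_scenario(scenario, mode, n_tf, n = n, seed = seed,
                             replicate = r)
    for (m in methods) {
      res <- tryCatch(.fit_and_score(sim, m, grid, control),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          list(replicate = r, method = m, message = conditionMessage(res))
      } else {
        res$replicate <- r
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  reps <- do.call(rbind, rows)
  num <- c("accuracy", "theta_tpr", "theta_tnr", "theta_avg",
           "b_tpr", "b_tnr", "b_avg")
  agg <- aggregate(reps[num], by = list(method = reps$method),
                   FUN = function(x) mean(x, na.rm = TRUE))
  agg <- agg[match(methods, agg$method), ]
  rownames(agg) <- NULL
  structure(list(replicates = reps, summary = agg, failures = failures,
                 scenario = scenario, mode = mode, n_tf = n_tf, n = n,
                 n_replicates = n_replicates, seed = seed),
            class = "gnmc_benchmark")
}

#' @export
print.gnmc_benchmark <- function(x, digits = 3, ...) {
  cat(sprintf("Benchmark: scenario %d (%s), %d TFs, n=%d, %d replicates\n",
              x$scenario, x$mode, x$n_tf, x$n, x$n_replicates))
  if (length(x$failures) > 0)
    cat("  failed runs excluded:", length(x$failures), "\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
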