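# Monte-Carlo scenario generators: transcription-factor driven target
# expression and multinomial class labels, so every other part of the
# package can be exercised without external data.
#
# Generating model, for T TFs each regulating 10 targets:
#   x_it ~ N(0,1)                      (TF expression)
#   y_ij = x_it beta_jt + N(0,1)       (target expression, block structure)
#   z_i  ~ Multinomial(pi_1, ..., pi_G),
#   log pi_g / pi_G = x_i' B theta_g   (intercepts zero)

.scenario_beta_values <- function(scenario, mode) {
  act <- mode == "activators"
  if (scenario %in% c(1, 2)) {
    if (act) rep(0.7, 10) else c(rep(0.7, 5), rep(-0.7, 5))
  } else if (scenario %in% c(3, 4)) {
    if (act) c(rep(0.9, 5), rep(0.7, 5)) else c(rep(0.9, 5), rep(-0.7, 5))
  } else stop("scenario must be 1, 2, 3 or 4")
}

#' True network of a simulation scenario
#'
#' Each of the `n_tf` transcription factors regulates its own block of 10
#' target genes with the scenario's effect sizes: scenarios 1-2 use 0.7 for
#' all ten targets, scenarios 3-4 use 0.9 for targets 1-5 and 0.7 for
#' targets 6-10; in `"activators_inhibitors"` mode targets 6-10 get
#' negative effects (-0.7). All cross-block entries are zero. Scenarios 3
#' and 4 share one specification and are aliases.
#'
#' @param scenario scenario id, 1-4.
#' @param mode `"activators"` or `"activators_inhibitors"`.
#' @param n_tf number of transcription factors (rows).
#' @return `n_tf` x `10 * n_tf` coefficient matrix.
#' @export
true_network <- function(scenario = 1,
                         mode = c("activators", "activators_inhibitors"),
                         n_tf = 10) {
  mode <- match.arg(mode)
  vals <- .scenario_beta_values(scenario, mode)
  B <- matrix(0, n_tf, 10 * n_tf)
  for (t in seq_len(n_tf))
    B[t, (t - 1) * 10 + 1:10] <- vals
  dimnames(B) <- list(paste0("TF", seq_len(n_tf)),
                      paste0("G", seq_len(10 * n_tf)))
  B
}

.theta_pattern <- function(scenario) {
  if (scenario %in% c(1, 3, 4)) {
    c(1, rep(1 / 5, 10), -1, rep(-1 / 20, 10),
      0.8, rep(0.8 / 5, 10), -0.8, rep(-0.8 / 20, 10))
  } else if (scenario == 2) {
    c(1, rep(1 / 10, 10), -1, rep(-1 / 10, 10),
      0.8, rep(0.8 / 10, 10), -0.8, rep(-0.8 / 10, 10))
  } else stop("scenario must be 1, 2, 3 or 4")
}

#' True classifier coefficients of a simulation scenario
#'
#' The scenario defines one 44-entry signal pattern (four lead coefficients
#' 1, -1, 0.8, -0.8, each followed by ten attenuated copies; scenario 2
#' attenuates by 1/10 instead of 1/5 and 1/20). To make the G = 3 classes
#' separable the pattern is placed on class-specific disjoint target
#' blocks: class 1 on targets 1-44, class 2 on targets 45-88, and class 3
#' is the all-zero reference. This requires at least 88 targets
#' (`n_tf >= 9`).
#'
#' @inheritParams true_network
#' @return 3 x `10 * n_tf` coefficient matrix.
#' @export
true_theta <- function(scenario = 1, n_tf = 10) {
  k <- 10 * n_tf
  pat <- .theta_pattern(scenario)
  if (k < 2 * length(pat))
    stop("need at least ", 2 * length(pat), " target genes (n_tf >= 9)")
  Theta <- matrix(0, 3, k,
                  dimnames = list(paste0("class", 1:3),
                                  paste0("G", seq_len(k))))
  Theta[1, seq_along(pat)] <- pat
  Theta[2, length(pat) + seq_along(pat)] <- pat
  Theta
}

.child_seed <- function(seed, replicate, attempt = 0) {
  (abs(as.integer(seed)) %% 100000L) * 10007L + replicate * 101L +
    attempt * 13L
}

#' Simulate one Monte-Carlo dataset
#'
#' Draws TF expression, target expression and class labels from the
#' scenario's generating model, and splits the samples into stratified
#' train / validation / test partitions. Deterministic given
#' `(seed, replicate)`. If a label draw leaves any class with fewer than
#' 3 samples the labels are redrawn with an incremented sub-seed (with a
#' message).
#'
#' @inheritParams true_network
#' @param n number of samples.
#' @param split partition fractions (train, validation, test).
#' @param seed global seed.
#' @param replicate replicate index; each replicate gets its own derived
#'   seed so it is reproducible in isolation.
#' @param Theta optional override of the true classifier coefficients
#'   (3 x 10*n_tf), e.g. all-zero to generate uniform labels.
#' @return object of class `gnmc_sim`: list with `X` (n x n_tf), `Y`
#'   (n x 10*n_tf), `labels`, `Z`, `true_B`, `true_Theta`, `split` (index
#'   vectors) and the scenario description.
#' @export
simulate_scenario <- function(scenario = 1,
                              mode = c("activators",
                                       "activators_inhibitors"),
                              n_tf = 10, n = 150,
                              split = c(0.8, 0.1, 0.1), seed = 1,
                              replicate = 1, Theta = NULL) {
  mode <- match.arg(mode)
  B <- true_network(scenario, mode, n_tf)
  if (is.null(Theta)) Theta <- true_theta(scenario, n_tf)
  k <- ncol(B)
  set.seed(.child_seed(seed, replicate))
  X <- matrix(rnorm(n * n_tf), n, n_tf,
              dimnames = list(NULL, rownames(B)))
  Y <- X %*% B + matrix(rnorm(n * k), n, k)
  colnames(Y) <- colnames(B)
  eta <- (X %*% B) %*% t(Theta)           # theta0 = 0
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta) / rowSums(exp(eta))
  draw_labels <- function() {
    apply(P, 1, function(pr) sample.int(3, 1, prob = pr))
  }
  z <- draw_labels()
  attempt <- 0
  while (min(tabulate(z, 3)) < 3 && attempt < 50) {
    attempt <- attempt + 1
    message("degenerate class draw; redrawing labels (attempt ", attempt, ")")
    set.seed(.child_seed(seed, replicate, attempt))
    z <- draw_labels()
  }
  labels <- factor(paste0("class", z), levels = paste0("class", 1:3))
  parts <- stratified_split(labels, split)
  structure(list(X = X, Y = Y, labels = labels,
                 Z = make_class_indicator(labels),
                 true_B = B, true_Theta = Theta,
                 split = parts,
                 scenario = scenario, mode = mode, n_tf = n_tf, n = n,
                 seed = seed, replicate = replicate),
            class = "gnmc_sim")
}

#' @export
print.gnmc_sim <- function(x, ...) {
  cat(sprintf("Simulated dataset: scenario %d (%s), %d TFs, %d targets, n=%d\n",
              x$scenario, x$mode, x$n_tf, ncol(x$Y), x$n))
  cat("  class counts:", paste(levels(x$labels), tabulate(x$labels),
                               sep = "=", collapse = " "), "\n")
  cat("  split:", paste(names(x$split), lengths(x$split), sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}
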