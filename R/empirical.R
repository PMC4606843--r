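#' Moment estimate of the effect and its known-variance z statistic
#'
#' Computes the design's moment estimator of the intervention effect
#' \eqn{\delta} from the scale scores, and the test statistic that uses
#' the *true* generating variances (the known-variance form under which
#' the closed-form power functions are derived):
#' \describe{
#'   \item{prepost}{\eqn{\hat\delta = (\bar S_{post} - \bar S_{pre})/k},
#'     \eqn{Var(\hat\delta) = 2(1/\rho - 1)\sigma_\mu^2/(kN)}.}
#'   \item{betweenwithin}{\eqn{\hat\delta = (\bar D_{trt} -
#'     \bar D_{ctl})/k} with \eqn{D} the per-subject pre-post change,
#'     \eqn{Var(\hat\delta) = 4(1/\rho - 1)\sigma_\mu^2/(kN)}.}
#'   \item{twosample}{\eqn{\hat\delta = (\bar S_{trt} - \bar S_{ctl})/k},
#'     \eqn{Var(\hat\delta) = 2(1/\rho + k - 1)\sigma_\mu^2/(kN)}.}
#' }
#' Under the model the statistic `z = delta_hat / sqrt(var_delta_hat)` is
#' standard normal when \eqn{\delta = 0}.
#'
#' @param dataset an [simulate_design()] result (class `"item_dataset"`)
#'   for a `"prepost"`, `"betweenwithin"` or `"twosample"` design.
#' @return list with `delta_hat` (score units), `var_delta_hat` (the true
#'   sampling variance), and `z`.
#' @export
estimate_delta <- function(dataset) {
  stopifnot(inherits(dataset, "item_dataset"))
  design <- dataset$design
  model <- design$model
  k <- model$k
  n <- design$n
  g <- dataset$groups
  est <- switch(design$design,
    prepost = {
      s <- g$group1$scores
      (mean(scale_scores(s$post)) - mean(scale_scores(s$pre))) / k
    },
    betweenwithin = {
      d1 <- scale_scores(g$treatment$scores$post) -
            scale_scores(g$treatment$scores$pre)
      d0 <- scale_scores(g$control$scores$post) -
            scale_scores(g$control$scores$pre)
      (mean(d1) - mean(d0)) / k
    },
    twosample = {
      (mean(scale_scores(g$treatment$scores$obs)) -
       mean(scale_scores(g$control$scores$obs))) / k
    },
    stop("no effect estimator for the '", design$design, "' design",
         call. = FALSE))
  v <- switch(design$design,
    prepost = 2 * (1 / model$rho - 1) * model$sigma_mu2 / (k * n),
    betweenwithin = 4 * (1 / model$rho - 1) * model$sigma_mu2 / (k * n),
    twosample = 2 * (1 / model$rho + k - 1) * model$sigma_mu2 / (k * n))
  list(delta_hat = est, var_delta_hat = v,
       z = if (v > 0) est / sqrt(v) else NA_real_)
}

#' Design-appropriate t-test on a simulated dataset
#'
#' The test a practitioner would run, treating the variances as unknown:
#' \describe{
#'   \item{prepost}{one-sample t-test on the per-subject scale-score
#'     changes (the paired t-test).}
#'   \item{betweenwithin}{two-sample t-test comparing per-subject pre-post
#'     changes between groups (pooled variance by default; this is the
#'     t-test whose known-variance analogue is the interaction z
#'     statistic).}
#'   \item{twosample}{two-sample t-test on the scale scores (pooled
#'     variance by default).}
#' }
#' A degenerate zero-variance difference vector (possible only with
#' error-free items and no shift) returns p = 1 by convention so Monte
#' Carlo loops stay total; a constant non-zero difference returns p = 0.
#'
#' @param dataset an `"item_dataset"` for one of the three comparison
#'   designs.
#' @param welch use the Welch (unequal-variance) two-sample test instead
#'   of the pooled one. The model guarantees equal arm variances, so
#'   pooled is the default.
#' @return the two-sided p-value.
#' @export
run_test <- function(dataset, welch = FALSE) {
  stopifnot(inherits(dataset, "item_dataset"))
  g <- dataset$groups
  switch(dataset$design$design,
    prepost = {
      d <- scale_scores(g$group1$scores$post) -
           scale_scores(g$group1$scores$pre)
      safe_t_p(d)
    },
    betweenwithin = {
      d1 <- scale_scores(g$treatment$scores$post) -
            scale_scores(g$treatment$scores$pre)
      d0 <- scale_scores(g$control$scores$post) -
            scale_scores(g$control$scores$pre)
      safe_t_p(d1, d0, welch)
    },
    twosample = {
      safe_t_p(scale_scores(g$treatment$scores$obs),
               scale_scores(g$control$scores$obs), welch)
    },
    stop("no t-test for the '", dataset$design$design, "' design",
         call. = FALSE))
}

safe_t_p <- function(x, y = NULL, welch = FALSE) {
  if (length(x) < 2L || (!is.null(y) && length(y) < 2L)) {
    stop("need at least 2 subjects per arm", call. = FALSE)
  }
  # a constant vector up to floating-point noise (error-free items)
  flat <- function(v) stats::sd(v) <= 1e-10 * max(1, abs(mean(v)))
  degenerate <- if (is.null(y)) flat(x) else flat(x) && flat(y)
  if (degenerate) {
    shift <- if (is.null(y)) mean(x) else mean(x) - mean(y)
    return(if (shift == 0) 1 else 0)
  }
  if (is.null(y)) {
    stats::t.test(x)$p.value
  } else {
    stats::t.test(x, y, var.equal = !welch)$p.value
  }
}

#' Monte Carlo empirical power of a design
#'
#' Replicates [simulate_design()] + [run_test()] `nreps` times and
#' reports the proportion of replicates with two-sided p strictly below
#' the design's significance level, together with its binomial standard
#' error \eqn{\sqrt{\hat p(1-\hat p)/nreps}} and the matching closed-form
#' power for side-by-side comparison.
#'
#' @param design a [cron_design()] object for a `"prepost"`,
#'   `"betweenwithin"` or `"twosample"` design.
#' @param nreps number of Monte Carlo replicates (default 1000).
#' @param seed integer root seed; per-replicate seeds are spawned from it
#'   so the result is deterministic.
#' @param welch passed to [run_test()].
#' @return an object of class `"empirical_power"`: list with `p_hat`,
#'   `n_reps`, `mc_se`, `seed`, `theoretical`, `design`.
#' @examples
#' d <- cron_design("twosample", n = 50, delta = 0.7, k = 5, c_alpha = 0.5)
#' empirical_power(d, nreps = 200, seed = 1)
#' @export
empirical_power <- function(design, nreps = 1000, seed = 1L,
                            welch = FALSE) {
  stopifnot(inherits(design, "cron_design"))
  if (design$design == "alpha") {
    stop("use empirical_testretest() for the alpha design", call. = FALSE)
  }
  if (nreps < 1) stop("'nreps' must be >= 1", call. = FALSE)
  seeds <- replicate_seeds(seed, nreps)
  rej <- vapply(seeds, function(s) {
    run_test(simulate_design(design, seed = s), welch) < design$sig.level
  }, logical(1))
  p_hat <- mean(rej)
  structure(list(p_hat = p_hat, n_reps = nreps,
                 mc_se = sqrt(p_hat * (1 - p_hat) / nreps),
                 seed = seed, theoretical = theoretical_power(design),
                 design = design),
            class = "empirical_power")
}

#' @export
print.empirical_power <- function(x, ...) {
  cat(sprintf(
    "Empirical power: %.4f (MC SE %.4f, %d replicates, seed %s)\n",
    x$p_hat, x$mc_se, x$n_reps, format(x$seed)))
  cat(sprintf("Theoretical power: %.4f\n", x$theoretical))
  invisible(x)
}

#' Monte Carlo test-retest correlation
#'
#' Simulates repeated administrations with shared true scores and no
#' shift, and averages the Pearson correlation of the two scale scores
#' over replicates. Under the model this converges to Cronbach alpha,
#' which is what lets the significance of alpha be tested as that of a
#' correlation.
#'
#' @param design a [cron_design()] object; any design is accepted but the
#'   administrations are always a no-shift test/retest pair.
#' @param nreps number of Monte Carlo replicates (default 1000).
#' @param seed integer root seed.
#' @return an object of class `"empirical_testretest"`: list with
#'   `mean_corr`, `corrs` (per replicate), `n_reps`, `seed`,
#'   `c_alpha` (the population value it estimates).
#' @examples
#' d <- cron_design("alpha", n = 30, k = 5, c_alpha = 0.5)
#' empirical_testretest(d, nreps = 200, seed = 1)
#' @export
empirical_testretest <- function(design, nreps = 1000, seed = 1L) {
  stopifnot(inherits(design, "cron_design"))
  tr_design <- design
  tr_design$design <- "alpha"
  tr_design$delta <- 0
  seeds <- replicate_seeds(seed, nreps)
  corrs <- vapply(seeds, function(s) {
    ds <- simulate_design(tr_design, seed = s)
    stats::cor(scale_scores(ds$groups$group1$scores$test),
               scale_scores(ds$groups$group1$scores$retest))
  }, numeric(1))
  structure(list(mean_corr = mean(corrs), corrs = corrs, n_reps = nreps,
                 seed = seed,
                 c_alpha = cronbach_alpha_pop(design$model)),
            class = "empirical_testretest")
}

#' @export
print.empirical_testretest <- function(x, ...) {
  cat(sprintf(
    "Mean test-retest correlation: %.4f over %d replicates (seed %s)\n",
    x$mean_corr, x$n_reps, format(x$seed)))
  cat(sprintf("Population Cronbach alpha: %.4f\n", x$c_alpha))
  invisible(x)
}
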