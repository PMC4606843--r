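#' Study design using a parallel-item instrument
#'
#' Bundles an instrument model with the comparison design whose power is of
#' interest. Four designs are supported:
#' \describe{
#'   \item{`"prepost"`}{one group measured before and after an
#'     intervention; paired comparison of scale-score means. `n` is the
#'     total number of subjects.}
#'   \item{`"betweenwithin"`}{two groups each measured pre and post;
#'     the group-by-time interaction (difference of within-group changes)
#'     is tested. `n` is the number of subjects *per group*.}
#'   \item{`"twosample"`}{two independent groups measured once;
#'     between-group comparison of scale-score means. `n` is per group.}
#'   \item{`"alpha"`}{test-retest administration with no intervention,
#'     used to test the significance of Cronbach alpha itself via the
#'     Fisher z-transformation of the test-retest correlation. `n` is the
#'     total number of subjects and `delta` is ignored.}
#' }
#'
#' @param design one of `"prepost"`, `"betweenwithin"`, `"twosample"`,
#'   `"alpha"`.
#' @param n sample size (total or per group as above); >= 2, and >= 4 for
#'   `"alpha"` (the Fisher z test needs N > 3).
#' @param delta standardized effect size \eqn{\Delta = \delta/\sigma_\mu}:
#'   the intervention shift in true-score SD units. Ignored for `"alpha"`.
#' @param k,rho,c_alpha,sigma_mu2 instrument description, passed to
#'   [parallel_items()]; give `rho` or `c_alpha`.
#' @param mu population true-score mean (score units). Only used when
#'   simulating data.
#' @param sig.level two-tailed significance level, in (0, 1).
#'
#' @return an object of class `"cron_design"`: list with elements
#'   `design`, `n`, `delta`, `model` (a `parallel_items` object), `mu`,
#'   `sig.level`.
#' @examples
#' d <- cron_design("prepost", n = 30, delta = 0.4, k = 5, c_alpha = 0.5)
#' theoretical_power(d)  # 0.341
#' @export
cron_design <- function(design = c("prepost", "betweenwithin", "twosample",
                                   "alpha"),
                        n, delta = 0, k = 5, rho = NULL, c_alpha = NULL,
                        sigma_mu2 = 1, mu = 0, sig.level = 0.05) {
  design <- match.arg(design)
  model <- parallel_items(k, rho = rho, c_alpha = c_alpha,
                          sigma_mu2 = sigma_mu2)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2 ||
      abs(n - round(n)) > 1e-8) {
    stop("'n' must be a single whole number >= 2", call. = FALSE)
  }
  n <- as.integer(round(n))
  if (design == "alpha" && n < 4L) {
    stop("the Fisher z test of alpha needs n >= 4", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta)) {
    stop("'delta' must be a single finite number", call. = FALSE)
  }
  check_prob_open(sig.level, "sig.level")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("'mu' must be a single finite number", call. = FALSE)
  }
  structure(list(design = design, n = n, delta = delta, model = model,
                 mu = mu, sig.level = sig.level),
            class = "cron_design")
}

#' @export
print.cron_design <- function(x, digits = 4, ...) {
  lab <- c(prepost = "pre-post (paired) comparison",
           betweenwithin = "between-group within-group (interaction)",
           twosample = "two-sample between-group comparison",
           alpha = "significance of Cronbach alpha (test-retest)")
  per <- if (x$design %in% c("betweenwithin", "twosample")) "per group"
         else "total"
  cat("Design:", lab[[x$design]], "\n")
  cat(sprintf("  N = %d (%s), two-tailed alpha level = %s\n",
              x$n, per, format(x$sig.level)))
  if (x$design != "alpha") {
    cat(sprintf("  standardized effect size Delta = %s\n", format(x$delta)))
  }
  cat(sprintf("  instrument: k = %d, rho = %s, Cronbach alpha = %s\n",
              x$model$k, format(x$model$rho, digits = digits),
              format(cronbach_alpha_pop(x$model), digits = digits)))
  invisible(x)
}

#' @export
summary.cron_design <- function(object, ...) {
  print(object)
  pw <- theoretical_power(object)
  cat(sprintf("  theoretical power = %s\n", format(pw, digits = 4)))
  invisible(list(design = object, power = pw))
}

#' Theoretical power of a design
#'
#' Dispatches to the closed-form power function appropriate for the
#' design: [power_prepost()], [power_between_within()],
#' [power_two_sample()], or [power_alpha_test()], evaluated at the
#' design's Cronbach alpha.
#'
#' @param design a [cron_design()] object.
#' @param ... passed on to the underlying power function (e.g.
#'   `exact_two_sided`).
#' @return the power (scalar in (0, 1)).
#' @export
theoretical_power <- function(design, ...) {
  stopifnot(inherits(design, "cron_design"))
  ca <- cronbach_alpha_pop(design$model)
  switch(design$design,
    prepost = power_prepost(design$delta, ca, design$n, design$sig.level, ...),
    betweenwithin = power_between_within(design$delta, ca, design$n,
                                         design$sig.level, ...),
    twosample = power_two_sample(design$delta, ca, design$n,
                                 design$sig.level, ...),
    alpha = power_alpha_test(ca, design$n, design$sig.level, ...))
}
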