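#' Sum of normal quantiles for power calculations
#'
#' \eqn{z_{\alpha,\varphi} = \Phi^{-1}(1 - \alpha/2) + \Phi^{-1}(\varphi)},
#' the quantity whose square appears in every sample-size formula here.
#'
#' @param sig.level two-tailed significance level, strictly in (0, 1).
#' @param power target power, strictly in (0, 1).
#' @return the scalar \eqn{z_{\alpha,\varphi}}.
#' @examples
#' z_pair(0.05, 0.80)  # 2.8016
#' @export
z_pair <- function(sig.level, power) {
  check_prob_open(sig.level, "sig.level")
  check_prob_open(power, "power")
  stats::qnorm(1 - sig.level / 2) + stats::qnorm(power)
}

#' Power of the significance test of Cronbach alpha
#'
#' Because the test-retest correlation of parallel-item scale scores
#' equals Cronbach alpha, the significance of alpha against a zero null
#' can be tested as the significance of a Pearson correlation through the
#' Fisher z-transformation. The power of the two-tailed test at level
#' `sig.level` is
#' \deqn{\varphi = 1 - \Phi\left[\Phi^{-1}(1-\alpha/2) - \sqrt{N-3}
#'   \left(\tfrac{1}{2}\log\frac{1+C_\alpha}{1-C_\alpha}
#'   + \frac{C_\alpha}{2(N-1)}\right)\right],}
#' where the second term in the inner parenthesis is the usual small-sample
#' mean correction of the transformed correlation. The probability mass in
#' the opposite rejection tail is ignored by default (it is negligible for
#' any non-null alpha); set `exact_two_sided = TRUE` to add it.
#'
#' @param c_alpha true Cronbach alpha, strictly in (0, 1).
#' @param n total number of subjects, >= 4.
#' @param sig.level two-tailed significance level.
#' @param exact_two_sided add the opposite rejection tail (default FALSE,
#'   the single-tail convention used throughout).
#' @return the power.
#' @examples
#' power_alpha_test(0.5, 30)  # 0.826
#' @export
power_alpha_test <- function(c_alpha, n, sig.level = 0.05,
                             exact_two_sided = FALSE) {
  check_prob_open(c_alpha, "c_alpha")
  check_prob_open(sig.level, "sig.level")
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    stop("'n' must be >= 4 for the Fisher z test", call. = FALSE)
  }
  zc <- stats::qnorm(1 - sig.level / 2)
  shift <- sqrt(n - 3) * (atanh(c_alpha) + c_alpha / (2 * (n - 1)))
  pw <- 1 - stats::pnorm(zc - shift)
  if (exact_two_sided) pw <- pw + stats::pnorm(-zc - shift)
  pw
}

#' Power of the pre-post (paired) comparison
#'
#' Power of the paired test of the mean pre-post change in scale scores,
#' as a function of Cronbach alpha only:
#' \deqn{\varphi_{PP} = \Phi\left\{|\Delta|
#'   \sqrt{\frac{N}{2(1/C_\alpha - 1)}} - \Phi^{-1}(1-\alpha/2)\right\},}
#' with \eqn{\Delta = \delta/\sigma_\mu} the standardized effect size and
#' `N` the total number of subjects. The power does not depend on the
#' number of items: instruments with equal alpha have equal power. Only
#' the rejection tail on the side of the effect is counted by default.
#'
#' @param delta standardized effect size \eqn{\Delta}.
#' @param c_alpha Cronbach alpha, strictly in (0, 1) (at alpha = 1 the
#'   paired difference is degenerate, at 0 its variance is infinite).
#' @param n total number of subjects, >= 2.
#' @param sig.level two-tailed significance level.
#' @param exact_two_sided add the opposite rejection tail.
#' @return the power; equals `sig.level / 2` at `delta = 0`.
#' @examples
#' power_prepost(0.4, 0.5, 30)  # 0.341
#' @export
power_prepost <- function(delta, c_alpha, n, sig.level = 0.05,
                          exact_two_sided = FALSE) {
  check_prob_open(c_alpha, "c_alpha")
  power_shift(abs(delta) * sqrt(n / (2 * (1 / c_alpha - 1))),
              sig.level, exact_two_sided, n)
}

#' Power of the between-group within-group (interaction) comparison
#'
#' Power of the test of equality of pre-post changes between two groups of
#' `n` subjects each:
#' \deqn{\varphi_{BW} = \Phi\left\{|\Delta|
#'   \sqrt{\frac{N}{4(1/C_\alpha - 1)}} - \Phi^{-1}(1-\alpha/2)\right\}.}
#' Identical to [power_prepost()] except for the factor 4 (two independent
#' within-group changes are differenced) and the per-group `n` convention.
#'
#' @inheritParams power_prepost
#' @param n number of subjects per group, >= 2.
#' @return the power.
#' @examples
#' power_between_within(0.4, 0.5, 30)  # 0.194
#' @export
power_between_within <- function(delta, c_alpha, n, sig.level = 0.05,
                                 exact_two_sided = FALSE) {
  check_prob_open(c_alpha, "c_alpha")
  power_shift(abs(delta) * sqrt(n / (4 * (1 / c_alpha - 1))),
              sig.level, exact_two_sided, n)
}

#' Power of the two-sample between-group comparison
#'
#' Power of the cross-sectional comparison of scale-score means between
#' two independent groups of `n` subjects each:
#' \deqn{\varphi_{TS} = \Phi\left\{|\Delta|\sqrt{C_\alpha N / 2}
#'   - \Phi^{-1}(1-\alpha/2)\right\}.}
#' Increasing in alpha under the fixed true-score-variance assumption;
#' `c_alpha = 1` (error-free measurement) is allowed and gives the
#' classical two-sample normal power.
#'
#' @inheritParams power_prepost
#' @param c_alpha Cronbach alpha, in (0, 1].
#' @param n number of subjects per group, >= 2.
#' @return the power.
#' @examples
#' power_two_sample(0.7, 0.5, 50)  # 0.697
#' @export
power_two_sample <- function(delta, c_alpha, n, sig.level = 0.05,
                             exact_two_sided = FALSE) {
  if (!is.numeric(c_alpha) || length(c_alpha) != 1L ||
      c_alpha <= 0 || c_alpha > 1) {
    stop("'c_alpha' must be in (0, 1]", call. = FALSE)
  }
  power_shift(abs(delta) * sqrt(c_alpha * n / 2),
              sig.level, exact_two_sided, n)
}

# shared tail arithmetic for the three shift-based power functions;
# n may be a continuous solution from a sample-size inversion, so only
# positivity is required here (designs enforce whole n >= 2)
power_shift <- function(shift, sig.level, exact_two_sided, n) {
  check_prob_open(sig.level, "sig.level")
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("'n' must be positive", call. = FALSE)
  }
  zc <- stats::qnorm(1 - sig.level / 2)
  pw <- stats::pnorm(shift - zc)
  if (exact_two_sided) pw <- pw + stats::pnorm(-shift - zc)
  pw
}

#' Power parameterized by the inter-item correlation
#'
#' The same three power functions written in terms of the inter-item
#' correlation `rho` and the number of items `k` instead of Cronbach
#' alpha:
#' \deqn{\varphi_{PP} = \Phi\{|\Delta|\sqrt{kN / (2(1/\rho-1))} - z_c\},
#'  \quad \varphi_{BW} = \Phi\{|\Delta|\sqrt{kN / (4(1/\rho-1))} - z_c\},}
#' \deqn{\varphi_{TS} = \Phi\{|\Delta|\sqrt{kN / (2(1/\rho+k-1))} - z_c\}.}
#' Any `(rho, k)` pair mapping to the same alpha gives the same power, so
#' these agree exactly with the alpha-parameterized forms after
#' [alpha_from_rho()] conversion.
#'
#' @param design `"prepost"`, `"betweenwithin"`, or `"twosample"`.
#' @param delta standardized effect size \eqn{\delta/\sigma_\mu}.
#' @param rho inter-item correlation, strictly in (0, 1).
#' @param k number of items (>= 1; non-integral values are accepted so
#'   that item-count solutions can be checked by substitution).
#' @param n total subjects (`"prepost"`) or subjects per group.
#' @param sig.level two-tailed significance level.
#' @param exact_two_sided add the opposite rejection tail.
#' @return the power.
#' @examples
#' power_rho(delta = 0.4, rho = 0.5, k = 5, n = 30)  # = power_prepost at
#' power_prepost(0.4, alpha_from_rho(0.5, 5), 30)    # alpha = 0.8333
#' @export
power_rho <- function(design = c("prepost", "betweenwithin", "twosample"),
                      delta, rho, k, n, sig.level = 0.05,
                      exact_two_sided = FALSE) {
  design <- match.arg(design)
  check_prob_open(rho, "rho")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("'k' must be positive", call. = FALSE)
  }
  shift <- switch(design,
    prepost = abs(delta) * sqrt(k * n / (2 * (1 / rho - 1))),
    betweenwithin = abs(delta) * sqrt(k * n / (4 * (1 / rho - 1))),
    twosample = abs(delta) * sqrt(k * n / (2 * (1 / rho + k - 1))))
  power_shift(shift, sig.level, exact_two_sided, n)
}

# -- sample size ---------------------------------------------------------

#' Required sample size for a target power
#'
#' Closed-form inverses of the power functions:
#' \deqn{N_{PP} = \frac{2(1/C_\alpha - 1)\,z_{\alpha,\varphi}^2}{\Delta^2},
#' \quad N_{BW} = \frac{4(1/C_\alpha - 1)\,z_{\alpha,\varphi}^2}{\Delta^2},
#' \quad N_{TS} = \frac{2\,z_{\alpha,\varphi}^2}{C_\alpha \Delta^2},}
#' with \eqn{z_{\alpha,\varphi}} from [z_pair()]. `samplesize_prepost()`
#' returns a total N; the other two return subjects per group. All are
#' decreasing in alpha and in the effect size. The continuous solution is
#' returned together with its ceiling (the conservative integer choice);
#' substituting the continuous solution back into the matching power
#' function recovers the target power exactly.
#'
#' @param delta standardized effect size, non-zero.
#' @param c_alpha Cronbach alpha (strictly in (0, 1); `(0, 1]` for the
#'   two-sample design).
#' @param sig.level two-tailed significance level.
#' @param power target power, strictly in (0, 1).
#' @return an object of class `"cron_samplesize"`: list with `n`
#'   (continuous solution), `n_ceiling`, and the inputs.
#' @examples
#' samplesize_prepost(0.4, 0.5, power = 0.80)     # N = 98.11, ceiling 99
#' samplesize_two_sample(0.7, 0.5, power = 0.80)  # N = 64.06 per group
#' @export
samplesize_prepost <- function(delta, c_alpha, sig.level = 0.05,
                               power = 0.80) {
  check_prob_open(c_alpha, "c_alpha")
  check_delta_nonzero(delta)
  n <- 2 * (1 / c_alpha - 1) * z_pair(sig.level, power)^2 / delta^2
  new_samplesize(n, "prepost", delta, c_alpha, sig.level, power)
}

#' @rdname samplesize_prepost
#' @export
samplesize_between_within <- function(delta, c_alpha, sig.level = 0.05,
                                      power = 0.80) {
  check_prob_open(c_alpha, "c_alpha")
  check_delta_nonzero(delta)
  n <- 4 * (1 / c_alpha - 1) * z_pair(sig.level, power)^2 / delta^2
  new_samplesize(n, "betweenwithin", delta, c_alpha, sig.level, power)
}

#' @rdname samplesize_prepost
#' @export
samplesize_two_sample <- function(delta, c_alpha, sig.level = 0.05,
                                  power = 0.80) {
  if (!is.numeric(c_alpha) || length(c_alpha) != 1L ||
      c_alpha <= 0 || c_alpha > 1) {
    stop("'c_alpha' must be in (0, 1]", call. = FALSE)
  }
  check_delta_nonzero(delta)
  n <- 2 * z_pair(sig.level, power)^2 / (c_alpha * delta^2)
  new_samplesize(n, "twosample", delta, c_alpha, sig.level, power)
}

new_samplesize <- function(n, design, delta, c_alpha, sig.level, power) {
  structure(list(n = n, n_ceiling = ceiling(n), design = design,
                 delta = delta, c_alpha = c_alpha, sig.level = sig.level,
                 power = power),
            class = "cron_samplesize")
}

#' @export
print.cron_samplesize <- function(x, ...) {
  per <- if (x$design == "prepost") "total" else "per group"
  cat(sprintf(
    "Required sample size (%s design): N = %.2f (%s), round up to %d\n",
    x$design, x$n, per, x$n_ceiling))
  cat(sprintf("  Delta = %s, Cronbach alpha = %s, sig.level = %s, power = %s\n",
              format(x$delta), format(x$c_alpha), format(x$sig.level),
              format(x$power)))
  invisible(x)
}

check_delta_nonzero <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta == 0) {
    stop("'delta' must be a single non-zero number", call. = FALSE)
  }
  invisible(delta)
}

# -- number of items -----------------------------------------------------

#' Required number of items for a target power
#'
#' For instrument development with a known inter-item correlation `rho`
#' and fixed sample size `n`, solves the rho-parameterized power function
#' for the number of items `k`:
#' \deqn{k_{PP} = \frac{2(1/\rho - 1) z_{\alpha,\varphi}^2}{N \Delta^2},
#'  \qquad
#'  k_{TS} = \frac{2(1/\rho - 1) z_{\alpha,\varphi}^2 / \Delta^2}
#'           {N - 2 z_{\alpha,\varphi}^2 / \Delta^2}.}
#' The two-sample design is feasible only when
#' \eqn{N > 2 z_{\alpha,\varphi}^2 / \Delta^2}: even an error-free
#' instrument (`rho = 1`, infinite `k`) cannot rescue a smaller group, and
#' an infeasible design raises an error.
#'
#' For the between-within design the self-consistent inversion of its
#' power function has numerator factor 4 (twice the pre-post value); a
#' variant with factor 2 also circulates in the literature. The factor-4
#' value is returned as `k` (substituting it into [power_rho()] recovers
#' the target power); the factor-2 variant is reported alongside as
#' `k_printed`.
#'
#' @param design `"prepost"`, `"betweenwithin"`, or `"twosample"`.
#' @param rho inter-item correlation, strictly in (0, 1).
#' @param n sample size (total for `"prepost"`, per group otherwise).
#' @param delta standardized effect size, non-zero.
#' @param sig.level two-tailed significance level.
#' @param power target power, strictly in (0, 1).
#' @return an object of class `"cron_items"`: list with `k` (continuous
#'   solution), `k_ceiling`, the inputs, and for `"betweenwithin"` also
#'   `k_printed`.
#' @examples
#' items_required("prepost", rho = 0.5, n = 99, delta = 0.4)  # k ~ 0.99
#' @export
items_required <- function(design = c("prepost", "betweenwithin",
                                      "twosample"),
                           rho, n, delta, sig.level = 0.05, power = 0.80) {
  design <- match.arg(design)
  check_prob_open(rho, "rho")
  check_delta_nonzero(delta)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("'n' must be >= 2", call. = FALSE)
  }
  z2 <- z_pair(sig.level, power)^2
  out <- list(design = design, rho = rho, n = n, delta = delta,
              sig.level = sig.level, power = power)
  if (design == "prepost") {
    out$k <- 2 * (1 / rho - 1) * z2 / (n * delta^2)
  } else if (design == "betweenwithin") {
    out$k <- 4 * (1 / rho - 1) * z2 / (n * delta^2)
    out$k_printed <- 2 * (1 / rho - 1) * z2 / (n * delta^2)
  } else {
    denom <- n - 2 * z2 / delta^2
    if (denom <= 0) {
      stop("infeasible design: the two-sample item-count formula needs ",
           "n > 2 * z_pair(sig.level, power)^2 / delta^2 (here n must ",
           sprintf("exceed %.2f)", 2 * z2 / delta^2), call. = FALSE)
    }
    out$k <- 2 * (1 / rho - 1) * z2 / delta^2 / denom
  }
  out$k_ceiling <- ceiling(out$k)
  structure(out, class = "cron_items")
}

#' @export
print.cron_items <- function(x, ...) {
  cat(sprintf(
    "Required number of items (%s design): k = %.3f, round up to %d\n",
    x$design, x$k, x$k_ceiling))
  if (!is.null(x$k_printed)) {
    cat(sprintf("  (factor-2 literature variant: k = %.3f)\n", x$k_printed))
  }
  cat(sprintf("  rho = %s, N = %s, Delta = %s, sig.level = %s, power = %s\n",
              format(x$rho), format(x$n), format(x$delta),
              format(x$sig.level), format(x$power)))
  invisible(x)
}
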