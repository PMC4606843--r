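#' Parallel-item instrument model
#'
#' Describes a questionnaire instrument of `k` parallel items at the
#' population level. Each item score is modelled as the subject's latent
#' true score plus an independent measurement error,
#' \eqn{Y_{ij} = \mu_i + e_{ij}}, with \eqn{Var(\mu_i) = \sigma_\mu^2}
#' (true-score variance, held fixed) and \eqn{Var(e_{ij}) = \sigma_e^2}.
#' The implied item covariance matrix is compound symmetric
#' (\eqn{\sigma_e^2 I + \sigma_\mu^2 11^T}), i.e. the items are essentially
#' tau-equivalent, and the inter-item correlation is
#' \eqn{\rho = \sigma_\mu^2 / (\sigma_\mu^2 + \sigma_e^2)}.
#'
#' The model is stored as `(k, rho, sigma_mu2)`; Cronbach alpha and all
#' variances are always derived from these, never stored, so the object can
#' not hold inconsistent duplicate state. A model may be specified through
#' `c_alpha` instead of `rho`, in which case the inter-item correlation is
#' recovered with [rho_from_alpha()].
#'
#' @param k number of items (positive whole number).
#' @param rho inter-item correlation, in (0, 1]. Exactly one of `rho` and
#'   `c_alpha` must be supplied.
#' @param c_alpha Cronbach alpha of the instrument, in (0, 1].
#' @param sigma_mu2 true-score variance \eqn{\sigma_\mu^2 > 0}
#'   (squared score units). Default 1, the conventional standardized scale.
#'
#' @return An object of class `"parallel_items"`: a list with elements
#'   `k`, `rho`, `sigma_mu2`.
#'
#' @examples
#' m <- parallel_items(k = 5, rho = 0.5)
#' cronbach_alpha_pop(m)        # 0.8333...
#' variance_decomposition(m)    # sigma_e2 = 1, sigma2 = 2
#' @seealso [alpha_from_rho()], [variance_decomposition()],
#'   [scale_score_variance()]
#' @export
parallel_items <- function(k, rho = NULL, c_alpha = NULL, sigma_mu2 = 1) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1 ||
      abs(k - round(k)) > 1e-8) {
    stop("'k' must be a single whole number >= 1", call. = FALSE)
  }
  k <- as.integer(round(k))
  if (is.null(rho) == is.null(c_alpha)) {
    stop("supply exactly one of 'rho' and 'c_alpha'", call. = FALSE)
  }
  if (is.null(rho)) {
    if (!is.numeric(c_alpha) || length(c_alpha) != 1L ||
        c_alpha <= 0 || c_alpha > 1) {
      stop("'c_alpha' must be a single number in (0, 1]", call. = FALSE)
    }
    rho <- rho_from_alpha(c_alpha, k)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1) {
    stop("'rho' must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(sigma_mu2) || length(sigma_mu2) != 1L || sigma_mu2 <= 0) {
    stop("'sigma_mu2' must be a single positive number", call. = FALSE)
  }
  structure(list(k = k, rho = rho, sigma_mu2 = sigma_mu2),
            class = "parallel_items")
}

#' @export
print.parallel_items <- function(x, digits = 4, ...) {
  vd <- variance_decomposition(x)
  cat("Parallel-item instrument model\n")
  cat(sprintf("  items (k)                 : %d\n", x$k))
  cat(sprintf("  inter-item correlation rho: %s\n", format(x$rho, digits = digits)))
  cat(sprintf("  Cronbach alpha            : %s\n",
              format(alpha_from_rho(x$rho, x$k), digits = digits)))
  cat(sprintf("  true-score variance       : %s\n",
              format(x$sigma_mu2, digits = digits)))
  cat(sprintf("  error variance sigma_e2   : %s\n",
              format(vd$sigma_e2, digits = digits)))
  cat(sprintf("  total item variance       : %s\n",
              format(vd$sigma2, digits = digits)))
  cat(sprintf("  Var(scale score S)        : %s\n",
              format(scale_score_variance(x), digits = digits)))
  invisible(x)
}

#' Cronbach alpha from the inter-item correlation
#'
#' Under compound symmetry, Cronbach alpha of `k` items with common
#' inter-item correlation `rho` is
#' \deqn{C_\alpha = \frac{k\rho}{1 + \rho(k - 1)},}
#' increasing in both `rho` and `k`. At `k = 1` it reduces to `rho` itself.
#'
#' @param rho inter-item correlation(s), in \[0, 1\].
#' @param k number of items, >= 1 (may be non-integral when inverting
#'   item-count formulas).
#' @return Cronbach alpha, same length as the longer argument (the
#'   arguments are recycled).
#' @examples
#' alpha_from_rho(0.5, 5)   # 0.8333...
#' @export
alpha_from_rho <- function(rho, k) {
  check_range(rho, "rho", 0, 1)
  check_k(k)
  k * rho / (1 + rho * (k - 1))
}

#' Inter-item correlation from Cronbach alpha
#'
#' Exact inverse of [alpha_from_rho()]:
#' \deqn{\rho = \frac{C_\alpha}{k - C_\alpha (k - 1)}.}
#'
#' @param c_alpha Cronbach alpha value(s), in \[0, 1\].
#' @inheritParams alpha_from_rho
#' @return inter-item correlation(s).
#' @examples
#' rho_from_alpha(alpha_from_rho(0.5, 5), 5)  # 0.5
#' @export
rho_from_alpha <- function(c_alpha, k) {
  check_range(c_alpha, "c_alpha", 0, 1)
  check_k(k)
  c_alpha / (k - c_alpha * (k - 1))
}

#' Population Cronbach alpha of an instrument model
#'
#' Convenience accessor: [alpha_from_rho()] evaluated at the model's
#' `rho` and `k`. Under the parallel-items model this equals both the
#' reliability of the scale score and the test-retest correlation.
#'
#' @param model a [parallel_items()] object.
#' @return Cronbach alpha in (0, 1].
#' @export
cronbach_alpha_pop <- function(model) {
  stopifnot(inherits(model, "parallel_items"))
  alpha_from_rho(model$rho, model$k)
}

#' Variance decomposition of an item score
#'
#' Under the fixed true-score-variance assumption the measurement-error
#' variance and total item variance are determined by `rho` and
#' `sigma_mu2`:
#' \deqn{\sigma_e^2 = (1/\rho - 1)\,\sigma_\mu^2, \qquad
#'       \sigma^2 = \sigma_\mu^2 / \rho = \sigma_\mu^2 + \sigma_e^2.}
#' Both are decreasing in `rho`: more consistent items have smaller errors.
#'
#' @param model a [parallel_items()] object with `rho > 0`.
#' @return list with components `sigma_e2` (error variance) and `sigma2`
#'   (total item variance).
#' @examples
#' variance_decomposition(parallel_items(5, rho = 0.25))
#' @export
variance_decomposition <- function(model) {
  stopifnot(inherits(model, "parallel_items"))
  if (model$rho <= 0) {
    stop("total variance is undefined at rho = 0", call. = FALSE)
  }
  sigma2 <- model$sigma_mu2 / model$rho
  list(sigma_e2 = sigma2 - model$sigma_mu2, sigma2 = sigma2)
}

#' Variance of the scale score
#'
#' Variance of the per-subject sum \eqn{S = \sum_j Y_{ij}} of the `k` item
#' scores:
#' \deqn{Var(S) = k \sigma^2 \{1 + \rho(k-1)\}
#'             = k \sigma_\mu^2 (1/\rho + k - 1)
#'             = k^2 \sigma_\mu^2 / C_\alpha.}
#' With the true-score variance held fixed, `Var(S)` is *decreasing* in
#' `rho` (and in Cronbach alpha): the indirect shrinkage of the total item
#' variance dominates the direct effect of the correlation on the variance
#' of a sum.
#'
#' @inheritParams variance_decomposition
#' @return `Var(S)` in squared score units.
#' @export
scale_score_variance <- function(model) {
  stopifnot(inherits(model, "parallel_items"))
  if (model$rho <= 0) stop("Var(S) is undefined at rho = 0", call. = FALSE)
  model$k * model$sigma_mu2 * (1 / model$rho + model$k - 1)
}

#' Test-retest correlation of the scale score
#'
#' When the same subjects are administered the instrument twice with a
#' shared true score and independent errors,
#' \eqn{Cov(S_{test}, S_{retest}) = k^2 \rho \sigma^2} and the correlation
#' of the two scale scores equals Cronbach alpha exactly. This is what
#' makes the test-retest correlation usable as an estimate of alpha even
#' for a single-item instrument, where the usual estimator is undefined.
#'
#' @inheritParams variance_decomposition
#' @return the test-retest correlation, numerically identical to
#'   [cronbach_alpha_pop()].
#' @export
testretest_correlation <- function(model) {
  cronbach_alpha_pop(model)
}

# -- internal argument checks -------------------------------------------

check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("'%s' must be in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

check_k <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 1)) {
    stop("'k' must be >= 1", call. = FALSE)
  }
  invisible(k)
}

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x <= 0 || x >= 1) {
    stop(sprintf("'%s' must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  }
  invisible(x)
}
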