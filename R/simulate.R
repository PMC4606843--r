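#' Simulate an item-score matrix under the parallel-items model
#'
#' Draws `n` subjects' true scores \eqn{\mu_i \sim N(\mu, \sigma_\mu^2)}
#' and, for each subject, `k` item scores
#' \eqn{Y_{ij} = \mu_i + shift + e_{ij}} with independent
#' \eqn{e_{ij} \sim N(0, \sigma_e^2)}. The shift is a location offset
#' applied to every item score (equivalently, to the construct mean); the
#' column covariance matrix is \eqn{\sigma_e^2 I + \sigma_\mu^2 11^T} in
#' expectation.
#'
#' @param n number of subjects.
#' @param model a [parallel_items()] object.
#' @param mu population true-score mean.
#' @param shift mean shift in score units (an intervention effect
#'   \eqn{\delta}).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the draw is reproducible.
#' @return a numeric `n` by `k` matrix with attribute `"true_scores"`
#'   (the vector of \eqn{\mu_i}) and columns named `item1..itemk`.
#' @examples
#' y <- simulate_scores(100, parallel_items(5, rho = 0.5), seed = 1)
#' cronbach_alpha(y)
#' @export
simulate_scores <- function(n, model, mu = 0, shift = 0, seed = NULL) {
  stopifnot(inherits(model, "parallel_items"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  true <- draw_true_scores(n, model, mu)
  draw_item_scores(true, model, shift)
}

# true scores mu_i ~ N(mu, sigma_mu2)
draw_true_scores <- function(n, model, mu) {
  mu + sqrt(model$sigma_mu2) * stats::rnorm(n)
}

# one administration: Y_ij = mu_i + shift + e_ij, errors independent per
# item and per administration
draw_item_scores <- function(true, model, shift = 0) {
  n <- length(true)
  k <- model$k
  sigma_e <- sqrt(variance_decomposition(model)$sigma_e2)
  e <- if (sigma_e > 0) {
    matrix(sigma_e * stats::rnorm(n * k), n, k)
  } else {
    matrix(0, n, k)
  }
  y <- true + shift + e
  colnames(y) <- paste0("item", seq_len(k))
  attr(y, "true_scores") <- true
  y
}

#' Scale scores (per-subject item sums)
#'
#' The analysis unit of every comparison here: \eqn{S_i = \sum_j Y_{ij}}.
#'
#' @param scores item-score matrix, rows = subjects.
#' @return numeric vector of row sums, length `nrow(scores)`.
#' @export
scale_scores <- function(scores) {
  rowSums(as_score_matrix(scores))
}

#' Simulate one dataset for a study design
#'
#' Generates the arm/administration layout the design calls for, always
#' with a shared true score across administrations of the same subject and
#' independent measurement errors per administration and item:
#' \describe{
#'   \item{prepost}{one group, `pre` and `post` matrices; `post` shifted
#'     by `delta * sigma_mu`.}
#'   \item{betweenwithin}{two independent groups (`control`, `treatment`),
#'     each with `pre` and `post`; only the treatment `post` is shifted.}
#'   \item{twosample}{two independent groups, one administration each;
#'     the treatment group is shifted.}
#'   \item{alpha}{one group, `test` and `retest` matrices, no shift.}
#' }
#' The standardized `delta` of the design is converted to score units by
#' multiplying with \eqn{\sigma_\mu}.
#'
#' @param design a [cron_design()] object.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `"item_dataset"`: list with `design` (the
#'   `cron_design`), `shift` (score-unit shift applied), and `groups`, a
#'   named list of groups each holding `true_scores` and a named list
#'   `scores` of item matrices.
#' @examples
#' d <- cron_design("prepost", n = 30, delta = 0.4, k = 5, c_alpha = 0.5)
#' ds <- simulate_design(d, seed = 7)
#' mean(scale_scores(ds$groups$group1$scores$post) -
#'      scale_scores(ds$groups$group1$scores$pre))
#' @export
simulate_design <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cron_design"))
  if (!is.null(seed)) set.seed(seed)
  model <- design$model
  n <- design$n
  mu <- design$mu
  shift <- design$delta * sqrt(model$sigma_mu2)

  one_group <- function(admins, shifts) {
    true <- draw_true_scores(n, model, mu)
    scores <- stats::setNames(
      lapply(shifts, function(s) {
        m <- draw_item_scores(true, model, s)
        attr(m, "true_scores") <- NULL
        m
      }),
      admins)
    list(true_scores = true, scores = scores)
  }

  groups <- switch(design$design,
    alpha = list(group1 = one_group(c("test", "retest"), c(0, 0))),
    prepost = list(group1 = one_group(c("pre", "post"), c(0, shift))),
    betweenwithin = list(
      control = one_group(c("pre", "post"), c(0, 0)),
      treatment = one_group(c("pre", "post"), c(0, shift))),
    twosample = list(
      control = one_group("obs", 0),
      treatment = one_group("obs", shift)))

  structure(list(design = design, shift = shift, groups = groups),
            class = "item_dataset")
}

#' @export
print.item_dataset <- function(x, ...) {
  cat("Simulated parallel-item dataset\n")
  print(x$design)
  for (g in names(x$groups)) {
    adm <- names(x$groups[[g]]$scores)
    cat(sprintf("  group '%s': N = %d, administrations: %s\n",
                g, length(x$groups[[g]]$true_scores),
                paste(adm, collapse = ", ")))
  }
  invisible(x)
}

#' Simulate replicate datasets from a design
#'
#' [stats::simulate()] method for `cron_design` objects: returns `nsim`
#' independent datasets. Replicate-level seeds are spawned from `seed`
#' once, so replicate `r` of a run is reproducible in isolation via its
#' recorded seed.
#'
#' @param object a [cron_design()] object.
#' @param nsim number of replicate datasets.
#' @param seed integer root seed (required for reproducibility; if `NULL`
#'   the current RNG state is used to spawn replicate seeds).
#' @param ... unused.
#' @return list of `nsim` [simulate_design()] results; each carries its
#'   own seed as attribute `"seed"`.
#' @export
simulate.cron_design <- function(object, nsim = 1, seed = NULL, ...) {
  seeds <- replicate_seeds(seed, nsim)
  lapply(seq_len(nsim), function(r) {
    ds <- simulate_design(object, seed = seeds[r])
    attr(ds, "seed") <- seeds[r]
    ds
  })
}

# spawn per-replicate seeds from one root seed
replicate_seeds <- function(seed, nreps) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, nreps, replace = FALSE)
}
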