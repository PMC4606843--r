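#' Reproduce a validation table
#'
#' Runs the Monte Carlo engine over one of the four benchmark parameter
#' grids used to validate the closed-form machinery and returns a tidy
#' data frame with the theoretical and empirical values side by side.
#' The grids are:
#' \describe{
#'   \item{1}{test-retest correlation: Cronbach alpha 0.1-0.9 by 0.1,
#'     total N in \{30, 50\}, k in \{5, 10\}; empirical column is the mean
#'     Pearson correlation of test and retest scale scores.}
#'   \item{2}{pre-post power: (total N = 30, Delta = 0.4) and
#'     (N = 50, Delta = 0.3), alpha 0.5-0.9, k in \{5, 10\}.}
#'   \item{3}{between-group within-group power: (N per group = 30,
#'     Delta = 0.4) and (N = 50, Delta = 0.3), alpha 0.5-0.9,
#'     k in \{5, 10\}.}
#'   \item{4}{two-sample power: (N per group = 50, Delta = 0.7) and
#'     (N = 100, Delta = 0.5), alpha 0.5-0.9, k in \{5, 10\}.}
#' }
#' Per-cell seeds are spawned once from `seed`, so the whole table is
#' deterministic given `seed` and any cell can be re-run in isolation.
#'
#' @param table_id 1, 2, 3 or 4.
#' @param nreps Monte Carlo replicates per cell (default 1000).
#' @param seed integer root seed.
#' @return a data frame with columns `design`, `n`, `k`, `delta`,
#'   `c_alpha`, `rho`, `theoretical`, `empirical`, `mc_se`, `n_reps`,
#'   `seed` (the per-cell seed). For `table_id = 1` the theoretical
#'   column is the population alpha and `empirical` the mean correlation.
#' @examples
#' reproduce_table(2, nreps = 50, seed = 1)
#' @export
reproduce_table <- function(table_id, nreps = 1000, seed = 1L) {
  if (!table_id %in% 1:4) stop("'table_id' must be 1, 2, 3 or 4",
                               call. = FALSE)
  grid <- table_grid(table_id)
  cell_seeds <- replicate_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    d <- cron_design(g$design, n = g$n, delta = g$delta, k = g$k,
                     c_alpha = g$c_alpha)
    if (g$design == "alpha") {
      r <- empirical_testretest(d, nreps = nreps, seed = cell_seeds[i])
      theo <- r$c_alpha
      emp <- r$mean_corr
      se <- stats::sd(r$corrs) / sqrt(nreps)
    } else {
      r <- empirical_power(d, nreps = nreps, seed = cell_seeds[i])
      theo <- r$theoretical
      emp <- r$p_hat
      se <- r$mc_se
    }
    data.frame(design = g$design, n = g$n, k = g$k, delta = g$delta,
               c_alpha = g$c_alpha,
               rho = rho_from_alpha(g$c_alpha, g$k),
               theoretical = theo, empirical = emp, mc_se = se,
               n_reps = nreps, seed = cell_seeds[i])
  })
  do.call(rbind, rows)
}

table_grid <- function(table_id) {
  if (table_id == 1) {
    g <- expand.grid(c_alpha = seq(0.1, 0.9, by = 0.1),
                     n = c(30L, 50L), k = c(5L, 10L))
    g$delta <- 0
    g$design <- "alpha"
    return(g)
  }
  blocks <- switch(as.character(table_id),
    "2" = list(c(30, 0.4), c(50, 0.3)),
    "3" = list(c(30, 0.4), c(50, 0.3)),
    "4" = list(c(50, 0.7), c(100, 0.5)))
  design <- c("2" = "prepost", "3" = "betweenwithin",
              "4" = "twosample")[[as.character(table_id)]]
  g <- do.call(rbind, lapply(blocks, function(b) {
    expand.grid(c_alpha = seq(0.5, 0.9, by = 0.1), k = c(5L, 10L),
                n = as.integer(b[1]), delta = b[2])
  }))
  g$design <- design
  g
}

#' Cronbach alpha as a function of the inter-item correlation
#'
#' Draws the [alpha_from_rho()] curves for several item counts on one
#' panel: alpha rises steeply with `rho` for many items, and reduces to
#' the identity line at `k = 1`. Purely illustrative.
#'
#' @param k item counts, one curve each.
#' @param rho grid of inter-item correlations.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of alpha values (rho in rows, k in
#'   columns).
#' @export
plot_alpha_curves <- function(k = c(1, 2, 5, 10, 20),
                              rho = seq(0.01, 0.99, by = 0.01), ...) {
  if (!length(k) || !length(rho)) stop("'k' and 'rho' must be non-empty",
                                       call. = FALSE)
  a <- sapply(k, function(kk) alpha_from_rho(rho, kk))
  graphics::matplot(rho, a, type = "l", lty = 1, col = seq_along(k),
                    xlab = "inter-item correlation rho",
                    ylab = "Cronbach alpha", ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = paste("k =", k),
                   col = seq_along(k), lty = 1, bty = "n")
  invisible(a)
}
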