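test_that("alpha/rho conversions match hand-evaluated values and edge cases", {
  expect_equal(alpha_from_rho(0, 5), 0)
  expect_equal(alpha_from_rho(1, 5), 1)
  expect_equal(alpha_from_rho(0.5, 1), 0.5)
  expect_equal(alpha_from_rho(0.5, 5), 5 * 0.5 / (1 + 0.5 * 4))
  expect_equal(rho_from_alpha(0.9, 10), 0.9 / (10 - 0.9 * 9))
  expect_equal(rho_from_alpha(0.7, 1), 0.7)
  expect_error(alpha_from_rho(1.2, 5), "rho")
  expect_error(alpha_from_rho(0.5, 0), "k")
  expect_error(rho_from_alpha(-0.1, 5), "c_alpha")
})

test_that("alpha_from_rho and rho_from_alpha are exact inverses on a grid", {
  for (k in c(1:10, 20, 50)) {
    rho <- seq(0.01, 0.99, by = 0.01)
    expect_equal(rho_from_alpha(alpha_from_rho(rho, k), k), rho,
                 tolerance = 1e-12)
  }
})

test_that("alpha is strictly increasing in rho and in k", {
  rho <- seq(0.05, 0.95, by = 0.05)
  for (k in 2:10) {
    expect_true(all(diff(alpha_from_rho(rho, k)) > 0))
  }
  for (r in rho) {
    expect_true(all(diff(sapply(1:20, alpha_from_rho, rho = r)) > 0))
  }
})

test_that("variance decomposition obeys sigma2 = sigma_mu2 + sigma_e2", {
  vd <- variance_decomposition(parallel_items(5, rho = 0.5))
  expect_equal(vd$sigma_e2, 1)
  expect_equal(vd$sigma2, 2)
  vd <- variance_decomposition(parallel_items(3, rho = 1, sigma_mu2 = 3))
  expect_equal(vd$sigma_e2, 0)
  expect_equal(vd$sigma2, 3)
  vd <- variance_decomposition(parallel_items(4, rho = 0.25))
  expect_equal(vd$sigma_e2, 3)
  expect_equal(vd$sigma2, 4)
  expect_error(parallel_items(5, rho = 0), "rho")
})

test_that("the two Var(S) parameterizations agree and decrease in rho", {
  grid <- expand.grid(k = c(1, 2, 5, 10), rho = seq(0.1, 0.9, by = 0.1),
                      s2 = c(0.5, 1, 4))
  for (i in seq_len(nrow(grid))) {
    m <- parallel_items(grid$k[i], rho = grid$rho[i], sigma_mu2 = grid$s2[i])
    sigma2 <- variance_decomposition(m)$sigma2
    v_total <- m$k * sigma2 * (1 + m$rho * (m$k - 1))
    v_alpha <- m$k^2 * m$sigma_mu2 / cronbach_alpha_pop(m)
    expect_equal(scale_score_variance(m), v_total, tolerance = 1e-12)
    expect_equal(scale_score_variance(m), v_alpha, tolerance = 1e-12)
  }
  expect_equal(scale_score_variance(parallel_items(1, rho = 0.5)), 2)
  expect_equal(scale_score_variance(parallel_items(5, rho = 0.5)), 30)
  expect_lt(scale_score_variance(parallel_items(5, rho = 0.9)),
            scale_score_variance(parallel_items(5, rho = 0.5)))
})

test_that("at k = 1 rho, alpha, reliability and test-retest all coincide", {
  for (r in c(0.2, 0.5, 0.7, 0.95)) {
    m <- parallel_items(1, rho = r)
    expect_equal(alpha_from_rho(r, 1), r)
    expect_equal(cronbach_alpha_pop(m), r)
    expect_equal(testretest_correlation(m), r)
  }
})

test_that("test-retest correlation equals the population alpha", {
  expect_equal(testretest_correlation(parallel_items(5, rho = 0.5)),
               alpha_from_rho(0.5, 5))
  expect_equal(testretest_correlation(parallel_items(1, rho = 0.7)), 0.7)
})

test_that("sample Cronbach alpha handles forced and degenerate structure", {
  set.seed(11)
  base <- rnorm(40)
  dup <- cbind(base, base, base)
  expect_equal(cronbach_alpha(dup), 1)
  indep <- matrix(rnorm(4000 * 4), 4000, 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.1)
  neg <- cbind(base, -base + rnorm(40, sd = 0.1))
  expect_lt(cronbach_alpha(neg), 0)   # passed through, not clamped
  expect_error(cronbach_alpha(matrix(rnorm(10), 10, 1)), "2 items")
  expect_error(cronbach_alpha(matrix(rnorm(4), 1, 4)), "2 subjects")
})

test_that("sample alpha is consistent for simulated compound symmetry", {
  y <- simulate_scores(1e5, std_model(), seed = 101)
  expect_equal(cronbach_alpha(y), alpha_from_rho(0.5, 5), tolerance = 0.01)
})

test_that("score matrices round-trip through wide and long text formats", {
  y <- simulate_scores(12, std_model(k = 3), seed = 5)
  attr(y, "true_scores") <- NULL
  wide <- tempfile(fileext = ".csv")
  write_scores(y, wide)
  expect_equal(unname(read_scores(wide)), unname(y), tolerance = 1e-12)

  long <- tempfile(fileext = ".csv")
  df <- data.frame(subject = rep(seq_len(nrow(y)), ncol(y)),
                   item = rep(colnames(y), each = nrow(y)),
                   score = as.vector(y))
  write.csv(df, long, row.names = FALSE)
  expect_equal(unname(read_scores(long, format = "long")), unname(y),
               tolerance = 1e-12)
})
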