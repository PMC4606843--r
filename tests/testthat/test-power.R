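test_that("z_pair matches normal quantile sums and is antisymmetric", {
  expect_equal(z_pair(0.05, 0.5), qnorm(0.975))
  expect_equal(z_pair(0.05, 0.8), qnorm(0.975) + qnorm(0.8))
  for (p in c(0.1, 0.3, 0.6, 0.9)) {
    expect_equal(z_pair(0.05, p) + z_pair(0.05, 1 - p), 2 * qnorm(0.975),
                 tolerance = 1e-12)
  }
  expect_error(z_pair(0, 0.8), "sig.level")
  expect_error(z_pair(0.05, 1), "power")
})

test_that("Fisher-z power for alpha matches a Monte Carlo of the test", {
  # independent oracle: simulate the Fisher-z test of a Pearson correlation
  # on bivariate normal samples with true correlation 0.5, N = 30
  set.seed(202)
  nrep <- 4000
  n <- 30
  r <- 0.5
  rej <- replicate(nrep, {
    z1 <- rnorm(n); z2 <- rnorm(n)
    x <- z1
    y <- r * z1 + sqrt(1 - r^2) * z2
    abs(atanh(cor(x, y))) * sqrt(n - 3) > qnorm(0.975)
  })
  expect_equal(power_alpha_test(0.5, 30), mean(rej), tolerance = 0.03)
  # frozen direct evaluation of the same closed form
  expect_equal(power_alpha_test(0.5, 30), 0.8261626, tolerance = 1e-6)
})

test_that("alpha-test power has the right limits and monotonicity", {
  expect_equal(power_alpha_test(1e-12, 50), 0.025, tolerance = 1e-6)
  grid <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(sapply(grid, power_alpha_test, n = 30)) > 0))
  expect_true(all(diff(sapply(c(10, 30, 100, 300),
                              function(n) power_alpha_test(0.5, n))) > 0))
  expect_error(power_alpha_test(1, 30), "c_alpha")
  expect_error(power_alpha_test(0.5, 3), "n")
})

test_that("zero effect size leaves exactly the one-tail rejection mass", {
  for (a in c(0.01, 0.05, 0.2)) {
    expect_equal(power_prepost(0, 0.7, 40, sig.level = a), a / 2)
    expect_equal(power_between_within(0, 0.7, 40, sig.level = a), a / 2)
    expect_equal(power_two_sample(0, 0.7, 40, sig.level = a), a / 2)
  }
})

test_that("exact two-sided option restores the full size at zero effect", {
  expect_equal(power_prepost(0, 0.5, 30, exact_two_sided = TRUE), 0.05)
  expect_equal(power_two_sample(0, 0.5, 30, exact_two_sided = TRUE), 0.05)
  # away from zero the extra tail is negligible but non-negative
  expect_gte(power_prepost(0.4, 0.5, 30, exact_two_sided = TRUE),
             power_prepost(0.4, 0.5, 30))
})

test_that("power functions are strictly increasing in alpha, n and effect", {
  ca <- seq(0.1, 0.9, by = 0.1)
  ns <- c(10, 20, 50, 100)
  ds <- c(0.1, 0.3, 0.5, 0.8)
  for (f in list(power_prepost, power_between_within, power_two_sample)) {
    expect_true(all(diff(sapply(ca, function(c) f(0.4, c, 30))) > 0))
    expect_true(all(diff(sapply(ns, function(n) f(0.4, 0.5, n))) > 0))
    expect_true(all(diff(sapply(ds, function(d) f(d, 0.5, 30))) > 0))
  }
})

test_that("domain edges of the power functions error as documented", {
  expect_error(power_prepost(0.4, 1, 30), "c_alpha")
  expect_error(power_prepost(0.4, 0, 30), "c_alpha")
  expect_error(power_between_within(0.4, 1, 30), "c_alpha")
  expect_error(power_two_sample(0.4, 0, 30), "c_alpha")
  expect_silent(power_two_sample(0.4, 1, 30))  # error-free instrument OK
})

test_that("sample-size formulas match hand evaluation and invert power", {
  ss <- samplesize_prepost(0.4, 0.5, power = 0.8)
  expect_equal(ss$n, 2 * 1 * z_pair(0.05, 0.8)^2 / 0.16, tolerance = 1e-10)
  expect_equal(ss$n, 98.111, tolerance = 1e-4)
  expect_equal(ss$n_ceiling, 99)

  bw <- samplesize_between_within(0.4, 0.5, power = 0.8)
  expect_equal(bw$n, 2 * ss$n, tolerance = 1e-12)
  expect_equal(bw$n_ceiling, 197)

  ts <- samplesize_two_sample(0.7, 0.5, power = 0.8)
  expect_equal(ts$n, 2 * z_pair(0.05, 0.8)^2 / (0.5 * 0.49),
               tolerance = 1e-10)
  expect_equal(ts$n, 64.0725, tolerance = 1e-4)
  expect_equal(ts$n_ceiling, 65)

  # at alpha = 1 the two-sample formula is the classical normal one
  expect_equal(samplesize_two_sample(0.7, 1, power = 0.8)$n,
               2 * z_pair(0.05, 0.8)^2 / 0.49, tolerance = 1e-12)
  expect_error(samplesize_prepost(0, 0.5), "delta")
})

test_that("sample-size / power duality holds to 1e-10 on a grid", {
  grid <- expand.grid(delta = c(0.2, 0.4, 0.7), c_alpha = c(0.3, 0.6, 0.9),
                      power = c(0.5, 0.8, 0.95))
  for (i in seq_len(nrow(grid))) {
    d <- grid$delta[i]; c <- grid$c_alpha[i]; p <- grid$power[i]
    expect_equal(power_prepost(d, c, samplesize_prepost(d, c, power = p)$n),
                 p, tolerance = 1e-10)
    expect_equal(
      power_between_within(d, c,
                           samplesize_between_within(d, c, power = p)$n),
      p, tolerance = 1e-10)
    expect_equal(
      power_two_sample(d, c, samplesize_two_sample(d, c, power = p)$n),
      p, tolerance = 1e-10)
  }
})

test_that("sample size decreases in alpha and in effect size", {
  n_by_ca <- sapply(seq(0.3, 0.9, by = 0.1),
                    function(c) samplesize_prepost(0.4, c, power = 0.8)$n)
  expect_true(all(diff(n_by_ca) < 0))
  n_by_d <- sapply(c(0.2, 0.4, 0.6),
                   function(d) samplesize_prepost(d, 0.5, power = 0.8)$n)
  expect_true(all(diff(n_by_d) < 0))
})

test_that("rho-parameterized power equals the alpha form after conversion", {
  grid <- expand.grid(rho = c(0.1, 0.3, 0.5, 0.8), k = c(1, 2, 5, 10),
                      n = c(20, 50), delta = c(0.3, 0.6))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ca <- alpha_from_rho(g$rho, g$k)
    expect_equal(power_rho("prepost", g$delta, g$rho, g$k, g$n),
                 power_prepost(g$delta, ca, g$n), tolerance = 1e-12)
    expect_equal(power_rho("betweenwithin", g$delta, g$rho, g$k, g$n),
                 power_between_within(g$delta, ca, g$n), tolerance = 1e-12)
    expect_equal(power_rho("twosample", g$delta, g$rho, g$k, g$n),
                 power_two_sample(g$delta, ca, g$n), tolerance = 1e-12)
  }
})

test_that("power depends on the instrument only through alpha", {
  # (rho, k) pairs with equal alpha give equal power
  ca <- 0.5
  for (k in c(2, 5, 10, 25)) {
    r <- rho_from_alpha(ca, k)
    expect_equal(power_rho("twosample", 0.7, r, k, 50),
                 power_two_sample(0.7, ca, 50), tolerance = 1e-12)
    expect_equal(power_rho("prepost", 0.4, r, k, 30),
                 power_prepost(0.4, ca, 30), tolerance = 1e-12)
  }
})

test_that("item-count solutions are consistent with the power functions", {
  pp <- items_required("prepost", rho = 0.5, n = 99, delta = 0.4)
  expect_equal(pp$k, 0.991, tolerance = 1e-3)
  expect_equal(pp$k_ceiling, 1)
  # substituting the continuous k recovers the target power
  expect_equal(power_rho("prepost", 0.4, 0.5, pp$k, 99), 0.8,
               tolerance = 1e-10)

  ts <- items_required("twosample", rho = 0.4, n = 100, delta = 0.7)
  expect_equal(power_rho("twosample", 0.7, 0.4, ts$k, 100), 0.8,
               tolerance = 1e-10)
  expect_error(items_required("twosample", rho = 0.4, n = 30, delta = 0.5),
               "infeasible")

  bw <- items_required("betweenwithin", rho = 0.5, n = 100, delta = 0.4)
  # default k inverts the interaction power function (factor 4)...
  expect_equal(power_rho("betweenwithin", 0.4, 0.5, bw$k, 100), 0.8,
               tolerance = 1e-10)
  # ...and the factor-2 variant is surfaced, not silently corrected
  expect_equal(bw$k_printed, bw$k / 2, tolerance = 1e-12)
})

test_that("per-group and total sample-size conventions are coherent", {
  # interaction power at per-group N equals paired power at total N with
  # a sqrt(2)-inflated effect: the factor-4 vs factor-2 identity
  for (ca in c(0.4, 0.7)) {
    expect_equal(power_between_within(0.4, ca, 30),
                 power_prepost(0.4 / sqrt(2), ca, 30), tolerance = 1e-12)
  }
})
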