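test_that("degenerate and limiting cases of the Beta-Poisson pmf", {
  # zero effective rate puts all mass at zero
  expect_equal(dbetapois(0, lam = 0, kon = 1, koff = 1), 1)
  expect_equal(dbetapois(0:3, lam = 0, kon = 0.2, koff = 7),
               c(1, 0, 0, 0))
  expect_equal(dbetapois_log(0, lam = 0, kon = 1, koff = 1), 0)

  # Beta mass concentrating at p = 1 recovers the plain Poisson
  expect_lt(max(abs(dbetapois(0:20, lam = 5, kon = 1, koff = 1e-8) -
                      dpois(0:20, 5))), 1e-4)

  # small effective mean: Poisson limit in the lowly-expressed regime
  pm <- dbetapois(0:10, lam = 0.5, kon = 50, koff = 0.01)
  expect_lt(max(abs(pm - dpois(0:10, 0.5 * 50 / 50.01))), 1e-3)
})

test_that("pmf matches the high-precision integration oracle", {
  x <- 0:200
  pm <- dbetapois(x, lam = 40, kon = 0.3, koff = 4)
  po <- bp_pmf_oracle(x, 40, 0.3, 4)
  expect_lt(max(abs(pm - po)), 1e-8)
  # log companion agrees with log of the oracle where mass is representable
  # relative agreement where the oracle itself retains relative accuracy
  lp <- dbetapois_log(x, lam = 40, kon = 0.3, koff = 4)
  ok <- po > 1e-6
  expect_lt(max(abs(exp(lp[ok]) - po[ok]) / po[ok]), 1e-6)
})

test_that("log-pmf is finite and exp-consistent in extreme regimes", {
  lp <- dbetapois_log(3, lam = 5000, kon = 0.1, koff = 100)
  expect_true(is.finite(lp))
  # exp(logpmf) equals pmf to tight relative error
  x <- 0:60
  pm <- dbetapois(x, 12, 0.7, 3)
  lp <- dbetapois_log(x, 12, 0.7, 3)
  keep <- pm > 1e-300
  expect_lt(max(abs(exp(lp[keep]) - pm[keep]) / pm[keep]), 1e-12)
  expect_false(any(is.nan(dbetapois_log(0:50, 2000, 0.01, 0.01))))
})

test_that("invalid parameters are rejected", {
  expect_error(dbetapois(0, lam = -1, kon = 1, koff = 1), "invalid")
  expect_error(dbetapois(0, lam = 1, kon = 0, koff = 1), "invalid")
  expect_error(dbetapois(0, lam = 1, kon = 1, koff = Inf), "invalid")
  expect_error(dbetapois(-1, lam = 1, kon = 1, koff = 1), "non-negative")
})

test_that("negative-binomial limit of the bursty regime", {
  # geometric case
  expect_equal(dnb_limit(0, burst_frequency = 1, burst_size = 5), 1 / 6)
  # zero burst size collapses to a point mass at zero
  expect_equal(dnb_limit(0:3, burst_frequency = 2, burst_size = 0),
               c(1, 0, 0, 0))
  # bursty limit: koff large at fixed ksyn/koff approaches the NB law
  x <- 0:200
  tv <- 0.5 * sum(abs(dnb_limit(x, 1, 5) -
                        dbetapois(x, lam = 5000, kon = 1, koff = 1000)))
  expect_lt(tv, 0.01)
})

test_that("pmf normalizes over its effective support", {
  set.seed(11)
  for (i in 1:8) {
    lam <- 10^runif(1, 0, 3)
    kon <- 10^runif(1, -2, 2)
    koff <- 10^runif(1, -2, 2)
    cap <- burstkin:::bp_support_cap(lam, kon, koff)
    expect_gte(sum(dbetapois(0:cap, lam, kon, koff)), 1 - 1e-8)
  }
})

test_that("binomial thinning equals rate scaling (observation model identity)", {
  grid <- list(c(20, 0.5, 2), c(60, 2, 0.5), c(10, 0.2, 0.2), c(100, 5, 20))
  for (g in grid) {
    lam <- g[1]; kon <- g[2]; koff <- g[3]
    for (beta in c(0.06, 0.5)) {
      cap <- burstkin:::bp_support_cap(lam, kon, koff)
      pmf_full <- dbetapois(0:cap, lam, kon, koff)
      thinned <- thin_pmf(pmf_full, beta, 0:50)
      direct <- dbetapois(0:50, beta * lam, kon, koff)
      expect_lt(max(abs(thinned - direct)), 1e-8)
    }
  }
})

test_that("two-allele distribution: convolution structure and moments", {
  # zero rate: point mass at zero
  expect_equal(dbetapois2(0:2, lam = 0, kon = 1, koff = 1), c(1, 0, 0))

  # mean of the two-allele law is twice the single-allele first moment
  lam <- 30; kon <- 0.6; koff <- 2.5
  x <- 0:burstkin:::bp_support_cap(2 * lam, kon, koff)
  p2 <- dbetapois2(x, lam, kon, koff)
  expect_equal(sum(p2), 1, tolerance = 1e-8)
  f1 <- bp_factorial_moments(lam, kon, koff, order = 1)
  expect_equal(sum(x * p2), 2 * f1, tolerance = 1e-6)

  # Monte-Carlo frequencies of sums of two independent draws (3-sigma bands)
  set.seed(21)
  n <- 1e6
  draw1 <- rpois(n, lam * rbeta(n, kon, koff))
  draw2 <- rpois(n, lam * rbeta(n, kon, koff))
  s <- draw1 + draw2
  for (xx in c(0, 1, 2, 5, 10, 25)) {
    phat <- mean(s == xx)
    pth <- dbetapois2(xx, lam, kon, koff)
    se <- sqrt(pth * (1 - pth) / n)
    expect_lt(abs(phat - pth), 3 * se + 1e-12)
  }

  # cross-route: convolution pmf agrees with the tensorized quadrature used
  # by the nonallele likelihood
  ll_conv <- sum(dbetapois2(c(0, 3, 7), lam, kon, koff, log = TRUE))
  ll_pair <- gene_loglik(c(0, 3, 7), rep(1, 3), ksyn = lam, kon = kon,
                         koff = koff, mode = "nonallele")
  expect_equal(ll_pair, ll_conv, tolerance = 1e-6)
})

test_that("closed-form factorial moments match limits, simulation and convexity", {
  # Beta mean -> 1 when kon >> koff
  f <- bp_factorial_moments(7, kon = 1e8, koff = 1, lam_scale = 2, order = 1)
  expect_equal(f, 14, tolerance = 1e-6)

  # sampling oracle at (ksyn = 50, kon = 0.5, koff = 2)
  set.seed(31)
  n <- 1e7
  xs <- rpois(n, 50 * rbeta(n, 0.5, 2))
  emp <- c(mean(xs), mean(xs * (xs - 1)), mean(xs * (xs - 1) * (xs - 2)))
  thr <- bp_factorial_moments(50, 0.5, 2)
  expect_equal(emp / thr, rep(1, 3), tolerance = 0.02)

  # positivity and log-convexity across a random parameter grid
  set.seed(32)
  for (i in 1:20) {
    th <- c(10^runif(1, 0, 3), 10^runif(1, -2, 2), 10^runif(1, -2, 2))
    f <- bp_factorial_moments(th[1], th[2], th[3])
    expect_true(all(f > 0))
    expect_gte(f[2] * 1, f[1]^2)          # f2 * f0 >= f1^2
    expect_gte(f[3] * f[1], f[2]^2)       # ratio sequence increasing
  }
})
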