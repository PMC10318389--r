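test_that("empirical factorial moments: correction algebra and oracle", {
  # constant beta: corrected = bare / beta^r exactly
  x <- c(0L, 3L, 1L, 7L, 2L, rep(1L, 30))
  b <- rep(0.2, length(x))
  fc <- empirical_factorial_moments(x, b, corrected = TRUE, min_cells = 10)
  fb <- empirical_factorial_moments(x, b, corrected = FALSE, min_cells = 10)
  expect_equal(unname(fc), unname(fb / 0.2^(1:3)))

  # all-zero gene
  expect_equal(unname(empirical_factorial_moments(rep(0L, 40), rep(0.5, 40))),
               c(0, 0, 0))

  # too few nonmissing cells
  expect_true(all(is.na(empirical_factorial_moments(
    c(1L, rep(NA, 40)), rep(0.5, 41)))))

  # unbiasedness against the closed form at (ksyn=50, kon=0.5, koff=2),
  # observed through variable capture
  set.seed(61)
  n <- 1e6
  beta <- pmin(rlnorm(n, log(0.06) - 0.5 * log(1.25), sqrt(log(1.25))), 1)
  xs <- rpois(n, beta * 50 * rbeta(n, 0.5, 2))
  fhat <- empirical_factorial_moments(xs, beta, corrected = TRUE)
  fth <- bp_factorial_moments(50, 0.5, 2)
  expect_equal(unname(fhat / fth), rep(1, 3), tolerance = 0.05)
})

test_that("moment inversion round-trips and flags inconsistent input", {
  f <- bp_factorial_moments(50, 0.5, 2)
  inv <- invert_moments(f[1], f[2], f[3])
  expect_equal(inv$status, "ok")
  expect_equal(c(inv$ksyn, inv$kon, inv$koff), c(50, 0.5, 2),
               tolerance = 1e-8)

  # Poisson-consistent moments admit no finite koff
  expect_equal(invert_moments(3, 9, 27)$status, "degenerate")
  expect_equal(invert_moments(0, 1, 1)$status, "degenerate")
  expect_equal(invert_moments(NaN, 1, 1)$status, "degenerate")

  # round-trip sweep across the prior box
  set.seed(62)
  for (i in 1:200) {
    th <- c(10^runif(1, 0, 3.7), 10^runif(1, -2, 2), 10^runif(1, -2, 2))
    f <- bp_factorial_moments(th[1], th[2], th[3])
    inv <- invert_moments(f[1], f[2], f[3])
    expect_equal(inv$status, "ok")
    expect_equal(c(inv$ksyn, inv$kon, inv$koff), th, tolerance = 1e-8)
  }
})

test_that("two-allele moment deconvolution inverts the convolution identities", {
  expect_equal(unname(deconvolve_two_allele_moments(6, 0, 0)[1]), 3)
  expect_equal(unname(deconvolve_two_allele_moments(0, 0, 0)), c(0, 0, 0))

  # identities verified against an enumeration oracle: factorial moments of
  # the convolved pmf equal the stated transforms of the single-allele ones
  lam <- 25; kon <- 0.7; koff <- 1.8
  cap <- burstkin:::bp_support_cap(2 * lam, kon, koff)
  x <- 0:cap
  p2 <- dbetapois2(x, lam, kon, koff)
  F1 <- sum(x * p2); F2 <- sum(x * (x - 1) * p2)
  F3 <- sum(x * (x - 1) * (x - 2) * p2)
  f <- bp_factorial_moments(lam, kon, koff)
  expect_equal(F1, 2 * f[1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(F2, 2 * f[2] + 2 * f[1]^2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(F3, 2 * f[3] + 6 * f[1] * f[2], tolerance = 1e-8,
               ignore_attr = TRUE)
  back <- deconvolve_two_allele_moments(F1, F2, F3)
  expect_equal(unname(back), unname(f), tolerance = 1e-7)

  # sampled nonallele data recover single-allele parameters through the
  # deconvolution + inversion path
  set.seed(63)
  n <- 1e6
  s <- rpois(n, lam * rbeta(n, kon, koff)) + rpois(n, lam * rbeta(n, kon, koff))
  Fh <- empirical_factorial_moments(s, rep(1, n), corrected = FALSE)
  fh <- deconvolve_two_allele_moments(Fh[1], Fh[2], Fh[3])
  inv <- invert_moments(fh[1], fh[2], fh[3])
  expect_equal(inv$status, "ok")
  expect_equal(log10(c(inv$ksyn, inv$kon, inv$koff)),
               log10(c(lam, kon, koff)), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("moment inference: determinism, bare/corrected identities, scaling", {
  pr <- prior_spec()
  ds <- simulate_dataset(pr, 12, 400, seed = 64)

  e1 <- infer_moments(ds, n_boot = 50, seed = 65)
  e2 <- infer_moments(ds, n_boot = 50, seed = 65)
  expect_identical(e1, e2)

  # on beta = 1 data the bare and corrected estimators coincide exactly
  ones <- rep(1, 200)
  ds1 <- simulate_dataset(prior_spec(beta_mean = 1, beta_cv = 0), 8, 200,
                          seed = 66)
  eb <- infer_moments(ds1$counts, ones, corrected = FALSE, n_boot = 0)
  ec <- infer_moments(ds1$counts, ones, corrected = TRUE, n_boot = 0)
  expect_equal(eb$ksyn, ec$ksyn)
  expect_equal(eb$koff, ec$koff)

  # identifiability is of beta_eff * ksyn only: rescaling beta_eff by c
  # rescales ksyn estimates by 1/c and leaves kon, koff unchanged
  be <- ds$cells$beta_eff
  ea <- infer_moments(ds$counts, be, n_boot = 0)
  eh <- infer_moments(ds$counts, be / 2, n_boot = 0)
  ok <- ea$status == "ok" & eh$status == "ok"
  expect_true(any(ok))
  expect_equal(eh$ksyn[ok], 2 * ea$ksyn[ok], tolerance = 1e-6)
  expect_equal(eh$kon[ok], ea$kon[ok], tolerance = 1e-6)
  expect_equal(eh$koff[ok], ea$koff[ok], tolerance = 1e-6)

  # interval columns bracket the point estimate for ok genes with intervals
  ok2 <- e1$status == "ok" & is.finite(e1$ksyn_lo)
  if (any(ok2)) {
    expect_true(all(e1$ksyn_lo[ok2] <= e1$ksyn_hi[ok2]))
  }
})
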