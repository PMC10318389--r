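test_that("prior sampling is log-uniform, seeded and range-respecting", {
  pr0 <- prior_spec(ksyn_log10 = c(2, 2), kon_log10 = c(0, 0),
                    koff_log10 = c(1, 1))
  kp <- sample_kinetics(pr0, 5, seed = 1)
  expect_equal(kp$ksyn, rep(100, 5))
  expect_equal(kp$burst_size, rep(10, 5))

  pr <- prior_spec()
  a <- sample_kinetics(pr, 100, seed = 2)
  b <- sample_kinetics(pr, 100, seed = 2)
  expect_identical(a, b)

  big <- sample_kinetics(pr, 1e5, seed = 3)
  for (col in c("ksyn", "kon", "koff")) {
    r <- pr[[paste0(col, "_log10")]]
    u <- (log10(big[[col]]) - r[1]) / (r[2] - r[1])
    expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.001)
  }
})

test_that("capture sampling hits the requested mean and stays in (0, 1]", {
  pr0 <- prior_spec(beta_cv = 0)
  expect_equal(sample_capture(pr0, 10, seed = 4)$beta, rep(0.06, 10))

  pr <- prior_spec(beta_mean = 0.06, beta_cv = 0.5)
  cc <- sample_capture(pr, 1e5, seed = 5)
  se <- sd(cc$beta) / sqrt(1e5)
  expect_lt(abs(mean(cc$beta) - 0.06), 3 * se)
  expect_true(all(cc$beta > 0 & cc$beta <= 1))
})

test_that("single-gene simulation obeys the observation model", {
  params <- kinetic_params(50, 0.8, 2)

  # zero capture: nothing observed
  cells0 <- make_cells(beta = rep(0, 50))
  expect_true(all(simulate_gene(params[1, ], cells0, seed = 6)$observed == 0))

  # full capture: empirical distribution matches the analytic pmf (chi-square)
  cells1 <- make_cells(beta = rep(1, 1e5))
  x <- simulate_gene(params[1, ], cells1, seed = 7, path = "direct")$observed
  cap <- burstkin:::bp_support_cap(50, 0.8, 2)
  pth <- dbetapois(0:cap, 50, 0.8, 2)
  # pooled bins: exact counts 0..14, tail lumped
  pb <- c(pth[1:15], 1 - sum(pth[1:15]))
  chi <- chisq.test(as.numeric(table(factor(pmin(x, 15), levels = 0:15))),
                    p = pb)
  expect_gt(chi$p.value, 0.001)

  # explicit thinning path and direct Beta-Poisson path agree in distribution
  cellsb <- make_cells(beta = rep(0.3, 1e5))
  xe <- simulate_gene(params[1, ], cellsb, seed = 8, path = "explicit")
  xd <- simulate_gene(params[1, ], cellsb, seed = 9, path = "direct")
  expect_gt(suppressWarnings(ks.test(xe$observed, xd$observed))$p.value, 0.001)
  # observed never exceeds original on the explicit path
  expect_true(all(xe$observed <= xe$original))

  # nonallele mean is twice the allele mean
  xa <- simulate_gene(params[1, ], cellsb, mode = "allele", seed = 10,
                      path = "direct")$observed
  xn <- simulate_gene(params[1, ], cellsb, mode = "nonallele", seed = 11,
                      path = "direct")$observed
  expect_equal(mean(xn) / mean(xa), 2, tolerance = 0.03)
})

test_that("missing masks are applied at the requested per-gene rates", {
  set.seed(12)
  m <- matrix(rpois(5000, 3), nrow = 5)
  expect_identical(sum(is.na(apply_missing_mask(m, 0, seed = 1))), 0L)
  full <- apply_missing_mask(m, c(1, 0, 0, 0, 0), seed = 2)
  expect_true(all(is.na(full[1, ])))
  expect_true(all(!is.na(full[2:5, ])))

  frac <- 0.3
  masked <- apply_missing_mask(m, frac, seed = 3)
  realized <- rowMeans(is.na(masked))
  sig <- sqrt(frac * (1 - frac) / ncol(m))
  expect_true(all(abs(realized - frac) < 3 * sig))

  # fully missing gene propagates to a failed inference status
  est <- infer_moments(full, rep(0.06, ncol(full)), n_boot = 0)
  expect_equal(est$status[1], "failed")
})

test_that("dataset and benchmark construction are reproducible", {
  pr <- prior_spec()
  d1 <- simulate_dataset(pr, 10, 50, seed = 13)
  d2 <- simulate_dataset(pr, 10, 50, seed = 13)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
  expect_equal(dim(d1$counts), c(10L, 50L))
  expect_equal(nrow(d1$truth), 10L)

  bm <- build_benchmark(pr, n_cells = c(50, 100), n_genes = 5, n_reps = 2,
                        seed = 14)
  expect_equal(nrow(bm), 4L)
  expect_equal(sum(vapply(bm$data, function(d) nrow(d$truth), numeric(1))), 20)
  bm2 <- build_benchmark(pr, n_cells = c(50, 100), n_genes = 5, n_reps = 2,
                         seed = 14)
  expect_identical(lapply(bm$data, `[[`, "counts"),
                   lapply(bm2$data, `[[`, "counts"))
})

test_that("zero fraction follows the analytic dropout curve", {
  pr <- prior_spec()
  set.seed(15)
  cells <- make_cells(beta = rep(0.06, 2e4))
  for (th in list(c(200, 0.5, 1), c(1000, 2, 5))) {
    params <- kinetic_params(th[1], th[2], th[3])
    x <- simulate_gene(params[1, ], cells, path = "direct")$observed
    p0 <- dbetapois(0, 0.06 * th[1], th[2], th[3])
    se <- sqrt(p0 * (1 - p0) / length(x))
    expect_lt(abs(mean(x == 0) - p0), 4 * se + 1e-4)
  }
})
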