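test_that("AIC arithmetic and Akaike weights", {
  expect_equal(aic(-100, 3), 206)
  expect_equal(aic(0, 0), 0)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102, 110))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # invariant to a constant shift of all log-likelihoods
  expect_equal(akaike_weights(aic(c(-5, -7, -9), 1)),
               akaike_weights(aic(c(-5, -7, -9) + 100, 1)))
})

test_that("capture-scaled Poisson log-likelihood", {
  # single cell with beta = 1: mu = x, loglik = log Poisson(x; x)
  r <- poisson_loglik(4L, 1)
  expect_equal(r$mu, 4)
  expect_equal(r$loglik, dpois(4, 4, log = TRUE))

  # 5-cell toy row, two-line manual computation
  x <- c(2L, 0L, 3L, 1L, 4L)
  b <- c(0.5, 0.2, 1, 0.8, 0.4)
  mu_hat <- mean(x / b)
  manual <- sum(dpois(x, mu_hat * b, log = TRUE))
  expect_equal(poisson_loglik(x, b)$loglik, manual)

  expect_equal(poisson_loglik(rep(0L, 10), rep(0.5, 10))$loglik, 0)
})

test_that("negative-binomial fit through the capture layer", {
  # underdispersed (constant) data hit the Poisson boundary where the
  # fitted mean is exactly the rescaled sample mean
  x <- rep(3L, 100); b <- rep(0.5, 100)
  nb <- nb_fit_loglik(x, b)
  expect_true(nb$poisson_boundary)
  expect_equal(nb$mu, mean(x / b), tolerance = 1e-6)
  expect_true(is.finite(nb$loglik))

  # self-consistency: NB observed through binomial capture is NB with the
  # same shape and capture-scaled mean; the fit recovers (mu, size)
  set.seed(101)
  n <- 2e4
  X <- rnbinom(n, size = 2, mu = 40)
  xo <- rbinom(n, X, 0.3)
  fit <- nb_fit_loglik(xo, rep(0.3, n))
  expect_equal(fit$mu, 40, tolerance = 0.05 * 40)
  expect_equal(fit$size, 2, tolerance = 0.15 * 2)

  z <- nb_fit_loglik(rep(0L, 50), rep(0.1, 50))
  expect_true(is.finite(z$loglik))
  expect_equal(z$mu, 0)
})

test_that("WAIC from posterior samples reduces correctly and matches two-pass", {
  x <- c(0L, 2L, 5L)
  be <- rep(0.5, 3)
  one <- data.frame(ksyn = 20, kon = 1, koff = 2)
  ll <- gene_loglik(x, be, 20, 1, 2)
  expect_equal(waic_from_samples(x, be, one), -2 * ll, tolerance = 1e-8)
  # repeated identical samples: variance term vanishes
  expect_equal(waic_from_samples(x, be, one[c(1, 1, 1), ]), -2 * ll,
               tolerance = 1e-8)

  # independent two-pass computation on 3 distinct samples
  smp <- data.frame(ksyn = c(20, 30, 15), kon = c(1, 0.8, 1.5),
                    koff = c(2, 2.5, 1))
  lp <- sapply(seq_len(3), function(s)
    dbetapois_log(x, be[1] * smp$ksyn[s], smp$kon[s], smp$koff[s]))
  lppd <- sum(log(rowMeans(exp(lp))))
  p_waic <- sum(apply(lp, 1, var))
  expect_equal(waic_from_samples(x, be, smp), -2 * (lppd - p_waic),
               tolerance = 1e-6)
})

test_that("model assignment table is well-formed and delegates correctly", {
  pr <- prior_spec()
  ds <- simulate_dataset(pr, 30, 200, seed = 102)
  bh <- estimate_beta(ds$counts, 0.06)$beta
  sel <- select_model(ds$counts, ds$truth, beta_eff = bh)
  tab <- tidy(sel)
  expect_equal(nrow(tab), 30)
  expect_equal(unname(rowSums(cbind(tab$weight_bp, tab$weight_nb,
                                    tab$weight_poisson))),
               rep(1, 30), tolerance = 1e-12)
  # assigned label is the argmin of the AICs
  aics <- cbind(tab$aic_bp, tab$aic_nb, tab$aic_poisson)
  expect_equal(tab$assigned,
               c("BP", "NB", "Poisson")[apply(aics, 1, which.min)])
  # the BP likelihood is the capture-aware gene likelihood at the truth
  expect_equal(tab$logL_bp[1],
               bp_loglik_at(ds$truth[1, ], ds$counts[1, ], bh))
  g <- glance(sel)
  expect_equal(g$n_bp + g$n_nb + g$n_poisson, 30L)
})

test_that("high expression makes the Beta-Poisson model identifiable", {
  pr_hi <- prior_spec(ksyn_log10 = c(3, 3.7), kon_log10 = c(-0.5, 0.5),
                      koff_log10 = c(-0.5, 0.5))
  ds <- simulate_dataset(pr_hi, 60, 300, seed = 103)
  bh <- estimate_beta(ds$counts, 0.06)$beta
  sel <- select_model(ds$counts, ds$truth, beta_eff = bh)
  expect_gt(mean(tidy(sel)$assigned == "BP"), 0.5)
})
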