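#' Empirical factorial moments of one gene, optionally capture-corrected
#'
#' Computes the first three sample falling-factorial moments of a gene's
#' counts. Under binomial capture the observed falling factorials satisfy
#' `E[x(x-1)...(x-r+1)] = beta_eff^r * f_r`, so the corrected estimator
#' averages `x(x-1)...(x-r+1) / beta_eff^r` over nonmissing cells and is
#' unbiased for the factorial moments of the original counts. The bare
#' estimator sets `beta_eff = 1` (no correction), as when raw counts are used
#' directly.
#'
#' @param x integer count vector for one gene (`NA` = missing).
#' @param beta_eff per-cell effective capture efficiencies.
#' @param corrected logical; divide by `beta_eff^r`?
#' @param min_cells minimum number of nonmissing cells required.
#' @return numeric `c(f1, f2, f3)`, or `NA`s when too few cells remain.
#' @export
empirical_factorial_moments <- function(x, beta_eff, corrected = TRUE,
                                        min_cells = 30L) {
  stopifnot(length(beta_eff) == length(x))
  ok <- !is.na(x)
  if (sum(ok) < min_cells) return(c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_))
  x <- as.numeric(x[ok])
  b <- if (corrected) beta_eff[ok] else rep(1, sum(ok))
  c(f1 = mean(x / b),
    f2 = mean(x * (x - 1) / b^2),
    f3 = mean(x * (x - 1) * (x - 2) / b^3))
}

#' Invert factorial moments to telegraph-model rates
#'
#' Solves the three moment equations
#' `f_r = ksyn^r * prod_{i<r} (kon + i) / (kon + koff + i)` for
#' `(ksyn, kon, koff)`. The closed-form solution (standard Beta-Poisson moment
#' algebra) is followed by one-two Newton steps in log-parameters to remove
#' floating-point cancellation near the Poisson-like corner. Moment triples
#' inconsistent with an overdispersed Beta-Poisson law (including exactly
#' Poisson data, where no finite `koff` exists) yield a degenerate flag rather
#' than an error.
#'
#' @param f1,f2,f3 factorial moments (positive).
#' @return a list with `ksyn`, `kon`, `koff`, `status`
#'   (`"ok"` or `"degenerate"`).
#' @export
invert_moments <- function(f1, f2, f3) {
  degen <- list(ksyn = NA_real_, kon = NA_real_, koff = NA_real_,
                status = "degenerate")
  if (any(!is.finite(c(f1, f2, f3))) || f1 <= 0 || f2 <= 0 || f3 <= 0)
    return(degen)
  r1 <- f1; r2 <- f2 / f1; r3 <- f3 / f2
  den1 <- r1 * r2 - 2 * r1 * r3 + r2 * r3
  den2 <- r1 - 2 * r2 + r3
  if (den1 == 0 || den2 == 0) return(degen)
  kon <- 2 * r1 * (r3 - r2) / den1
  koff <- 2 * (r3 - r2) * (r1 - r3) * (r2 - r1) / (den1 * den2)
  ksyn <- (-r1 * r2 + 2 * r1 * r3 - r2 * r3) / den2
  if (any(!is.finite(c(ksyn, kon, koff))) || ksyn <= 0 || kon <= 0 || koff <= 0)
    return(degen)
  th <- moment_newton_polish(c(ksyn, kon, koff), log(c(f1, f2, f3)))
  if (any(!is.finite(th)) || any(th <= 0)) return(degen)
  list(ksyn = th[1], kon = th[2], koff = th[3], status = "ok")
}

# Newton refinement of the log-moment equations in log-parameters, with the
# step restricted (truncated SVD) to well-conditioned directions. Near the
# Poisson-like corner (kon >> koff) the Jacobian is nearly rank-deficient and
# an unrestricted step only amplifies floating-point noise in the residual,
# degrading the algebraically exact closed form; truncation leaves those
# directions at their closed-form values.
moment_newton_polish <- function(theta, log_f_target, iter = 3L,
                                 trunc = 1e-4) {
  for (it in seq_len(iter)) {
    k <- theta[1]; a <- theta[2]; b <- theta[3]
    g <- numeric(3); J <- matrix(0, 3, 3)
    for (r in 1:3) {
      i <- 0:(r - 1)
      g[r] <- r * log(k) + sum(log(a + i) - log(a + b + i))
      J[r, 1] <- r
      J[r, 2] <- a * sum(1 / (a + i) - 1 / (a + b + i))
      J[r, 3] <- -b * sum(1 / (a + b + i))
    }
    s <- tryCatch(svd(J), error = function(e) NULL)
    if (is.null(s)) return(theta)
    keep <- s$d > trunc * s$d[1]
    step <- drop(s$v[, keep, drop = FALSE] %*%
                   ((t(s$u[, keep, drop = FALSE]) %*% (log_f_target - g)) /
                      s$d[keep]))
    if (any(!is.finite(step))) return(theta)
    theta <- theta * exp(pmax(pmin(step, 2), -2))
  }
  theta
}

#' Recover single-allele factorial moments from nonallele totals
#'
#' For total counts that are the sum of two independent identically
#' distributed alleles, the factorial moments of the sum `S = A + B` satisfy
#' `F1 = 2 f1`, `F2 = 2 f2 + 2 f1^2`, `F3 = 2 f3 + 6 f1 f2`. This inverts
#' those convolution identities to per-allele moments.
#'
#' @param F1,F2,F3 factorial moments of the total counts.
#' @return numeric `c(f1, f2, f3)` per allele.
#' @export
deconvolve_two_allele_moments <- function(F1, F2, F3) {
  f1 <- F1 / 2
  f2 <- (F2 - 2 * f1^2) / 2
  f3 <- (F3 - 6 * f1 * f2) / 2
  c(f1 = f1, f2 = f2, f3 = f3)
}

#' Method-of-moments inference with bootstrap intervals
#'
#' Per-gene point estimates from moment inversion on the full data, with 95%
#' intervals from cell-resampled (with replacement) re-inversions. The
#' capture-corrected variant (`corrected = TRUE`, "MME") rescales falling
#' factorials by per-cell effective capture efficiencies; the bare variant
#' ("BMME") uses raw counts and therefore estimates capture-confounded rates.
#' Failed bootstrap resamples are dropped and counted.
#'
#' @param counts genes x cells matrix (`NA` = missing) or a `burst_dataset`.
#' @param beta_eff per-cell effective capture efficiencies (ignored for the
#'   bare variant). Defaults to the dataset's cells when a `burst_dataset` is
#'   given.
#' @param mode `"allele"` or `"nonallele"` (totals deconvolved to per-allele
#'   moments before inversion).
#' @param corrected logical; capture-corrected (MME) or bare (BMME)?
#' @param n_boot bootstrap replicates for the intervals (0 = point only).
#' @param min_cells minimum nonmissing cells per gene.
#' @param seed integer seed for the bootstrap.
#' @return a tibble (one row per gene x parameter in wide form): columns
#'   `gene`, `method`, `ksyn`, `kon`, `koff`, `burst_size`, `burst_frequency`,
#'   interval columns `<param>_lo` / `<param>_hi`, `n_boot_failed`, `status`.
#' @export
infer_moments <- function(counts, beta_eff = NULL,
                          mode = c("allele", "nonallele"), corrected = TRUE,
                          n_boot = 200L, min_cells = 30L, seed = NULL) {
  mode <- match.arg(mode)
  inp <- resolve_counts(counts, beta_eff)
  if (!is.null(seed)) set.seed(seed)
  method <- if (corrected) "MME" else "BMME"
  rows <- lapply(seq_len(nrow(inp$counts)), function(g) {
    x <- inp$counts[g, ]
    fit <- moment_fit_one(x, inp$beta_eff, mode, corrected, min_cells)
    ci <- matrix(NA_real_, 2, 3,
                 dimnames = list(c("lo", "hi"), c("ksyn", "kon", "koff")))
    n_failed <- NA_integer_
    if (fit$status == "ok" && n_boot > 0) {
      ok <- which(!is.na(x))
      boot <- matrix(NA_real_, n_boot, 3)
      for (b in seq_len(n_boot)) {
        idx <- sample(ok, length(ok), replace = TRUE)
        bf <- moment_fit_one(x[idx], inp$beta_eff[idx], mode, corrected, min_cells)
        if (bf$status == "ok") boot[b, ] <- c(bf$ksyn, bf$kon, bf$koff)
      }
      n_failed <- sum(is.na(boot[, 1]))
      if (n_boot - n_failed >= 20) {
        ci[] <- apply(boot, 2, stats::quantile,
                      probs = c(0.025, 0.975), na.rm = TRUE)
      }
    }
    tibble::tibble(
      gene = rownames(inp$counts)[g] %||% paste0("gene", g),
      method = method,
      ksyn = fit$ksyn, kon = fit$kon, koff = fit$koff,
      burst_size = fit$ksyn / fit$koff, burst_frequency = fit$kon,
      ksyn_lo = ci[1, 1], ksyn_hi = ci[2, 1],
      kon_lo = ci[1, 2], kon_hi = ci[2, 2],
      koff_lo = ci[1, 3], koff_hi = ci[2, 3],
      n_boot_failed = n_failed,
      status = fit$status
    )
  })
  dplyr::bind_rows(rows)
}

moment_fit_one <- function(x, beta_eff, mode, corrected, min_cells) {
  f <- empirical_factorial_moments(x, beta_eff, corrected = corrected,
                                   min_cells = min_cells)
  if (any(is.na(f)))
    return(list(ksyn = NA_real_, kon = NA_real_, koff = NA_real_,
                status = "failed"))
  if (mode == "nonallele") f <- deconvolve_two_allele_moments(f[1], f[2], f[3])
  invert_moments(f[1], f[2], f[3])
}

# normalize counts/beta_eff input: accepts a burst_dataset or a matrix
resolve_counts <- function(counts, beta_eff = NULL) {
  if (inherits(counts, "burst_dataset")) {
    if (is.null(beta_eff)) beta_eff <- counts$cells$beta_eff
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts))
  if (is.null(beta_eff)) beta_eff <- rep(1, ncol(counts))
  stopifnot(length(beta_eff) == ncol(counts))
  list(counts = counts, beta_eff = as.numeric(beta_eff))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
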