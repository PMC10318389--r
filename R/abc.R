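#' Summary statistics of one gene's counts given its capture context
#'
#' Fixed-length, deterministic summary vector used by both the ABC and the
#' neural-network inference: `log1p` of the three capture-corrected factorial
#' moments, the zero fraction, `log1p` mean and variance, and `log1p`
#' quartiles of the capture-rescaled counts `x / beta_eff`. Computed over
#' nonmissing cells.
#'
#' @param x integer counts for one gene (`NA` = missing).
#' @param beta_eff per-cell effective capture efficiencies.
#' @return named numeric vector of length 9.
#' @export
summarize_gene <- function(x, beta_eff) {
  m <- summarize_matrix(matrix(x, nrow = 1), beta_eff)
  stats::setNames(as.numeric(m[1, ]), colnames(m))
}

# vectorized over rows; NA-safe
summarize_matrix <- function(counts, beta_eff) {
  X <- counts
  storage.mode(X) <- "double"
  B <- matrix(beta_eff, nrow(X), ncol(X), byrow = TRUE)
  B[is.na(X)] <- NA
  f1 <- rowMeans(X / B, na.rm = TRUE)
  f2 <- rowMeans(X * (X - 1) / B^2, na.rm = TRUE)
  f3 <- rowMeans(X * (X - 1) * (X - 2) / B^3, na.rm = TRUE)
  zf <- rowMeans(X == 0, na.rm = TRUE)
  mu <- rowMeans(X, na.rm = TRUE)
  m2 <- rowMeans(X^2, na.rm = TRUE)
  va <- pmax(m2 - mu^2, 0)
  XB <- X / B
  qs <- t(apply(XB, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
                na.rm = TRUE, names = FALSE))
  out <- cbind(log1p(pmax(f1, 0)), log1p(pmax(f2, 0)), log1p(pmax(f3, 0)),
               zf, log1p(mu), log1p(va),
               log1p(qs[, 1]), log1p(qs[, 2]), log1p(qs[, 3]))
  colnames(out) <- c("lf1", "lf2", "lf3", "zero_frac", "lmean", "lvar",
                     "lq25", "lq50", "lq75")
  out
}

#' Rejection-ABC reference table for a fixed cell context
#'
#' Draws kinetic parameters from the prior and simulates each parameter set
#' through the observation model using the *observed* effective capture
#' efficiencies verbatim (the simulations condition on the cells at hand),
#' then summarizes each simulated gene. The table is built once per dataset
#' and shared by all genes.
#'
#' @param prior a [prior_spec()].
#' @param beta_eff observed per-cell effective capture efficiencies.
#' @param n_sims number of prior draws.
#' @param mode `"allele"` or `"nonallele"`.
#' @param seed integer seed.
#' @return a list with `theta` (n_sims x 3), `stats` (n_sims x 9),
#'   `stat_sd` (prior-predictive standard deviations used for distance
#'   standardization).
#' @export
abc_reference <- function(prior, beta_eff, n_sims = 1e5,
                          mode = c("allele", "nonallele"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  truth <- sample_kinetics(prior, n_sims)
  counts <- bp_simulate_matrix(truth, beta_eff,
                               n_alleles = if (mode == "nonallele") 2L else 1L)
  S <- summarize_matrix(counts, beta_eff)
  sdv <- apply(S, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(theta = cbind(ksyn = truth$ksyn, kon = truth$kon, koff = truth$koff),
       stats = S, stat_sd = sdv, mode = mode, prior = prior)
}

#' Rejection-ABC inference of burst kinetics
#'
#' Likelihood-free posterior per gene: the draws whose simulated summaries lie
#' closest (standardized Euclidean distance) to the observed gene's summaries
#' are accepted; the point estimate is the posterior median and the 95%
#' credible interval the (2.5%, 97.5%) posterior quantiles. Accepted samples
#' are returned for reuse (e.g. WAIC).
#'
#' @inheritParams infer_moments
#' @param prior a [prior_spec()].
#' @param n_sims prior draws for the reference table.
#' @param accept_frac fraction of draws accepted; `n_sims * accept_frac` must
#'   be at least 50.
#' @param reference optionally a precomputed [abc_reference()] (then `prior`,
#'   `n_sims` and `seed` are ignored for table construction).
#' @return an object of class `burst_abc`: list with `estimates` (tibble like
#'   [infer_moments()], method `"ABC"`) and `samples` (long tibble `gene`,
#'   `draw`, `ksyn`, `kon`, `koff`).
#' @export
infer_abc <- function(counts, beta_eff = NULL, mode = c("allele", "nonallele"),
                      prior = prior_spec(), n_sims = 1e5, accept_frac = 0.001,
                      seed = NULL, reference = NULL) {
  mode <- match.arg(mode)
  inp <- resolve_counts(counts, beta_eff)
  if (is.null(reference)) {
    stopifnot(n_sims * accept_frac >= 50)
    reference <- abc_reference(prior, inp$beta_eff, n_sims = n_sims,
                               mode = mode, seed = seed)
  }
  n_ref <- nrow(reference$stats)
  n_acc <- max(50L, as.integer(round(n_ref * accept_frac)))
  obs <- summarize_matrix(inp$counts, inp$beta_eff)
  Sz <- sweep(reference$stats, 2, reference$stat_sd, "/")
  Oz <- sweep(obs, 2, reference$stat_sd, "/")
  genes <- rownames(inp$counts) %||% paste0("gene", seq_len(nrow(inp$counts)))
  est <- vector("list", nrow(inp$counts))
  smp <- vector("list", nrow(inp$counts))
  refnorm <- rowSums(Sz^2)
  for (g in seq_len(nrow(inp$counts))) {
    xg <- inp$counts[g, ]
    if (all(is.na(xg)) || all(xg == 0, na.rm = TRUE) || any(!is.finite(Oz[g, ]))) {
      est[[g]] <- abc_row(genes[g], NULL)
      next
    }
    d2 <- refnorm - 2 * drop(Sz %*% Oz[g, ]) + sum(Oz[g, ]^2)
    keep <- order(d2)[seq_len(n_acc)]
    th <- reference$theta[keep, , drop = FALSE]
    est[[g]] <- abc_row(genes[g], th)
    smp[[g]] <- tibble::tibble(gene = genes[g], draw = seq_len(n_acc),
                               ksyn = th[, 1], kon = th[, 2], koff = th[, 3])
  }
  structure(list(estimates = dplyr::bind_rows(est),
                 samples = dplyr::bind_rows(smp),
                 prior = reference$prior %||% prior, mode = mode),
            class = "burst_abc")
}

abc_row <- function(gene, th) {
  if (is.null(th)) {
    return(tibble::tibble(
      gene = gene, method = "ABC", ksyn = NA_real_, kon = NA_real_,
      koff = NA_real_, burst_size = NA_real_, burst_frequency = NA_real_,
      ksyn_lo = NA_real_, ksyn_hi = NA_real_, kon_lo = NA_real_,
      kon_hi = NA_real_, koff_lo = NA_real_, koff_hi = NA_real_,
      status = "failed"))
  }
  q <- apply(th, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  tibble::tibble(
    gene = gene, method = "ABC",
    ksyn = q[2, 1], kon = q[2, 2], koff = q[2, 3],
    burst_size = q[2, 1] / q[2, 3], burst_frequency = q[2, 2],
    ksyn_lo = q[1, 1], ksyn_hi = q[3, 1],
    kon_lo = q[1, 2], kon_hi = q[3, 2],
    koff_lo = q[1, 3], koff_hi = q[3, 3],
    status = "ok")
}

#' @export
print.burst_abc <- function(x, ...) {
  cat(sprintf("Rejection-ABC fit: %d genes, %d accepted draws/gene (%s mode)\n",
              nrow(x$estimates), max(x$samples$draw %||% 0), x$mode))
  invisible(x)
}
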