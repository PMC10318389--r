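#' Benchmark recovery metrics against known truth
#'
#' Compares per-gene estimates to generating truth on log10 scale, per
#' parameter: the coefficient of determination (R2) between estimated and true
#' log10 values, the mean absolute log10 error (MAE), the fraction of truths
#' falling outside the 95% intervals (O95), and the mean interval width in
#' log10 space (FW95). Failed or degenerate genes are excluded from the
#' metrics but counted.
#'
#' @param estimates tibble from one of the `infer_*` functions (or
#'   `burst_abc$estimates`).
#' @param truth [kinetic_params()] table; joined by `gene`.
#' @return a tibble of class `burst_metrics`: columns `method`, `parameter`,
#'   `r2`, `mae`, `o95`, `fw95`, `n_used`, `n_failed`.
#' @export
compute_metrics <- function(estimates, truth) {
  if (inherits(estimates, "burst_abc")) estimates <- estimates$estimates
  joined <- dplyr::inner_join(
    estimates,
    dplyr::rename_with(truth, ~ paste0(.x, "_true"), -"gene"),
    by = "gene")
  out <- lapply(c("ksyn", "kon", "koff"), function(p) {
    est <- joined[[p]]
    tru <- joined[[paste0(p, "_true")]]
    lo <- joined[[paste0(p, "_lo")]]
    hi <- joined[[paste0(p, "_hi")]]
    ok <- joined$status == "ok" & is.finite(est) & est > 0
    n_failed <- sum(!ok)
    e <- log10(est[ok]); t <- log10(tru[ok])
    resid <- e - t
    r2 <- if (length(e) > 1 && stats::var(t) > 0)
      1 - sum(resid^2) / sum((t - mean(t))^2) else NA_real_
    mae <- mean(abs(resid))
    has_ci <- ok & is.finite(lo) & is.finite(hi)
    o95 <- if (any(has_ci))
      mean(tru[has_ci] < lo[has_ci] | tru[has_ci] > hi[has_ci]) else NA_real_
    fw95 <- if (any(has_ci))
      mean(log10(hi[has_ci] / lo[has_ci])) else NA_real_
    tibble::tibble(method = estimates$method[1], parameter = p, r2 = r2,
                   mae = mae, o95 = o95, fw95 = fw95,
                   n_used = sum(ok), n_failed = n_failed)
  })
  structure(dplyr::bind_rows(out), class = c("burst_metrics", "tbl_df",
                                             "tbl", "data.frame"))
}

#' Between-allele correlation induced by shared capture efficiency
#'
#' Simulates, for each gene, two independent allele count rows that share the
#' same per-cell effective capture efficiencies, and returns the Pearson
#' correlation between the alleles across cells. With constant capture the
#' alleles are independent and correlations center on zero; variable capture
#' induces a positive correlation because both alleles are thinned by the same
#' cell-specific factor - the model's explanation for observed inter-allele
#' correlations without invoking coordinated allele activity.
#'
#' @param params_table [kinetic_params()] table of genes to simulate.
#' @param n_cells number of cells per gene.
#' @param prior a [prior_spec()] supplying the capture distribution.
#' @param seed integer seed.
#' @return a tibble with columns `gene`, `correlation`.
#' @export
two_allele_correlation_check <- function(params_table, n_cells = 100,
                                         prior = prior_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- sample_capture(prior, n_cells)
  cors <- vapply(seq_len(nrow(params_table)), function(g) {
    a1 <- simulate_gene(params_table[g, ], cells, mode = "allele",
                        path = "direct")$observed
    a2 <- simulate_gene(params_table[g, ], cells, mode = "allele",
                        path = "direct")$observed
    if (stats::sd(a1) == 0 || stats::sd(a2) == 0) return(NA_real_)
    stats::cor(a1, a2)
  }, numeric(1))
  tibble::tibble(gene = params_table$gene, correlation = cors)
}

#' Dropout rate versus mean expression
#'
#' Per-gene descriptive pair: mean over nonmissing entries and the fraction of
#' (nonmissing) zeros. Under the capture-thinned Beta-Poisson model the zero
#' fraction is a decreasing function of the mean, with no zero inflation
#' needed.
#'
#' @param counts genes x cells matrix (`NA` = missing) or `burst_dataset`.
#' @return a tibble with columns `gene`, `mean_expression`, `dropout`.
#' @export
dropout_vs_mean <- function(counts) {
  if (inherits(counts, "burst_dataset")) counts <- counts$counts
  stopifnot(is.matrix(counts))
  genes <- rownames(counts) %||% paste0("gene", seq_len(nrow(counts)))
  m <- rowMeans(counts, na.rm = TRUE)
  z <- rowMeans(counts == 0, na.rm = TRUE)
  all_na <- apply(counts, 1, function(x) all(is.na(x)))
  m[all_na] <- 0; z[all_na] <- 1
  tibble::tibble(gene = genes, mean_expression = m, dropout = z)
}
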