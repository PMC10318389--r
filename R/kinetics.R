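#' Construct a table of telegraph-model kinetic parameters
#'
#' Bundles per-gene kinetic rates into a validated tibble and derives the two
#' burst descriptors used throughout the package: burst size `ksyn / koff`
#' (mean transcripts per activity burst) and burst frequency `kon` (burst
#' initiations per effective decay time). All rates are relative to the
#' effective mRNA decay rate and therefore dimensionless.
#'
#' @param ksyn synthesis rates (> 0).
#' @param kon activation rates (> 0).
#' @param koff inactivation rates (> 0).
#' @param gene optional gene identifiers (default `gene1, gene2, ...`).
#' @return a tibble with columns `gene`, `ksyn`, `kon`, `koff`, `burst_size`,
#'   `burst_frequency`.
#' @export
kinetic_params <- function(ksyn, kon, koff, gene = NULL) {
  n <- length(ksyn)
  stopifnot(length(kon) == n, length(koff) == n)
  if (any(!is.finite(ksyn) | ksyn <= 0) ||
      any(!is.finite(kon) | kon <= 0) ||
      any(!is.finite(koff) | koff <= 0))
    stop("kinetic rates must be strictly positive and finite", call. = FALSE)
  if (is.null(gene)) gene <- paste0("gene", seq_len(n))
  tibble::tibble(
    gene = as.character(gene),
    ksyn = as.numeric(ksyn),
    kon = as.numeric(kon),
    koff = as.numeric(koff),
    burst_size = ksyn / koff,
    burst_frequency = as.numeric(kon)
  )
}

#' Log-scale prior specification for kinetics and capture efficiency
#'
#' Defines the sampling box for kinetic parameters (independent log10-uniform
#' per rate) and the capture-efficiency distribution (log-normal with a given
#' mean and coefficient of variation, clipped to `(0, 1]`). These defaults span
#' the Poisson-like, intermediate and bursty negative-binomial regimes; the
#' capture mean of 0.06 reflects typical droplet-protocol efficiencies.
#'
#' @param ksyn_log10 numeric length-2, log10 range of the synthesis rate.
#' @param kon_log10 numeric length-2, log10 range of the activation rate.
#' @param koff_log10 numeric length-2, log10 range of the inactivation rate.
#' @param beta_mean mean capture efficiency in `(0, 1]`.
#' @param beta_cv coefficient of variation of the capture efficiency (>= 0).
#' @return an object of class `burst_prior`.
#' @export
prior_spec <- function(ksyn_log10 = c(0, 3.7),
                       kon_log10 = c(-2, 2),
                       koff_log10 = c(-2, 2),
                       beta_mean = 0.06,
                       beta_cv = 0.5) {
  for (r in list(ksyn_log10, kon_log10, koff_log10))
    stopifnot(length(r) == 2L, is.finite(r), r[1] <= r[2])
  stopifnot(beta_mean > 0, beta_mean <= 1, beta_cv >= 0)
  structure(
    list(ksyn_log10 = ksyn_log10, kon_log10 = kon_log10,
         koff_log10 = koff_log10, beta_mean = beta_mean, beta_cv = beta_cv),
    class = "burst_prior"
  )
}

#' @export
print.burst_prior <- function(x, ...) {
  cat("Telegraph-model prior\n")
  cat(sprintf("  log10 ksyn  in [%g, %g]\n", x$ksyn_log10[1], x$ksyn_log10[2]))
  cat(sprintf("  log10 kon   in [%g, %g]\n", x$kon_log10[1], x$kon_log10[2]))
  cat(sprintf("  log10 koff  in [%g, %g]\n", x$koff_log10[1], x$koff_log10[2]))
  cat(sprintf("  capture efficiency: log-normal mean %g, CV %g, clipped to (0, 1]\n",
              x$beta_mean, x$beta_cv))
  invisible(x)
}
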