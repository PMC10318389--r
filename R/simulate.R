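#' Sample kinetic parameters from the log-uniform prior
#'
#' Draws independent log10-uniform kinetic parameters for `n_genes` genes from
#' the ranges in a [prior_spec()].
#'
#' @param prior a [prior_spec()] object.
#' @param n_genes number of genes.
#' @param seed integer seed for reproducibility.
#' @return a [kinetic_params()] tibble.
#' @export
sample_kinetics <- function(prior, n_genes, seed = NULL) {
  stopifnot(inherits(prior, "burst_prior"), n_genes >= 1)
  if (!is.null(seed)) set.seed(seed)
  kinetic_params(
    ksyn = 10^stats::runif(n_genes, prior$ksyn_log10[1], prior$ksyn_log10[2]),
    kon = 10^stats::runif(n_genes, prior$kon_log10[1], prior$kon_log10[2]),
    koff = 10^stats::runif(n_genes, prior$koff_log10[1], prior$koff_log10[2])
  )
}

#' Sample per-cell capture efficiencies
#'
#' Draws capture efficiencies from a log-normal distribution with the mean and
#' coefficient of variation in the prior, clipped to `(0, 1]`. With `cv = 0`
#' all cells receive the mean efficiency.
#'
#' @param prior a [prior_spec()] object.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param size optional per-cell relative sizes (default 1).
#' @return a tibble with columns `cell`, `beta`, `size`, `beta_eff`.
#' @export
sample_capture <- function(prior, n_cells, seed = NULL, size = NULL) {
  stopifnot(inherits(prior, "burst_prior"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- prior$beta_mean
  cv <- prior$beta_cv
  if (cv == 0) {
    beta <- rep(m, n_cells)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(m) - sdlog^2 / 2
    beta <- stats::rlnorm(n_cells, meanlog, sdlog)
    beta <- pmin(beta, 1)
  }
  if (is.null(size)) size <- rep(1, n_cells)
  stopifnot(length(size) == n_cells, all(size > 0))
  tibble::tibble(
    cell = paste0("cell", seq_len(n_cells)),
    beta = beta,
    size = size,
    beta_eff = effective_capture(beta, size)
  )
}

#' Simulate observed counts for one gene
#'
#' Generates steady-state telegraph-model counts observed through binomial
#' capture. The explicit path draws promoter activity `p ~ Beta(kon, koff)`,
#' original counts `X ~ Poisson(size * ksyn * p)` and observed counts
#' `x ~ Binomial(X, beta)`. By the thinning identity this is distributionally
#' identical to drawing directly from the Beta-Poisson law with rate
#' `beta * size * ksyn`; the direct path is available as a shortcut.
#' Nonallele mode sums two independent allele draws sharing the same cell
#' context.
#'
#' @param params one row of a [kinetic_params()] table (or a list with
#'   `ksyn`, `kon`, `koff`).
#' @param cells tibble from [sample_capture()] (columns `beta`, `size`).
#' @param mode `"allele"` or `"nonallele"`.
#' @param seed integer seed.
#' @param path `"explicit"` (Poisson then binomial thinning) or `"direct"`
#'   (Beta-Poisson at the thinned rate).
#' @return a list with integer vectors `observed` and (explicit path only)
#'   `original`.
#' @export
simulate_gene <- function(params, cells, mode = c("allele", "nonallele"),
                          seed = NULL, path = c("explicit", "direct")) {
  mode <- match.arg(mode)
  path <- match.arg(path)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cells)
  n_alleles <- if (mode == "nonallele") 2L else 1L
  observed <- integer(n)
  original <- integer(n)
  for (a in seq_len(n_alleles)) {
    p <- stats::rbeta(n, params$kon, params$koff)
    if (path == "explicit") {
      X <- stats::rpois(n, cells$size * params$ksyn * p)
      x <- stats::rbinom(n, X, cells$beta)
      original <- original + X
    } else {
      x <- stats::rpois(n, cells$beta * cells$size * params$ksyn * p)
    }
    observed <- observed + x
  }
  out <- list(observed = observed)
  if (path == "explicit") out$original <- original
  out
}

#' Flag entries missing completely at random
#'
#' Applies a per-gene missing-value mask to a count matrix, emulating
#' allele-resolved data in which the number of missing values varies between
#' genes. Masked entries are set to `NA` and are excluded by all downstream
#' moment and likelihood computations.
#'
#' @param counts genes x cells integer matrix.
#' @param missing_fraction scalar or per-gene vector of missing rates in `[0, 1]`.
#' @param seed integer seed.
#' @return the matrix with `NA` at masked positions.
#' @export
apply_missing_mask <- function(counts, missing_fraction, seed = NULL) {
  stopifnot(is.matrix(counts))
  G <- nrow(counts)
  if (length(missing_fraction) == 1L) missing_fraction <- rep(missing_fraction, G)
  stopifnot(length(missing_fraction) == G,
            all(missing_fraction >= 0), all(missing_fraction <= 1))
  if (!is.null(seed)) set.seed(seed)
  for (g in seq_len(G)) {
    if (missing_fraction[g] > 0) {
      hit <- stats::runif(ncol(counts)) < missing_fraction[g]
      counts[g, hit] <- NA
    }
  }
  counts
}

#' Simulate a full synthetic dataset with known truth
#'
#' Draws kinetics from the prior, capture efficiencies per cell, and one count
#' row per gene (vectorized over the whole matrix), returning observed counts
#' together with the generating truth - the backbone of all benchmarks.
#'
#' @param prior a [prior_spec()].
#' @param n_genes number of genes.
#' @param n_cells number of cells.
#' @param mode `"allele"` or `"nonallele"`.
#' @param seed integer seed (set once for the whole dataset).
#' @param missing_fraction optional per-gene (or scalar) missing rate.
#' @param truth optional [kinetic_params()] table to reuse instead of sampling.
#' @param cells optional capture tibble to reuse instead of sampling.
#' @return an object of class `burst_dataset`: a list with `counts` (matrix,
#'   genes x cells, `NA` = missing), `truth`, `cells`, `mode`, `seed`.
#' @export
simulate_dataset <- function(prior, n_genes, n_cells,
                             mode = c("allele", "nonallele"), seed = NULL,
                             missing_fraction = 0, truth = NULL, cells = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) truth <- sample_kinetics(prior, n_genes)
  n_genes <- nrow(truth)
  if (is.null(cells)) cells <- sample_capture(prior, n_cells)
  n_cells <- nrow(cells)
  counts <- bp_simulate_matrix(truth, cells$beta_eff, n_alleles =
                                 if (mode == "nonallele") 2L else 1L)
  dimnames(counts) <- list(truth$gene, cells$cell)
  if (any(missing_fraction > 0))
    counts <- apply_missing_mask(counts, missing_fraction)
  structure(list(counts = counts, truth = truth, cells = cells,
                 mode = mode, seed = seed),
            class = "burst_dataset")
}

#' @export
print.burst_dataset <- function(x, ...) {
  cat(sprintf("Synthetic burst-kinetics dataset: %d genes x %d cells (%s mode)\n",
              nrow(x$counts), ncol(x$counts), x$mode))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$counts))))
  invisible(x)
}

# vectorized matrix simulation via the thinning shortcut: one rbeta/rpois call
# over all gene-cell pairs per allele
bp_simulate_matrix <- function(truth, beta_eff, n_alleles = 1L) {
  G <- nrow(truth)
  C <- length(beta_eff)
  counts <- matrix(0L, G, C)
  kon <- rep(truth$kon, times = C)
  koff <- rep(truth$koff, times = C)
  lam0 <- outer(truth$ksyn, beta_eff)
  for (a in seq_len(n_alleles)) {
    p <- stats::rbeta(G * C, kon, koff)
    counts <- counts + matrix(stats::rpois(G * C, lam0 * p), G, C)
  }
  counts
}

#' Build a benchmark collection across cell numbers and replicates
#'
#' Generates the replicated synthetic benchmark: for each number of cells and
#' each replicate, a dataset of `n_genes` genes with truth attached. Replicates
#' share the prior but redraw kinetics and capture efficiencies.
#'
#' @param prior a [prior_spec()].
#' @param n_cells integer vector of cell numbers (e.g. `c(200, 1000, 5000)`).
#' @param n_genes genes per dataset.
#' @param n_reps replicates per cell number.
#' @param mode `"allele"` or `"nonallele"`.
#' @param seed integer seed; replicate seeds are derived deterministically.
#' @return a tibble with columns `n_cells`, `rep`, `seed`, `data`
#'   (list-column of `burst_dataset`).
#' @export
build_benchmark <- function(prior, n_cells, n_genes, n_reps = 20,
                            mode = c("allele", "nonallele"), seed = 1) {
  mode <- match.arg(mode)
  grid <- tidyr::expand_grid(n_cells = as.integer(n_cells),
                             rep = seq_len(n_reps))
  grid$seed <- seed + 7919L * (seq_len(nrow(grid)) - 1L)
  grid$data <- purrr::pmap(grid, function(n_cells, rep, seed) {
    simulate_dataset(prior, n_genes, n_cells, mode = mode, seed = seed)
  })
  grid
}
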