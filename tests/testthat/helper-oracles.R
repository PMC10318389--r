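# High-precision independent pmf oracle: probability-integral-transform of the
# mixing Beta, P(x) = int_0^1 dpois(x, lam * qbeta(u, kon, koff)) du, with
# adaptive integration split at several points around the Poisson peak. The
# integrand is bounded by 1 and free of endpoint singularities, so this is
# accurate to ~1e-12 independently of the package's Gauss-Jacobi machinery.
bp_pmf_oracle <- function(x, lam, kon, koff, rel.tol = 1e-11) {
  vapply(x, function(xx) {
    if (lam == 0) return(as.numeric(xx == 0))
    f <- function(u) dpois(xx, lam * qbeta(u, kon, koff))
    # split ladder around the Poisson peak; anchored at 1 for x = 0 so the
    # boundary layer exp(-lam * qbeta(u)) near u = 0 is always resolved
    sp <- pbeta((max(xx, 1) / lam) * 2^seq(-3, 3, by = 0.5), kon, koff)
    brk <- sort(unique(c(0, pmin(pmax(sp, 1e-10), 1 - 1e-10), 1)))
    # qbeta emits precision warnings for extreme Beta shapes; the affected
    # regions have negligible measure in u (verified against p-space
    # integration), so they are muffled here
    sum(vapply(seq_len(length(brk) - 1), function(i)
      suppressWarnings(
        integrate(f, brk[i], brk[i + 1], rel.tol = rel.tol, abs.tol = 1e-16,
                  subdivisions = 5000L, stop.on.error = FALSE)$value),
      numeric(1)))
  }, numeric(1))
}

# cell-context tibble with explicit values, for toy constructions
make_cells <- function(beta, size = rep(1, length(beta))) {
  tibble::tibble(cell = paste0("cell", seq_along(beta)),
                 beta = beta, size = size, beta_eff = beta * size)
}

# analytic thinning of a pmf vector: P(x) = sum_X pmf(X) * dbinom(x, X, beta)
thin_pmf <- function(pmf, beta, x_out) {
  X <- seq_along(pmf) - 1L
  vapply(x_out, function(xx) sum(pmf * dbinom(xx, X, beta)), numeric(1))
}
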