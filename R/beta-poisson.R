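#' Beta-Poisson distribution of the telegraph model
#'
#' Stationary transcript-count law of the two-state (telegraph) gene model:
#' a Poisson count whose rate `lam * p` is modulated by a Beta-distributed
#' promoter activity `p ~ Beta(kon, koff)`. All rates are relative to the
#' effective mRNA decay rate, so `lam` is the (dimensionless) synthesis rate
#' possibly already scaled by capture efficiency and cell size.
#'
#' The pmf is evaluated by Gauss-Jacobi quadrature whose weight function is the
#' Beta kernel itself, so endpoint singularities (`kon < 1` or `koff < 1`) are
#' absorbed exactly into the rule. Evaluation is in log space throughout.
#' The quadrature order is escalated automatically until two successive orders
#' agree, so returned probabilities are accurate to well below `1e-10`.
#'
#' @param x vector of non-negative integer counts.
#' @param lam effective synthesis rate (>= 0), scalar.
#' @param kon promoter activation rate (> 0), scalar.
#' @param koff promoter inactivation rate (> 0), scalar.
#' @param log logical; return log-probabilities?
#' @param n_quad optional fixed quadrature order; by default the order is
#'   chosen from `lam` and doubled until stable.
#'
#' @return numeric vector of (log-)probabilities, same length as `x`.
#' @examples
#' dbetapois(0:5, lam = 10, kon = 0.5, koff = 2)
#' @export
dbetapois <- function(x, lam, kon, koff, log = FALSE, n_quad = NULL) {
  check_bp_params(lam, kon, koff)
  x <- check_counts(x)
  lp <- bp_logpmf_core(x, lam, kon, koff, n_quad = n_quad)
  if (log) lp else exp(lp)
}

#' Log-pmf of the Beta-Poisson distribution
#'
#' Numerically safe companion of [dbetapois()]: never returns `NaN` for valid
#' inputs and stays finite even for extreme rates (e.g. `lam = 5000` with
#' heavily skewed Beta kernels).
#'
#' @inheritParams dbetapois
#' @return numeric vector of log-probabilities.
#' @export
dbetapois_log <- function(x, lam, kon, koff, n_quad = NULL) {
  dbetapois(x, lam, kon, koff, log = TRUE, n_quad = n_quad)
}

#' Negative-binomial bursty limit of the telegraph model
#'
#' In the bursty regime (large `koff` and `ksyn` with their ratio fixed) the
#' Beta-Poisson law converges to a negative binomial characterized by the burst
#' frequency (shape) and burst size (mean per burst).
#'
#' @param x vector of non-negative integers.
#' @param burst_frequency shape parameter, the activation rate `kon` (> 0).
#' @param burst_size mean transcripts per burst, `ksyn / koff` (>= 0).
#' @param log logical; return log-probabilities?
#' @return numeric vector of (log-)probabilities.
#' @export
dnb_limit <- function(x, burst_frequency, burst_size, log = FALSE) {
  stopifnot(is.finite(burst_frequency), burst_frequency > 0,
            is.finite(burst_size), burst_size >= 0)
  x <- check_counts(x)
  if (burst_size == 0) {
    lp <- ifelse(x == 0, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  stats::dnbinom(x, size = burst_frequency,
                 mu = burst_frequency * burst_size, log = log)
}

#' Distribution of the sum of two independent identical alleles
#'
#' Total (nonallele-specific) counts are modelled as the sum of two
#' independent Beta-Poisson draws with identical kinetics sharing the same
#' effective rate. Computed as the discrete self-convolution of the
#' single-allele pmf, truncated where the single-allele law has accumulated
#' mass at least `1 - 1e-10`.
#'
#' @inheritParams dbetapois
#' @return numeric vector of (log-)probabilities.
#' @export
dbetapois2 <- function(x, lam, kon, koff, log = FALSE, n_quad = NULL) {
  check_bp_params(lam, kon, koff)
  x <- check_counts(x)
  if (lam == 0) {
    lp <- ifelse(x == 0, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  xmax <- max(x)
  grid <- 0:max(bp_support_cap(lam, kon, koff), xmax)
  p1 <- exp(bp_logpmf_core(grid, lam, kon, koff, n_quad = n_quad))
  p2 <- bp_self_convolve(p1)
  out <- rep(0, length(x))
  inside <- x < length(p2)
  out[inside] <- p2[x[inside] + 1L]
  if (log) base::log(out) else out
}

#' Factorial moments of the Beta-Poisson law
#'
#' Closed-form falling-factorial moments
#' `f_r = (lam_scale * ksyn)^r * prod_{i=0}^{r-1} (kon + i) / (kon + koff + i)`,
#' the quantities matched by the method-of-moments estimators.
#'
#' @param ksyn synthesis rate (> 0).
#' @param kon activation rate (> 0).
#' @param koff inactivation rate (> 0).
#' @param lam_scale multiplicative scale on the synthesis rate (e.g. an
#'   effective capture efficiency); default 1.
#' @param order highest moment order, 1 to 3.
#' @return numeric vector `c(f1, ..., f_order)`.
#' @export
bp_factorial_moments <- function(ksyn, kon, koff, lam_scale = 1, order = 3L) {
  stopifnot(is.finite(ksyn), ksyn > 0, is.finite(kon), kon > 0,
            is.finite(koff), koff > 0, is.finite(lam_scale), lam_scale >= 0,
            order >= 1L, order <= 3L)
  vapply(seq_len(order), function(r) {
    i <- 0:(r - 1)
    (lam_scale * ksyn)^r * prod((kon + i) / (kon + koff + i))
  }, numeric(1))
}

# ---- internal machinery ------------------------------------------------------

check_bp_params <- function(lam, kon, koff) {
  if (!(length(lam) == 1L && length(kon) == 1L && length(koff) == 1L))
    stop("lam, kon, koff must be scalars", call. = FALSE)
  if (!is.finite(lam) || lam < 0)
    stop("invalid parameter: lam must be finite and >= 0", call. = FALSE)
  if (!is.finite(kon) || kon <= 0 || !is.finite(koff) || koff <= 0)
    stop("invalid parameter: kon and koff must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

check_counts <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    stop("x must contain non-negative integers", call. = FALSE)
  as.integer(round(x))
}

# Gauss-Jacobi nodes/log-weights for weight (1-t)^alpha (1+t)^beta on [-1, 1]
# via Golub-Welsch on the symmetric Jacobi matrix. mu0 kept in log space so
# extreme Beta shapes (kon or koff ~ 1e-8 or ~ 1e4) do not overflow.
gauss_jacobi <- function(n, alpha, beta) {
  ab <- alpha + beta
  d <- numeric(n)
  d[1] <- (beta - alpha) / (ab + 2)
  if (n > 1) {
    k <- seq_len(n - 1)
    d[k + 1] <- (beta^2 - alpha^2) / ((2 * k + ab) * (2 * k + ab + 2))
  }
  e <- numeric(max(n - 1, 0))
  if (n > 1) {
    # k = 1 written with the (1 + ab) factor cancelled so ab = -1 is regular
    e[1] <- sqrt(4 * (1 + alpha) * (1 + beta) / ((2 + ab)^2 * (3 + ab)))
    if (n > 2) {
      k <- 2:(n - 1)
      e[k] <- sqrt(4 * k * (k + alpha) * (k + beta) * (k + ab) /
                     ((2 * k + ab)^2 * (2 * k + ab + 1) * (2 * k + ab - 1)))
    }
  }
  J <- diag(d, nrow = n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    J[cbind(idx, idx + 1L)] <- e
    J[cbind(idx + 1L, idx)] <- e
  }
  es <- eigen(J, symmetric = TRUE)
  ord <- order(es$values)
  log_mu0 <- (ab + 1) * log(2) + lbeta(alpha + 1, beta + 1)
  list(nodes = es$values[ord],
       logw = log_mu0 + 2 * log(abs(es$vectors[1, ord])))
}

# Quadrature rule against the normalized Beta(kon, koff) kernel on (0, 1):
# sum(exp(logW)) == 1 and  E[f(p)] = sum exp(logW) f(p).
bp_quad_rule <- function(n, kon, koff) {
  gj <- gauss_jacobi(n, alpha = koff - 1, beta = kon - 1)
  list(p = (1 + gj$nodes) / 2,
       logW = gj$logw - (kon + koff - 1) * log(2) - lbeta(kon, koff),
       n = n)
}

# log pmf for count vector x and per-element rate vector lam given a rule;
# x recycles column-major against the (x, node) rate matrix
bp_logpmf_rule <- function(x, lam, rule) {
  L <- outer(lam, rule$p)
  M <- matrix(stats::dpois(x, L, log = TRUE), nrow = length(x))
  M <- sweep(M, 2, rule$logW, "+")
  row_logsumexp(M)
}

row_logsumexp <- function(M) {
  m <- apply(M, 1, max)
  fin <- is.finite(m)
  out <- m
  if (any(fin))
    out[fin] <- m[fin] + log(rowSums(exp(M[fin, , drop = FALSE] - m[fin])))
  out
}

bp_order_guess <- function(lam) {
  if (lam <= 100) 50L else if (lam <= 1000) 100L else if (lam <= 10000) 200L else 400L
}

# adaptive evaluation: double the order until two successive rules agree
bp_logpmf_core <- function(x, lam, kon, koff, n_quad = NULL, tol = 1e-11) {
  if (lam == 0) return(ifelse(x == 0, 0, -Inf))
  if (!is.null(n_quad)) {
    return(bp_logpmf_rule(x, rep(lam, length(x)), bp_quad_rule(n_quad, kon, koff)))
  }
  n <- bp_order_guess(lam)
  lamv <- rep(lam, length(x))
  cur <- bp_logpmf_rule(x, lamv, bp_quad_rule(n, kon, koff))
  repeat {
    n2 <- 2L * n
    nxt <- bp_logpmf_rule(x, lamv, bp_quad_rule(n2, kon, koff))
    if (max(abs(exp(nxt) - exp(cur))) < tol || n2 >= 800L) return(nxt)
    n <- n2
    cur <- nxt
  }
}

# upper support point covering all but ~1e-12 of the mass (mean + 20 sd, padded)
bp_support_cap <- function(lam, kon, koff) {
  m <- lam * kon / (kon + koff)
  f2 <- lam^2 * kon * (kon + 1) / ((kon + koff) * (kon + koff + 1))
  v <- max(f2 + m - m^2, m, 1)
  as.integer(ceiling(m + 20 * sqrt(v)) + 10)
}

# self-convolution of a pmf vector truncated at mass coverage >= 1 - 1e-10
bp_self_convolve <- function(p) {
  cm <- cumsum(p)
  keep <- min(which(cm >= 1 - 1e-10), length(p))
  p <- p[seq_len(keep)]
  n <- length(p)
  out <- numeric(2 * n - 1)
  for (i in seq_len(n)) {
    idx <- i:(i + n - 1)
    out[idx] <- out[idx] + p[i] * p
  }
  out
}
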