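#' Estimate per-cell capture efficiencies from total counts
#'
#' Each transcript in cell `j` is observed with probability `beta_j`, so total
#' counts are proportional to capture efficiency (and cell size). Capture
#' efficiencies are estimated by normalizing cell totals to a supplied mean
#' efficiency: `beta_j = mean_beta * T_j / mean(T)`, with `T_j` the cell's
#' total count over nonmissing entries. Values exceeding 1 are clipped (and
#' reported via the `n_clipped` attribute).
#'
#' @param counts genes x cells integer matrix; `NA` entries are treated as
#'   missing and excluded from the totals.
#' @param mean_beta assumed mean capture efficiency in `(0, 1]`.
#' @return a tibble with columns `cell`, `total`, `beta`; attribute
#'   `n_clipped` counts cells clipped at 1.
#' @examples
#' m <- matrix(c(10L, 30L, 20L, 60L), nrow = 2, byrow = TRUE)
#' estimate_beta(m, mean_beta = 0.06)
#' @export
estimate_beta <- function(counts, mean_beta) {
  stopifnot(is.matrix(counts), length(mean_beta) == 1L,
            is.finite(mean_beta), mean_beta > 0, mean_beta <= 1)
  totals <- colSums(counts, na.rm = TRUE)
  if (all(totals == 0))
    stop("degenerate input: all counts are zero, cannot estimate capture efficiencies",
         call. = FALSE)
  beta <- mean_beta * totals / mean(totals)
  n_clipped <- sum(beta > 1)
  beta <- pmin(beta, 1)
  cells <- colnames(counts)
  if (is.null(cells)) cells <- paste0("cell", seq_along(beta))
  out <- tibble::tibble(cell = cells, total = as.numeric(totals), beta = beta)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Effective capture efficiency folding in relative cell size
#'
#' Capture efficiency and relative cell size act on observed counts through
#' their product only, which scales the effective synthesis rate per cell.
#' When `size` is omitted the size variability is regarded as absorbed into
#' the capture estimate and `beta` is returned unchanged. Products exceeding 1
#' are clipped (with a warning).
#'
#' @param beta per-cell capture efficiencies in `(0, 1]`.
#' @param size optional per-cell relative sizes (> 0).
#' @return numeric vector of effective capture efficiencies.
#' @export
effective_capture <- function(beta, size = NULL) {
  stopifnot(all(is.finite(beta)), all(beta > 0), all(beta <= 1))
  if (is.null(size)) return(as.numeric(beta))
  stopifnot(length(size) == length(beta), all(is.finite(size)), all(size > 0))
  be <- beta * size
  if (any(be > 1)) {
    warning(sum(be > 1), " effective capture efficiencies exceeded 1 and were clipped")
    be <- pmin(be, 1)
  }
  as.numeric(be)
}
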