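#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ABC fit into its per-gene estimate table
#'
#' @param x a `burst_abc` object.
#' @param ... unused.
#' @return the per-gene estimates tibble.
#' @method tidy burst_abc
#' @export
tidy.burst_abc <- function(x, ...) x$estimates

#' One-row summary of an ABC fit
#'
#' @param x a `burst_abc` object.
#' @param ... unused.
#' @return a one-row tibble: genes fitted, failures, accepted draws per gene.
#' @method glance burst_abc
#' @export
glance.burst_abc <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$estimates),
    n_failed = sum(x$estimates$status != "ok"),
    n_accepted = if (nrow(x$samples)) max(x$samples$draw) else 0L,
    mode = x$mode)
}

#' Per-member diagnostics of a trained ensemble
#'
#' @param x a `burst_nn` object.
#' @param ... unused.
#' @return a tibble with one row per ensemble member and its held-out loss.
#' @method tidy burst_nn
#' @export
tidy.burst_nn <- function(x, ...) {
  tibble::tibble(member = seq_len(x$E), holdout_nll = x$hold_nll)
}

#' One-row summary of a trained ensemble
#'
#' @param x a `burst_nn` object.
#' @param ... unused.
#' @return a one-row tibble with ensemble size, held-out losses and RMSEs.
#' @method glance burst_nn
#' @export
glance.burst_nn <- function(x, ...) {
  tibble::tibble(
    E = x$E, holdout_nll = mean(x$hold_nll), baseline_nll = x$baseline_nll,
    rmse_log10_ksyn = unname(x$hold_rmse[1]),
    rmse_log10_kon = unname(x$hold_rmse[2]),
    rmse_log10_koff = unname(x$hold_rmse[3]),
    mode = x$mode)
}

#' Tidy a model-selection result into its per-gene table
#'
#' @param x a `burst_selection` object.
#' @param ... unused.
#' @return the per-gene selection tibble.
#' @method tidy burst_selection
#' @export
tidy.burst_selection <- function(x, ...) x$table

#' One-row summary of a model-selection result
#'
#' @param x a `burst_selection` object.
#' @param ... unused.
#' @return a one-row tibble with assignment counts per model.
#' @method glance burst_selection
#' @export
glance.burst_selection <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    n_bp = sum(x$table$assigned == "BP"),
    n_nb = sum(x$table$assigned == "NB"),
    n_poisson = sum(x$table$assigned == "Poisson"))
}
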