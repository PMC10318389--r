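#' Read a gene x cell count matrix
#'
#' Reads TSV/CSV (genes as rows with identifiers in the first column, cells as
#' header columns; a configurable token marks missing values) or MatrixMarket
#' sparse format (`.mtx`, with optional `<stem>.genes.txt` / `<stem>.cells.txt`
#' sidecar identifier files; sparse format carries no missing-value mask).
#' Values must be non-negative integers; violations raise a parse error that
#' names the offending line.
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension by
#'   default.
#' @param na_token string encoding missing values (TSV/CSV only).
#' @return integer matrix (genes x cells, `NA` = missing) with dimnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        na_token = "NA") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("unknown format for extension '.", ext,
                          "'; pass format= explicitly", call. = FALSE))
  }
  if (format == "mtx") return(read_counts_mtx(path))
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path)
  if (length(lines) < 2) stop("parse error: file has no data rows", call. = FALSE)
  parts <- strsplit(lines, sep, fixed = TRUE)
  ncol_header <- length(parts[[1]])
  cells <- parts[[1]][-1]
  G <- length(lines) - 1L
  mat <- matrix(NA_integer_, G, length(cells))
  genes <- character(G)
  for (i in seq_len(G)) {
    row <- parts[[i + 1]]
    if (length(row) != ncol_header)
      stop("parse error at line ", i + 1, ": expected ", ncol_header,
           " fields, found ", length(row), call. = FALSE)
    genes[i] <- row[1]
    vals <- row[-1]
    miss <- vals == na_token
    num <- suppressWarnings(as.numeric(vals[!miss]))
    if (any(is.na(num)))
      stop("parse error at line ", i + 1, ": non-numeric count value",
           call. = FALSE)
    if (any(num < 0))
      stop("parse error at line ", i + 1, ": negative count value",
           call. = FALSE)
    if (any(num != floor(num)))
      stop("parse error at line ", i + 1, ": non-integer count value",
           call. = FALSE)
    out <- rep(NA_integer_, length(vals))
    out[!miss] <- as.integer(num)
    mat[i, ] <- out
  }
  dimnames(mat) <- list(genes, cells)
  mat
}

read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  if (any(m < 0) || any(m != floor(m)))
    stop("parse error: mtx file contains negative or non-integer values",
         call. = FALSE)
  storage.mode(m) <- "integer"
  stem <- sub("\\.mtx$", "", path)
  gf <- paste0(stem, ".genes.txt"); cf <- paste0(stem, ".cells.txt")
  rownames(m) <- if (file.exists(gf)) readLines(gf)
    else paste0("gene", seq_len(nrow(m)))
  colnames(m) <- if (file.exists(cf)) readLines(cf)
    else paste0("cell", seq_len(ncol(m)))
  m
}

#' Write a gene x cell count matrix
#'
#' Inverse of [read_counts()]; TSV/CSV round-trips bit-exactly including the
#' missing-value mask. MatrixMarket output writes sidecar identifier files and
#' drops the mask (sparse format has no missing-value notion).
#'
#' @param counts integer matrix (genes x cells).
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; guessed from the extension.
#' @param na_token token to write for missing entries.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "csv", "mtx"),
                         na_token = "NA") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("unknown format for extension '.", ext, "'",
                          call. = FALSE))
  }
  stopifnot(is.matrix(counts))
  genes <- rownames(counts) %||% paste0("gene", seq_len(nrow(counts)))
  cells <- colnames(counts) %||% paste0("cell", seq_len(ncol(counts)))
  if (format == "mtx") {
    if (any(is.na(counts)))
      warning("mtx format has no missing-value mask; NA entries written as 0")
    m <- counts; m[is.na(m)] <- 0L
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(genes, paste0(stem, ".genes.txt"))
    writeLines(cells, paste0(stem, ".cells.txt"))
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  body <- apply(counts, 1, function(r) {
    r <- ifelse(is.na(r), na_token, format(r, scientific = FALSE, trim = TRUE))
    paste(r, collapse = sep)
  })
  writeLines(c(paste(c("gene", cells), collapse = sep),
               paste(genes, body, sep = sep)), path)
  invisible(path)
}

#' Filter genes by mean expression and missing-value burden
#'
#' Keeps genes whose mean expression across nonmissing entries is strictly
#' above `min_mean` (a gene at exactly the threshold is removed), then drops
#' genes whose missing fraction exceeds `max_missing_frac`. The two stages are
#' reported separately in the `filter_report` attribute.
#'
#' @param counts genes x cells matrix (`NA` = missing).
#' @param min_mean expression threshold (strict inequality).
#' @param max_missing_frac maximum tolerated fraction of missing entries.
#' @return the filtered matrix; attribute `filter_report` is a tibble with
#'   one row per stage (`stage`, `n_before`, `n_after`).
#' @export
filter_genes <- function(counts, min_mean = 1.0, max_missing_frac = 0.5) {
  stopifnot(is.matrix(counts))
  n0 <- nrow(counts)
  mu <- rowMeans(counts, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  keep1 <- mu > min_mean
  c1 <- counts[keep1, , drop = FALSE]
  mf <- rowMeans(is.na(c1))
  keep2 <- mf <= max_missing_frac
  out <- c1[keep2, , drop = FALSE]
  attr(out, "filter_report") <- tibble::tibble(
    stage = c("mean_expression", "missing_fraction"),
    n_before = c(n0, nrow(c1)),
    n_after = c(nrow(c1), nrow(out)))
  out
}
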