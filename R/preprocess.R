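#' Library-size normalization and log transform
#'
#' Computes `x' = ln(1 + x * s / total)` per cell, the standard log-normalize
#' with a configurable scale factor (default 10,000). The sparsity pattern is
#' preserved: a normalized value is 0 exactly when the count is 0.
#'
#' Cells with zero total counts are an error (silently dropping them would
#' desynchronize the companion label file).
#'
#' @param counts a [count_matrix()].
#' @param scale_factor positive scale factor `s`.
#' @return a `norm_matrix`: list with the sparse `values` matrix, the
#'   `scale_factor` and the `species` tag.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 || scale_factor <= 0) {
    abort_input("normalize_log: scale_factor must be a single positive number")
  }
  X <- counts$counts
  totals <- Matrix::colSums(X)
  if (any(totals == 0)) {
    bad <- colnames(X)[totals == 0]
    abort_input(
      "normalize_log: %d cells have zero total counts: %s",
      length(bad), paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  ## transform nonzero entries in place; column of each entry recovered from
  ## the CSC pointer vector
  col_of <- rep.int(seq_len(ncol(X)), diff(X@p))
  X@x <- log1p(X@x * scale_factor / totals[col_of])
  structure(
    list(values = X, scale_factor = scale_factor, species = counts$species),
    class = "norm_matrix"
  )
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf(
    "norm_matrix: %d genes x %d cells (%s), scale factor %g\n",
    nrow(x$values), ncol(x$values), x$species, x$scale_factor
  ))
  invisible(x)
}
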