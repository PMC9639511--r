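#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats pnorm rlnorm rnbinom
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Condition helpers: input errors (bad files / bad arguments at the boundary,
## CLI exit code 2) vs stage failures (anything raised mid-pipeline, exit 3).
abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("schomology_input_error", "schomology_error")))
}

abort_stage <- function(stage, parent_msg) {
  stop(errorCondition(sprintf("stage '%s' failed: %s", stage, parent_msg),
    class = c("schomology_stage_error", "schomology_error"),
    stage = stage
  ))
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Hashes `(master, ...)` into a 31-bit integer so that each
#' (target cluster, source cluster) pair gets its own deterministic
#' permutation stream, independent of evaluation order.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels mixed into the hash.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  s <- paste(c(as.character(master), vapply(list(...), as.character, "")), collapse = "\x1f")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Fixed-precision number formatting shared by every text writer, so that
## identical results serialize to identical bytes (>= 12 significant digits;
## 15 keeps round-trips well inside the 1e-12 relative contract).
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[scHomology:%s] %s", stage, sprintf(fmt, ...)))
}
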