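#' Signal a classed cdmsteward error
#'
#' All user-facing failures in the package are classed conditions so callers
#' (and the CLI) can distinguish user errors from internal ones. The class
#' vector is `c(paste0("dst_", class), "dst_error", "error", "condition")`.
#'
#' @param class short error class, e.g. "duplicate_variable".
#' @param message human-readable message.
#' @param data optional named list attached to the condition.
#' @keywords internal
dst_abort <- function(class, message, data = list()) {
  cond <- structure(
    class = c(paste0("dst_", class), "dst_error", "error", "condition"),
    c(list(message = message, call = NULL), data)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar-string check used throughout the validators
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
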