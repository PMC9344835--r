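#' Value range of a clinical variable
#'
#' A value range constrains the admissible values of a CDM variable. Three
#' kinds exist: `"numeric"` (a closed interval `[min, max]`), `"enumeration"`
#' (a fixed set of category labels) and `"unconstrained"` (no constraint,
#' used for free-text, dates and open-ended numerics).
#'
#' @param kind one of `"numeric"`, `"enumeration"`, `"unconstrained"`.
#' @param min,max inclusive finite bounds; required iff `kind = "numeric"`.
#' @param categories character vector of unique non-empty category labels;
#'   required iff `kind = "enumeration"`. Uniqueness is enforced
#'   case-insensitively because categorical values are matched
#'   case-insensitively during standardization.
#'
#' @return An object of class `value_range`.
#' @examples
#' value_range("numeric", min = 0, max = 30)
#' value_range("enumeration", categories = c("CN", "MCI", "AD"))
#' value_range("unconstrained")
#' @export
value_range <- function(kind = c("unconstrained", "numeric", "enumeration"),
                        min = NULL, max = NULL, categories = NULL) {
  kind <- match.arg(kind)
  vr <- structure(
    list(kind = kind,
         min = if (kind == "numeric") as.numeric(min),
         max = if (kind == "numeric") as.numeric(max),
         categories = if (kind == "enumeration") as.character(categories)),
    class = "value_range"
  )
  validate_value_range(vr)
  vr
}

validate_value_range <- function(vr) {
  if (!inherits(vr, "value_range")) {
    dst_abort("schema", "not a value_range object")
  }
  if (vr$kind == "numeric") {
    if (length(vr$min) != 1L || length(vr$max) != 1L ||
        !is.finite(vr$min) || !is.finite(vr$max)) {
      dst_abort("schema", "numeric range needs finite scalar min and max")
    }
    if (vr$min > vr$max) {
      dst_abort("schema",
                sprintf("numeric range has min > max (%g > %g)", vr$min, vr$max))
    }
  } else if (vr$kind == "enumeration") {
    cats <- vr$categories
    if (length(cats) < 1L || anyNA(cats) || any(!nzchar(cats))) {
      dst_abort("schema", "enumeration needs at least one non-empty category")
    }
    if (anyDuplicated(tolower(cats))) {
      dst_abort("schema", "enumeration categories duplicate after case-folding")
    }
  } else {
    if (!is.null(vr$min) || !is.null(vr$max) || !is.null(vr$categories)) {
      dst_abort("schema", "unconstrained range must not carry bounds or categories")
    }
  }
  invisible(vr)
}

#' @export
format.value_range <- function(x, ...) {
  switch(x$kind,
         numeric = sprintf("[%g, %g]", x$min, x$max),
         enumeration = paste0("{", paste(x$categories, collapse = ", "), "}"),
         unconstrained = "(unconstrained)")
}

#' @export
print.value_range <- function(x, ...) {
  cat("<value_range>", format(x), "\n")
  invisible(x)
}
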