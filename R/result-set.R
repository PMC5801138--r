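# Ordered per-molecule results: descriptor name -> value or missing_value,
# in registration order.

new_result_set <- function(molecule_name, values) {
  structure(list(molecule_name = molecule_name, values = values),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> %s: %d descriptor(s), %d missing\n",
              x$molecule_name, length(x$values),
              sum(vapply(x$values, is_missing, TRUE))))
  invisible(x)
}

#' @export
length.result_set <- function(x) length(x$values)

#' Handle missing values in a result set
#'
#' `fill_missing()` replaces every [missing_value()] entry by a numeric
#' sentinel; `drop_missing()` removes those entries; `as_mapping()` returns
#' the plain named list of values in registration order.
#'
#' @param result a `result_set` as returned by [calculate()].
#' @param fill numeric sentinel (default `NaN`).
#' @return `fill_missing()` and `drop_missing()` return a `result_set`;
#'   `as_mapping()` a named list.
#' @export
fill_missing <- function(result, fill = NaN) {
  stopifnot(inherits(result, "result_set"))
  result$values <- lapply(result$values, function(v) if (is_missing(v)) fill else v)
  result
}

#' @rdname fill_missing
#' @export
drop_missing <- function(result) {
  stopifnot(inherits(result, "result_set"))
  result$values <- result$values[!vapply(result$values, is_missing, TRUE)]
  result
}

#' @rdname fill_missing
#' @export
as_mapping <- function(result) {
  stopifnot(inherits(result, "result_set"))
  result$values
}

#' @export
as.data.frame.result_set <- function(x, ...) {
  vals <- lapply(x$values, function(v) if (is_missing(v)) NA_real_ else as.numeric(v))
  cbind(data.frame(name = x$molecule_name, stringsAsFactors = FALSE),
        as.data.frame(vals, check.names = FALSE))
}
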