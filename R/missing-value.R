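# Typed missing values: descriptors return these instead of raising, so one
# bad molecule or one undefined quantity never aborts a batch.

.MISSING_REASONS <- c("parse_failure", "disconnected", "empty_graph",
                      "divide_by_zero", "unsupported_atom",
                      "dependency_failure", "timeout")

#' Typed missing value
#'
#' A first-class non-result carrying the causal reason. Returned by
#' descriptor evaluations that are undefined for a molecule (for example a
#' distance-based descriptor on a disconnected molecule) and propagated
#' through dependent and composite descriptors.
#'
#' @param reason one of `r paste0('"', .MISSING_REASONS, '"', collapse = ", ")`.
#' @param message human-readable detail.
#' @param descriptor name of the originating descriptor (filled in by the
#'   calculator when known).
#' @return An object of class `missing_value`.
#' @export
missing_value <- function(reason, message = reason, descriptor = NA_character_) {
  reason <- match.arg(reason, .MISSING_REASONS)
  structure(list(reason = reason, message = as.character(message),
                 descriptor = as.character(descriptor)),
            class = "missing_value")
}

#' @rdname missing_value
#' @param x object to test.
#' @export
is_missing <- function(x) inherits(x, "missing_value")

#' @export
print.missing_value <- function(x, ...) {
  cat(sprintf("<missing: %s> %s (descriptor: %s)\n", x$reason, x$message,
              x$descriptor))
  invisible(x)
}

#' @export
format.missing_value <- function(x, ...) sprintf("<missing:%s>", x$reason)

# signal a missing value as a classed condition; calculate() catches these
raise_missing <- function(mv) {
  stop(structure(class = c("topodesc_missing", "error", "condition"),
                 list(message = mv$message, call = NULL, mv = mv)))
}

# unwrap: if x is missing, abort evaluation with it; else return it
value_or_raise <- function(x) {
  if (is_missing(x)) raise_missing(x)
  x
}
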