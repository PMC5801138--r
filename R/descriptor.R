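# Descriptor objects: named, parameterized, self-describing calculation
# units returning one scalar each. Composites built with arithmetic
# operators are descriptors too.

#' Define a descriptor
#'
#' @param family family label (e.g. `"ZagrebIndex"`).
#' @param name unique identifier within a calculator.
#' @param fn evaluator `function(mol, ctx)` returning a single numeric value
#'   or a [missing_value()]. `ctx$need("<intermediate>")` resolves (and
#'   caches per molecule) shared intermediates such as `"dist"` or `"delta"`;
#'   if the intermediate is itself missing, evaluation aborts and the missing
#'   value propagates.
#' @param parameters named list of parameter values (self-description only).
#' @param dependencies character vector of intermediate names the evaluator
#'   uses (declared for introspection; resolution happens through `ctx`).
#' @return An object of class `descriptor`.
#' @export
descriptor <- function(family, name, fn, parameters = list(),
                       dependencies = character(0)) {
  stopifnot(is.function(fn), nzchar(name))
  structure(list(family = family, name = name, fn = fn,
                 parameters = parameters, dependencies = dependencies),
            class = "descriptor")
}

#' @export
print.descriptor <- function(x, ...) {
  p <- if (length(x$parameters))
    paste0(" [", paste(names(x$parameters), unlist(x$parameters),
                       sep = "=", collapse = ", "), "]") else ""
  cat(sprintf("<descriptor> %s (%s)%s\n", x$name, x$family, p))
  invisible(x)
}

# evaluate a descriptor in a context, memoized under its name so composites
# and registered descriptors share work
eval_descriptor <- function(d, mol, ctx) {
  key <- paste0("desc::", d$name)
  if (ctx$has(key)) return(ctx$get(key))
  val <- d$fn(mol, ctx)
  ctx$set(key, val)
  val
}

#' Combine descriptors with arithmetic
#'
#' Builds a composite descriptor whose value is `op` applied to the operand
#' values; a [missing_value()] in any operand propagates with reason
#' `"dependency_failure"` and division by zero yields `"divide_by_zero"`.
#' The standard arithmetic operators (`+`, `-`, `*`, `/`, `^`) are
#' overloaded for descriptors, so `combine()` is rarely called directly.
#'
#' @param a a [descriptor()] or numeric constant.
#' @param op one of `"+"`, `"-"`, `"*"`, `"/"`, `"^"` or `"negate"`.
#' @param b a [descriptor()] or numeric constant; omit for `"negate"`.
#' @return A composite [descriptor()], name auto-generated from operands.
#' @examples
#' z <- preset("ZagrebIndex")
#' prod_term <- combine(z[[1]], "*", z[[2]])
#' @export
combine <- function(a, op, b = NULL) {
  op <- match.arg(op, c("+", "-", "*", "/", "^", "negate"))
  opname <- function(x) {
    if (inherits(x, "descriptor")) x$name else format(x)
  }
  opval <- function(x, mol, ctx) {
    if (inherits(x, "descriptor")) {
      v <- tryCatch(eval_descriptor(x, mol, ctx),
                    topodesc_missing = function(e) e$mv)
      if (is_missing(v))
        raise_missing(missing_value("dependency_failure",
                                    paste("operand", x$name, "is missing:", v$reason)))
      v
    } else {
      x
    }
  }
  if (op == "negate") {
    name <- paste0("-(", opname(a), ")")
    fn <- function(mol, ctx) -opval(a, mol, ctx)
  } else {
    name <- paste0("(", opname(a), " ", op, " ", opname(b), ")")
    fn <- function(mol, ctx) {
      va <- opval(a, mol, ctx)
      vb <- opval(b, mol, ctx)
      if (op == "/" && vb == 0)
        return(missing_value("divide_by_zero", paste(name, ": zero denominator")))
      switch(op, `+` = va + vb, `-` = va - vb, `*` = va * vb,
             `/` = va / vb, `^` = va ^ vb)
    }
  }
  structure(list(family = "Composite", name = name, fn = fn,
                 parameters = list(op = op),
                 dependencies = character(0),
                 operands = list(a = a, b = b)),
            class = c("composite_descriptor", "descriptor"))
}

#' @export
Ops.descriptor <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/", "^"))
    stop("operator '", .Generic, "' is not defined for descriptors")
  if (missing(e2)) {
    if (.Generic == "-") return(combine(e1, "negate"))
    return(e1)
  }
  combine(e1, .Generic, e2)
}
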