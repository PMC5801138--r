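# Calculator: ordered registry of descriptors with dependency-resolved,
# per-molecule cached evaluation, error containment as typed missing values,
# and order-preserving parallel batch computation.

# ---- shared intermediates ---------------------------------------------------

# Providers for intermediates shared across descriptors (the distance matrix,
# the delta vectors, subgraph enumerations, ...). Each provider is a pure
# function of (mol, ctx); results are cached per molecule by the context.
intermediate_providers <- function() {
  list(
    adjacency = function(mol, ctx) adjacency_matrix(mol),
    dist      = function(mol, ctx) distance_matrix(mol),
    detour    = function(mol, ctx) detour_matrix(mol),
    delta     = function(mol, ctx) delta_vector(mol),
    delta_v   = function(mol, ctx) valence_delta_vector(mol),
    sssr      = function(mol, ctx) sssr_rings(mol),
    mid_w     = function(mol, ctx) mid_atom_weights(mol),
    kappa_descs    = function(mol, ctx) kappa_shape(mol),
    distance_descs = function(mol, ctx) distance_descriptors(mol, dist = ctx$need("dist")),
    detour_descs   = function(mol, ctx) detour_descriptors(mol, bundle = ctx$need("detour"))
  )
}

# evaluation context: per-molecule memo store + intermediate resolution
new_eval_context <- function(cache = TRUE) {
  store <- new.env(parent = emptyenv())
  providers <- intermediate_providers()
  ctx <- new.env(parent = emptyenv())
  ctx$has <- function(key) cache && !is.null(store[[key]])
  ctx$get <- function(key) store[[key]]
  ctx$set <- function(key, val) { if (cache) store[[key]] <- val; invisible(val) }
  ctx$mol <- NULL
  ctx$need <- function(name) {
    key <- paste0("int::", name)
    if (ctx$has(key)) return(value_or_raise(ctx$get(key)))
    prov <- providers[[name]]
    if (is.null(prov)) {
      # dynamic intermediates: connected edge subgraphs of a given order
      if (grepl("^subg_[0-9]+$", name)) {
        m <- as.integer(sub("^subg_", "", name))
        prov <- function(mol, ctx) classified_edge_subgraphs(mol, m)
      } else {
        stop("unknown intermediate: ", name)
      }
    }
    val <- prov(ctx$mol, ctx)
    ctx$set(key, val)
    value_or_raise(val)
  }
  ctx
}

# ---- calculator -------------------------------------------------------------

#' Create a descriptor calculator
#'
#' @param ... items to [register()]: [descriptor()] objects, family names
#'   (registered via their [preset()]), or lists of either.
#' @return An object of class `calculator`, an ordered descriptor registry.
#' @examples
#' calc <- calculator("WienerIndex", "ZagrebIndex")
#' names(calc)
#' @export
calculator <- function(...) {
  calc <- structure(list(descriptors = list()), class = "calculator")
  for (item in list(...)) calc <- register(calc, item)
  calc
}

#' @export
print.calculator <- function(x, ...) {
  fams <- unique(vapply(x$descriptors, function(d) d$family, ""))
  cat(sprintf("<calculator> %d descriptor(s) from %d family(ies)\n",
              length(x$descriptors), length(fams)))
  invisible(x)
}

#' @export
length.calculator <- function(x) length(x$descriptors)

#' @export
names.calculator <- function(x) vapply(x$descriptors, function(d) d$name, "")

#' Register descriptors on a calculator
#'
#' Descriptors are appended in registration order, which is also the order of
#' every [calculate()] result. A family name string registers the family's
#' [preset()]; a list registers each element.
#'
#' @param calc a [calculator()].
#' @param item a [descriptor()], a family name, or a list of either.
#' @return The updated calculator.
#' @export
register <- function(calc, item) {
  stopifnot(inherits(calc, "calculator"))
  if (inherits(item, "descriptor")) {
    existing <- names(calc)
    if (item$name %in% existing)
      stop("descriptor '", item$name, "' is already registered")
    calc$descriptors[[length(calc$descriptors) + 1L]] <- item
    return(calc)
  }
  if (is.character(item) && length(item) == 1L) {
    return(register(calc, preset(item)))
  }
  if (is.list(item)) {
    for (d in item) calc <- register(calc, d)
    return(calc)
  }
  stop("cannot register object of class ", paste(class(item), collapse = "/"))
}

#' Calculate all registered descriptors for one molecule
#'
#' Every registered descriptor is evaluated exactly once; shared
#' intermediates (distance matrix, delta vectors, subgraph enumerations, ...)
#' are computed once per molecule and cached for its duration. Failures are
#' contained as [missing_value()] entries -- no error escapes unless
#' `strict = TRUE`.
#'
#' @param calc a [calculator()].
#' @param mol a [mol_graph()]; preprocessed internally with `policy`.
#' @param policy a [preprocess_policy()] applied before evaluation.
#' @param strict raise the first failure as an error instead of containing it
#'   (debugging aid).
#' @param cache enable the per-molecule dependency cache (disabling it never
#'   changes any value, only the cost).
#' @return A `result_set` in registration order; see [as_mapping()],
#'   [fill_missing()], [drop_missing()].
#' @export
calculate <- function(calc, mol, policy = preprocess_policy(),
                      strict = FALSE, cache = TRUE) {
  stopifnot(inherits(calc, "calculator"), inherits(mol, "mol_graph"))
  nms <- names(calc)
  if (is_parse_failure(mol)) {
    vals <- lapply(nms, function(nm)
      missing_value("parse_failure", attr(mol, "parse_message") %||% "unparseable record", nm))
    names(vals) <- nms
    return(new_result_set(mol$name, vals))
  }
  pm <- tryCatch(preprocess(mol, policy), error = function(e) e)
  if (inherits(pm, "error")) {
    vals <- lapply(nms, function(nm)
      missing_value("empty_graph", conditionMessage(pm), nm))
    names(vals) <- nms
    return(new_result_set(mol$name, vals))
  }
  ctx <- new_eval_context(cache = cache)
  ctx$mol <- pm
  vals <- vector("list", length(nms))
  names(vals) <- nms
  for (k in seq_along(calc$descriptors)) {
    d <- calc$descriptors[[k]]
    v <- tryCatch(
      eval_descriptor(d, pm, ctx),
      topodesc_missing = function(e) e$mv,
      error = function(e) missing_value("dependency_failure", conditionMessage(e))
    )
    if (is_missing(v)) {
      if (is.na(v$descriptor) || !nzchar(v$descriptor)) v$descriptor <- d$name
      if (strict) stop("descriptor '", d$name, "' failed: ", v$reason,
                       " (", v$message, ")")
    }
    vals[[k]] <- v
  }
  rs <- new_result_set(pm$name, vals)
  attr(rs, "metadata") <- list(
    aromaticity_model = attr(pm, "aromaticity_model"),
    n_heavy_atoms = n_atoms(pm)
  )
  rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calculate descriptors for many molecules, optionally in parallel
#'
#' Molecules are distributed over `processes` worker processes (fork-based;
#' serial fallback where forking is unavailable) in chunks of
#' `ceiling(n / (4 * processes))`. Output order always equals input order and
#' results are identical to a serial run; a failure on one molecule yields an
#' all-missing row for that molecule only.
#'
#' @param calc a [calculator()].
#' @param mols list of [mol_graph()] objects.
#' @param processes integer >= 1.
#' @inheritParams calculate
#' @return List of `result_set` objects, one per molecule, in input order.
#' @export
map_parallel <- function(calc, mols, processes = 1L,
                         policy = preprocess_policy()) {
  stopifnot(processes >= 1L)
  one <- function(m) {
    tryCatch(calculate(calc, m, policy = policy),
             error = function(e) {
               nms <- names(calc)
               vals <- lapply(nms, function(nm)
                 missing_value("dependency_failure", conditionMessage(e), nm))
               names(vals) <- nms
               new_result_set(m$name, vals)
             })
  }
  n <- length(mols)
  if (n == 0L) return(list())
  if (processes == 1L || .Platform$OS.type != "unix") {
    return(lapply(mols, one))
  }
  chunk_size <- max(1L, ceiling(n / (4L * processes)))
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  res_chunks <- parallel::mclapply(chunks, function(idx) lapply(mols[idx], one),
                                   mc.cores = processes, mc.preschedule = TRUE)
  out <- vector("list", n)
  for (ci in seq_along(chunks)) out[chunks[[ci]]] <- res_chunks[[ci]]
  out
}

# ---- presets ----------------------------------------------------------------

#' Family presets
#'
#' Each descriptor family ships a preset: its default, ordered list of
#' descriptor instances. Parameter overrides extend ranges without touching
#' source (e.g. `preset("RingCount", max_n = 16)` adds 13- to 16-membered
#' ring counters for macrolide work).
#'
#' @param family family name; see `preset_families()`.
#' @param ... family-specific overrides (`RingCount`: `max_n`).
#' @return List of [descriptor()] objects.
#' @export
preset <- function(family, ...) {
  reg <- preset_registry()
  fn <- reg[[family]]
  if (is.null(fn)) stop("unknown descriptor family: ", family,
                        " (known: ", paste(names(reg), collapse = ", "), ")")
  fn(...)
}

#' @rdname preset
#' @export
preset_families <- function() names(preset_registry())

#' Calculator with every in-scope family registered
#'
#' @param ring_max_n largest ring size counted by the RingCount family
#'   (>= 12).
#' @return A [calculator()] with all families in their canonical order.
#' @export
full_calculator <- function(ring_max_n = 12L) {
  calc <- calculator()
  for (fam in preset_families()) {
    items <- if (fam == "RingCount") preset(fam, max_n = ring_max_n) else preset(fam)
    calc <- register(calc, items)
  }
  calc
}
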