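#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes.
ce_abort <- function(msg, class = "clonexpr_error", call. = FALSE) {
  stop(structure(
    class = c(class, "clonexpr_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ce_warn <- function(msg, class = "clonexpr_warning") {
  warning(structure(
    class = c(class, "clonexpr_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

vcapply <- function(X, FUN, ...) vapply(X, FUN, character(1L), ...)
vnapply <- function(X, FUN, ...) vapply(X, FUN, numeric(1L), ...)
viapply <- function(X, FUN, ...) vapply(X, FUN, integer(1L), ...)
vlapply <- function(X, FUN, ...) vapply(X, FUN, logical(1L), ...)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Deterministic sub-seed derivation (32-bit safe) so per-patient random
# streams do not shift when unrelated patients are added.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483629) + 1L
}

stopifnot_fraction <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    ce_abort(sprintf("`%s` must be a single value in [0, 1], got %s", name,
                     paste(format(x), collapse = ", ")),
             class = "clonexpr_config_error")
  }
  invisible(x)
}

benjamini_hochberg <- function(p) stats::p.adjust(p, method = "BH")
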