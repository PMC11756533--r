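# Typed error helpers.  All user-facing argument problems raise conditions of
# class "qens_invalid_parameter" (or a more specific class) so that callers
# and tests can distinguish them from genuine runtime failures.

abort_invalid <- function(msg, class = "qens_invalid_parameter") {
  rlang::abort(msg, class = class)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_invalid(sprintf("`%s` must be finite and > 0", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_invalid(sprintf("`%s` must be finite and >= 0", name))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_invalid(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# Resolve a per-q quantity given either a scalar, a function of q, or a
# vector named by q (names matched to within 1e-8).
value_at_q <- function(x, q, name = deparse(substitute(x))) {
  if (is.function(x)) return(x(q))
  if (length(x) == 1L && is.null(names(x))) return(as.numeric(x))
  if (!is.null(names(x))) {
    qs <- as.numeric(names(x))
    i <- which(abs(qs - q) < 1e-8)
    if (length(i) == 1L) return(as.numeric(x[[i]]))
  }
  abort_invalid(sprintf("cannot resolve `%s` at q = %g", name, q))
}
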