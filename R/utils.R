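# Internal helpers shared across modules.

stop_classed <- function(msg, base_class, class = NULL) {
  rlang::abort(msg, class = c(class, base_class, "neolaminar_error"))
}

stop_domain <- function(msg, class = NULL) {
  stop_classed(msg, "neolaminar_domain_error", class)
}

stop_contract <- function(msg, class = NULL) {
  stop_classed(msg, "neolaminar_contract_error", class)
}

stop_geometry <- function(msg, class = NULL) {
  stop_classed(msg, "neolaminar_geometry_error", class)
}

stop_format <- function(msg, class = NULL) {
  stop_classed(msg, "neolaminar_format_error", class)
}

stop_parameter <- function(msg, class = NULL) {
  stop_classed(msg, "neolaminar_parameter_error", class)
}

# Seeds derived from a master seed must stay below 2^31 - 1 (R integers).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
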