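# Classed conditions so callers (and tests) can distinguish failure modes.

mf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "memforce_error"), call = call))
}

stop_invalid <- function(msg) mf_stop(msg, "memforce_invalid_input")

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_invalid(sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_invalid(sprintf("`%s` must be TRUE or FALSE", name))
  invisible(x)
}

# Seeds derived from a master seed must stay valid 32-bit R integers.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
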