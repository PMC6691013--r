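# Internal helpers: seeded streams, argument checks.

# Derive a per-operation RNG seed from (seed, op-name) so each generator draws
# from its own reproducible stream regardless of call order.
stream_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.integer(seed)) %% 2147483647 + h) %% 2147483647)
}

with_stream <- function(seed, op, code) {
  withr::with_seed(stream_seed(seed, op), code)
}

stop_data <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_data(sprintf("`%s` must be a finite numeric scalar", name))
  ok_lo <- if (closed_lower) x >= lower else x > lower
  ok_hi <- if (closed_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi)
    stop_data(sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

synthetic_truth <- function(parameters, seed) {
  structure(list(parameters = parameters, seed = seed),
            class = "synthetic_truth")
}
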