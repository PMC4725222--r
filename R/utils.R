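# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_gwaset <- function(msg, class = "gwaset_error") {
  rlang::abort(msg, class = class)
}

# all stochastic code runs under an explicit seed; no function touches the
# global RNG state outside withr::with_seed
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_gwaset(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_range <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 2L && !anyNA(x) && x[1] <= x[2] &&
    (if (lo_open) all(x > lo) else all(x >= lo)) &&
    (if (hi_open) all(x < hi) else all(x <= hi))
  if (!ok) abort_gwaset(sprintf("`%s` must be a length-2 numeric range within the allowed bounds", name))
  as.numeric(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) abort_gwaset(sprintf("`%s` must be a probability in the allowed interval", name))
  as.numeric(x)
}

# smallest p-value reported anywhere downstream; keeps -log10 and the
# chi-square conversion finite
P_FLOOR <- 1e-300

clamp_p <- function(p) pmin(pmax(p, P_FLOOR), 1)
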