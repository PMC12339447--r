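#' @keywords internal
"_PACKAGE"

# Condition helpers: classed errors so the CLI can map them to exit codes.
rt_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rt_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

config_error <- function(msg) rt_error(msg, "rt_config_error")
data_error   <- function(msg) rt_error(msg, "rt_data_error")
train_error  <- function(msg) rt_error(msg, "rt_train_error")

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic generators do not disturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    config_error("`seed` must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream indices, staying within
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + 1234567 + as.double(i)) %% 2147483647
  as.integer(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmax/pmin keep x's dims

stopifnot_prob_vector <- function(p, what = "proportions") {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    config_error(sprintf("%s must be nonnegative and sum to 1", what))
  invisible(TRUE)
}

# Largest-remainder apportionment of n items into proportions p, with the
# leftover units going to the bins in order of decreasing fractional part
# (ties broken by bin order).
largest_remainder <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
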