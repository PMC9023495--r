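#' @useDynLib compressnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils head write.table read.delim
NULL

# Classed errors: config (bad user settings), input (bad data), spec
# (inconsistent network description), internal (assertion failures).
cn_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(paste0("cn_", class, "_error"), "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

cn_assert <- function(cond, class, fmt, ...) {
  if (!isTRUE(cond)) cn_stop(class, fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Evaluate `code` with the global RNG temporarily seeded; the caller's RNG
# state is restored afterwards so library code never perturbs user streams.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label; stays inside the
# 32-bit signed range R's set.seed() accepts.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483629
  as.integer(h) + 1L
}

round_half_up <- function(x) floor(x + 0.5)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
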