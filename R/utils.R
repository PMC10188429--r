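# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Cheap content fingerprint used in stage logs (dims + sum + extrema).
content_digest <- function(x) {
  v <- as.numeric(x)
  sprintf("[%s] sum=%.10e min=%.6e max=%.6e",
          paste(if (is.matrix(x)) dim(x) else length(v), collapse = "x"),
          sum(v), min(v), max(v))
}

log_stage <- function(stage, ..., verbose = getOption("eegvit.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[eegvit:%s] %s", stage, paste0(..., collapse = " ")))
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(TRUE)
}
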