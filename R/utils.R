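# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
# seed = NULL means "use the current stream" (no-op wrapper).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_ccfd <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ccfd_error")))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x)
  if (ok) {
    ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  }
  if (!ok) {
    stop_ccfd(sprintf("`%s` must be a single finite number in %s%s, %s%s",
                      name, if (strict) "(" else "[", lower, upper,
                      if (strict) ")" else "]"),
              "ccfd_invalid_argument")
  }
  invisible(x)
}
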