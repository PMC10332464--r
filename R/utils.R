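`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                          integer = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop(sprintf("'%s' must be a numeric of length %d", name, len),
         call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && any(x < 0)) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  if (integer && any(x != as.integer(x))) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# seed scoping: run `expr` under a fixed RNG seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
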