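#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded package functions do not disturb the
#' caller's random number stream. With `seed = NULL` the expression runs on
#' the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # touch the stream so there is a state to save
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic map (master seed, stage label) -> integer seed, kept well
#' below .Machine$integer.max so derived seeds remain valid R seeds.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label.
#' @return Integer seed.
#' @keywords internal
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483399) + 1L
}

# circular absolute difference between angles in degrees, result in [0, 180]
ang_dist <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
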