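#' @useDynLib chromexpr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is as
#' @importFrom stats rnorm runif rbeta rpois rbinom predict cor dnorm pnorm sd var
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one master seed through named
#' substreams so that individual stages (sequence sampling, motif placement,
#' weight initialization, batch shuffling, ...) are independently
#' reproducible. The derived value is always a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param ... stream name components (characters or integers), e.g.
#'   `derive_seed(7, "fold", 3)`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- as.double(master %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded internals do not
#' disturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

cx_log <- function(...) {
  if (isTRUE(getOption("chromexpr.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
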