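`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_(...)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == trunc(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Seed a generator stream
#'
#' All randomness in the synthetic-data generators flows from a single integer
#' seed; each output gets its own documented stream so that regenerating one
#' stage never perturbs another.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return invisibly, the derived integer seed that was set.
#' @keywords internal
seed_stream <- function(seed, stream) {
  offs <- c(annotation = 11L, fragmap = 23L, chip = 37L, nascent = 53L,
            capture = 71L, ra = 89L, truth = 97L, misc = 101L)
  o <- offs[[match.arg(stream, names(offs))]]
  derived <- (as.integer(seed) %% 1000000L) * 1009L + o
  set.seed(derived)
  invisible(derived)
}

#' Round half up to a fixed number of decimals
#' @keywords internal
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Truncate (round toward zero) to a fixed number of decimals
#' @keywords internal
trunc_decimal <- function(x, digits = 1L) {
  p <- 10^digits
  trunc(x * p) / p
}
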