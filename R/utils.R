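# Internal helpers shared across modules.

#' Round half away from zero to the nearest integer
#'
#' Unlike [round()], ties (x.5) move away from zero, the convention used for
#' staple-food portion weights.
#' @noRd
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Round to 2 decimals, half to even, in decimal arithmetic
#'
#' Works on the decimal representation of `x` (after clearing binary
#' floating-point residue at the 6th decimal of 100*x) so that e.g.
#' 106.785 -> 106.78 and 0.778 -> 0.78.
#' @noRd
round2_half_even <- function(x) {
  s <- round(x * 100, 6)            # clear float residue, keep true ties
  f <- floor(s)
  r <- s - f
  tie <- abs(r - 0.5) < 1e-9
  out <- ifelse(tie, ifelse(f %% 2 == 0, f, f + 1), round(s))
  out / 100
}

#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the seed if non-NULL and restores the caller's RNG state on exit, so
#' seeded package functions do not disturb the session's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' Children are drawn from the master stream and kept strictly below 2^31 so
#' they remain valid R integer seeds.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
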