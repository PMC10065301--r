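# Small numerical helpers shared across the package.

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the
#' convention used for all printed area and percentage figures), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 guard keeps decimal ties (e.g. 2.675) from falling just below
  # .5 through binary representation
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a percentage the way area tables print it
#'
#' Two decimals, half away from zero, with the second decimal dropped when
#' zero (58.15 but 29.3).
#'
#' @param x numeric vector
#' @return character vector
#' @export
format_percent <- function(x) {
  r <- round_half_away(x, 2)
  vapply(r, function(v) {
    s <- formatC(v, format = "f", digits = 2)
    sub("0$", "", s)
  }, character(1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a stream of child seeds from one master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
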