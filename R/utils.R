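#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Presentation rounding used in reported tables: exact halves round up
#' (2.345 -> 2.35), unlike base \code{round()}'s round-half-even. Applied only
#' at reporting time; all internal ratios are kept at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(7.875)   # 7.88
#' roundHalfUp(11.0749) # 11.07
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stable order: by score descending, ties by ascending id
.orderByScoreThenId <- function(score, id) order(-score, id)
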