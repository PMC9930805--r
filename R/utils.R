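#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data :=
#' @importFrom stats approx lm coef pnorm pt qt rnorm runif sd t.test ks.test
#'   predict var
#' @importFrom utils head tail
NULL

# Round half-up at `digits` decimals. Base round() uses round-half-even and is
# also at the mercy of binary representation (round(7.005, 2) == 7); age-group
# binning needs the decimal convention, so nudge by a scale-relative epsilon
# before flooring.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-6) / p
}

# Temporarily seed the session RNG; restores (or clears) the previous state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_dentalage <- function(message, class, ...) {
  abort(message, class = c(class, "dentalage_error"), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
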