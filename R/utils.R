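#' Evaluate an expression under a local, seeded RNG
#'
#' All stochastic operations in the package route their randomness through
#' this helper: the global RNG state is saved, the seed applied, and the
#' previous state restored on exit, so no function leaves global side effects
#' and identical seeds give identical results.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  expr
}

#' Geometric mean of positive values
#' @param x positive numeric vector.
#' @return scalar geometric mean, computed in log space.
#' @keywords internal
geomean <- function(x) {
  if (any(!is.finite(x) | x <= 0)) {
    abort("geometric mean requires positive finite values", class = "plasmonet_data_error")
  }
  exp(mean(log(x)))
}

abort_data <- function(msg) abort(msg, class = "plasmonet_data_error")
abort_arg <- function(msg) abort(msg, class = "plasmonet_argument_error")
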