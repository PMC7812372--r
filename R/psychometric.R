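#' Logistic psychometric function
#'
#' Constructs the psychometric-function family used throughout the package:
#' as the generative observer in simulations, as the likelihood inside the
#' UML adaptive procedure, and as the target of post-hoc MCMC refits. The
#' probability of a correct response at stimulus value `x` is
#'
#' \deqn{p(x) = \gamma + (1 - \gamma - \lambda) \, [1 + e^{-\beta (x - \alpha)}]^{-1}}
#'
#' where `alpha` is the midpoint, `beta > 0` the slope, `gamma` the guess
#' rate (fixed at the reciprocal of the number of response alternatives in
#' a forced-choice task) and `lambda` the lapse rate, which lowers only the
#' upper asymptote. `scale` declares the stimulus axis on which `alpha` and
#' `beta` live: tasks tracked on a ratio-like dimension (frequency or F0
#' difference, IPD) operate on `log` stimulus values, level-like dimensions
#' (AM depth in dB, SNR in dB) on `linear` values. A function declared on
#' the log scale expects already-logged stimulus values.
#'
#' @param midpoint Midpoint `alpha`, in stimulus units on the declared scale.
#' @param slope Slope `beta`, in inverse stimulus units; must be positive.
#' @param guess Guess rate `gamma` in `[0, 1]`.
#' @param lapse Lapse rate `lambda` in `[0, 1)`; `guess + lapse < 1`.
#' @param scale `"linear"` or `"log"`; a declaration of the stimulus axis.
#' @return An object of class `psyfun`.
#' @examples
#' pf <- psyfun(midpoint = -20, slope = 0.5, guess = 1/3)
#' prob_correct(pf, -20)  # halfway between guess and ceiling
#' @export
psyfun <- function(midpoint, slope, guess = 0.5, lapse = 0,
                   scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.finite(midpoint), is.finite(slope), is.finite(guess),
            is.finite(lapse))
  if (slope <= 0) stop("slope must be positive")
  if (guess < 0 || guess > 1) stop("guess rate must lie in [0, 1]")
  if (lapse < 0 || lapse >= 1) stop("lapse rate must lie in [0, 1)")
  if (guess + lapse >= 1) stop("guess + lapse must be < 1")
  structure(list(midpoint = midpoint, slope = slope, guess = guess,
                 lapse = lapse, scale = scale),
            class = "psyfun")
}

#' @export
print.psyfun <- function(x, ...) {
  cat(sprintf(
    "Logistic psychometric function (%s stimulus scale)\n  midpoint %.4g  slope %.4g  guess %.3g  lapse %.3g\n",
    x$scale, x$midpoint, x$slope, x$guess, x$lapse))
  invisible(x)
}

#' Probability of a correct response
#'
#' Evaluates the psychometric function at one or more stimulus values on
#' its declared scale. Strictly increasing in `x` and bounded in
#' `[guess, 1 - lapse]`.
#'
#' @param pf A [psyfun] object.
#' @param x Numeric vector of stimulus values (already on `pf$scale`).
#' @return Vector of probabilities.
#' @export
prob_correct <- function(pf, x) {
  stopifnot(inherits(pf, "psyfun"))
  if (any(!is.finite(x))) stop("non-finite stimulus value")
  F <- stats::plogis(pf$slope * (x - pf$midpoint))
  pf$guess + (1 - pf$guess - pf$lapse) * F
}

#' Stimulus value attaining a criterion performance
#'
#' Inverts the psychometric function. The criterion can be given either as
#' a `fraction` of the function's dynamic range (the point where the
#' underlying logistic equals that fraction; `fraction = 1/2` returns the
#' midpoint exactly, and `fraction = 1/4` is the "1/4 point" used in
#' sensitivity re-analyses of speech-reception thresholds, ~25% correct
#' only for a zero-guess observer), or as a raw `performance` level on the
#' probability-correct scale, which must lie strictly inside
#' `(guess, 1 - lapse)`.
#'
#' @param pf A [psyfun] object.
#' @param fraction Fraction of dynamic range in (0, 1). Default `0.5`.
#' @param performance Probability-correct criterion; overrides `fraction`.
#' @return Stimulus value on the declared scale.
#' @export
threshold_at_p <- function(pf, fraction = 0.5, performance = NULL) {
  stopifnot(inherits(pf, "psyfun"))
  if (!is.null(performance)) {
    lo <- pf$guess
    hi <- 1 - pf$lapse
    if (any(performance <= lo | performance >= hi))
      stop(sprintf(
        "performance criterion must lie strictly inside (%.4g, %.4g)",
        lo, hi))
    fraction <- (performance - lo) / (1 - lo - pf$lapse)
  }
  if (any(fraction <= 0 | fraction >= 1))
    stop("fraction of dynamic range must lie strictly inside (0, 1)")
  pf$midpoint + stats::qlogis(fraction) / pf$slope
}

#' Simulate a Bernoulli response from an observer
#'
#' @param pf A [psyfun] observer.
#' @param x Stimulus value(s) on the declared scale.
#' @return Logical vector: correct/incorrect.
#' @export
simulate_response <- function(pf, x) {
  stats::runif(length(x)) < prob_correct(pf, x)
}
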