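#' Simulate a transformed up-down adaptive staircase
#'
#' Classical n-down 1-up staircase of the kind used for forced-choice
#' audiometry: the level drops by one step only after `down` consecutive
#' correct responses and rises after any incorrect response. With
#' `down = 2` the procedure converges on the stimulus level at which the
#' probability of a correct response is `0.5^(1/2) = 0.707` (Levitt's
#' 70.7% point); with `down = 1` on the 50% point. The track runs with a
#' larger initial step until `n_reversals_initial` reversals have
#' occurred, then switches to the final step size for the measurement
#' phase; the threshold estimate is the mean of the measurement-phase
#' reversal levels.
#'
#' Step sizes and reversal counts are procedure configuration; the
#' defaults are typical values for a 2I-2AFC audiometric track.
#'
#' @param observer A [psyfun] with positive slope; responses are drawn
#'   Bernoulli from it.
#' @param start_level Starting level (observer stimulus units).
#' @param step_initial,step_final Step sizes (> 0) for the initial and
#'   measurement phases.
#' @param n_reversals_initial Reversals run at the initial step size.
#' @param n_reversals_measurement Measurement-phase reversals averaged
#'   for the threshold estimate.
#' @param down Number of consecutive correct responses required to
#'   decrease the level (default 2).
#' @param min_level,max_level Optional clamps on the presented level.
#' @param max_trials Safety cap on trial count.
#' @return An object of class `staircase_track`: list with `levels`,
#'   `responses`, `reversal_levels`, `reversal_trials`,
#'   `measurement_reversals`, `threshold` and `n_trials`.
#' @export
staircase_run <- function(observer, start_level,
                          step_initial = 4, step_final = 2,
                          n_reversals_initial = 4,
                          n_reversals_measurement = 12,
                          down = 2, min_level = -Inf, max_level = Inf,
                          max_trials = 1000) {
  stopifnot(inherits(observer, "psyfun"), step_initial > 0,
            step_final > 0, down >= 1, n_reversals_measurement >= 1)
  if (observer$slope <= 0) stop("observer slope must be positive")
  level <- start_level
  cc <- 0L
  direction <- 0L  # -1 going down, +1 going up, 0 before first move
  levels <- responses <- numeric(0)
  rev_levels <- rev_trials <- numeric(0)
  n_rev_total <- n_reversals_initial + n_reversals_measurement
  trial <- 0L
  while (length(rev_levels) < n_rev_total && trial < max_trials) {
    trial <- trial + 1L
    levels[trial] <- level
    r <- simulate_response(observer, level)
    responses[trial] <- r
    step <- if (length(rev_levels) < n_reversals_initial)
      step_initial else step_final
    move <- 0L
    if (r) {
      cc <- cc + 1L
      if (cc >= down) {
        move <- -1L
        cc <- 0L
      }
    } else {
      move <- +1L
      cc <- 0L
    }
    if (move != 0L) {
      if (direction != 0L && move != direction) {
        rev_levels <- c(rev_levels, level)
        rev_trials <- c(rev_trials, trial)
      }
      direction <- move
      level <- min(max(level + move * step, min_level), max_level)
    }
  }
  meas <- rev_levels[seq_along(rev_levels) > n_reversals_initial]
  structure(list(levels = levels, responses = as.logical(responses),
                 reversal_levels = rev_levels,
                 reversal_trials = rev_trials,
                 measurement_reversals = meas,
                 threshold = mean(meas), n_trials = trial),
            class = "staircase_track")
}

#' @export
print.staircase_track <- function(x, ...) {
  cat(sprintf(
    "Up-down staircase: %d trials, %d reversals, threshold %.3f (mean of %d measurement reversals)\n",
    x$n_trials, length(x$reversal_levels), x$threshold,
    length(x$measurement_reversals)))
  invisible(x)
}

#' Equilibrium performance of repeated staircase tracks
#'
#' Convenience used by validation suites: simulates `n_tracks` staircase
#' replicates on a known observer and evaluates the observer's
#' psychometric function at the grand-mean threshold estimate, returning
#' the tracked percent-correct level.
#'
#' @param observer A [psyfun].
#' @param n_tracks Number of replicate tracks.
#' @param ... Passed to [staircase_run].
#' @return List with `thresholds` (per track), `grand_mean`,
#'   `percent_correct` at the grand mean, and `n_trials` pooled across
#'   tracks.
#' @export
staircase_equilibrium <- function(observer, n_tracks = 1000, ...) {
  tracks <- lapply(seq_len(n_tracks), function(i)
    staircase_run(observer, ...))
  th <- vapply(tracks, `[[`, numeric(1), "threshold")
  nt <- sum(vapply(tracks, `[[`, numeric(1), "n_trials"))
  gm <- mean(th)
  list(thresholds = th, grand_mean = gm,
       percent_correct = 100 * prob_correct(observer, gm),
       n_trials = nt)
}
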