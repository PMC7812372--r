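#' Initialize an updated maximum-likelihood (UML) adaptive track
#'
#' The UML procedure maintains a discrete-grid posterior over the three
#' free parameters of the observer's logistic psychometric function
#' (midpoint `alpha`, slope `beta`, lapse `lambda`; the guess rate is
#' fixed by the number of response alternatives). The posterior starts at
#' the experimenter-defined prior and is updated after every response;
#' each trial's stimulus is placed at one of four "sweetpoints" that
#' minimize the expected estimation variance of the parameters, chosen by
#' a 2-down 1-up selection rule.
#'
#' @param prior Either a parametric prior specification — a list with
#'   elements `midpoint = c(mean, sd)` (Normal on the task's stimulus
#'   axis), `slope = c(shape, rate)` (gamma), `lapse = c(shape, rate)`
#'   (gamma, truncated to the lapse grid) — or a list of three numeric
#'   vectors `alpha`, `beta`, `lambda` of prior densities matching the
#'   grids.
#' @param grids List of strictly increasing numeric vectors `alpha`,
#'   `beta`, `lambda` discretizing the parameter space.
#' @param bounds Length-2 numeric: minimum and maximum presentable
#'   stimulus on the task axis (e.g. an AM-depth cap of 0 dB, an IPD cap
#'   of log10(180)).
#' @param start First stimulus to present (e.g. 100% AM depth, a 10%
#'   frequency difference, a 180-degree IPD).
#' @param guess Fixed guess rate.
#' @return An object of class `uml` holding the grids, normalized
#'   log-posterior, bounds, sweetpoint selection state and trial history.
#' @seealso [uml_update], [uml_sweetpoints], [uml_next_stimulus], [uml_run]
#' @export
uml_init <- function(prior, grids, bounds, start, guess) {
  stopifnot(is.list(grids), all(c("alpha", "beta", "lambda") %in%
                                  names(grids)))
  for (g in grids[c("alpha", "beta", "lambda")]) {
    if (length(g) < 1 || any(!is.finite(g)))
      stop("grids must be non-empty and finite")
    if (length(g) > 1 && any(diff(g) <= 0))
      stop("grids must be strictly increasing")
  }
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2],
            is.finite(start), start >= bounds[1], start <= bounds[2],
            guess >= 0, guess < 1)
  if (!is.null(prior$midpoint)) {
    la <- stats::dnorm(grids$alpha, prior$midpoint[["mean"]],
                       prior$midpoint[["sd"]], log = TRUE)
    lb <- stats::dgamma(grids$beta, shape = prior$slope[["shape"]],
                        rate = prior$slope[["rate"]], log = TRUE)
    ll <- stats::dgamma(grids$lambda, shape = prior$lapse[["shape"]],
                        rate = prior$lapse[["rate"]], log = TRUE)
    # a gamma density is -Inf at 0 for shape > 1; keep a proper atom there
    ll[grids$lambda == 0 & !is.finite(ll)] <- min(ll[is.finite(ll)],
                                                  0) - 10
  } else {
    stopifnot(all(c("alpha", "beta", "lambda") %in% names(prior)))
    if (any(unlist(prior[c("alpha", "beta", "lambda")]) < 0))
      stop("prior densities must be non-negative")
    la <- log(prior$alpha)
    lb <- log(prior$beta)
    ll <- log(prior$lambda)
  }
  lp <- outer(outer(la, lb, "+"), ll, "+")
  if (all(!is.finite(lp))) stop("prior has zero mass everywhere on the grid")
  lp <- lp - .logsumexp(lp)
  structure(list(grids = grids, log_post = lp, guess = guess,
                 bounds = bounds, start = start,
                 history = data.frame(stimulus = numeric(0),
                                      response = logical(0),
                                      sweetpoint_index = integer(0)),
                 consecutive_correct = 0L, sweet_index = 4L),
            class = "uml")
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Grid log-likelihood of one response (internal)
#'
#' @return Array over the (alpha, beta, lambda) grid.
#' @noRd
.uml_loglik <- function(grids, guess, stimulus, response) {
  F <- stats::plogis(outer(stimulus - grids$alpha, grids$beta))
  out <- array(0, dim = c(length(grids$alpha), length(grids$beta),
                          length(grids$lambda)))
  for (k in seq_along(grids$lambda)) {
    p <- guess + (1 - guess - grids$lambda[k]) * F
    out[, , k] <- if (response) log(p) else log1p(-p)
  }
  out
}

#' Update a UML track with one trial
#'
#' Performs the Bayes update of the grid posterior with the Bernoulli
#' likelihood of the observed response, appends the trial to the history,
#' and advances the 2-down 1-up sweetpoint selection rule: after two
#' consecutive correct responses the selection moves one sweetpoint down
#' (towards lower stimulus values), after any incorrect response one
#' sweetpoint up, clamped to the four available sweetpoints.
#'
#' @param state A `uml` object.
#' @param stimulus The stimulus that was presented (within bounds).
#' @param response Logical: was the response correct?
#' @return The updated `uml` object.
#' @export
uml_update <- function(state, stimulus, response) {
  stopifnot(inherits(state, "uml"), is.logical(response),
            length(response) == 1)
  if (!is.finite(stimulus)) stop("non-finite stimulus")
  if (stimulus < state$bounds[1] - 1e-9 ||
      stimulus > state$bounds[2] + 1e-9)
    stop("stimulus outside task bounds")
  lp <- state$log_post +
    .uml_loglik(state$grids, state$guess, stimulus, response)
  state$log_post <- lp - .logsumexp(lp)
  state$history <- rbind(state$history,
                         data.frame(stimulus = stimulus,
                                    response = response,
                                    sweetpoint_index = state$sweet_index))
  if (response) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      state$sweet_index <- max(1L, state$sweet_index - 1L)
      state$consecutive_correct <- 0L
    }
  } else {
    state$sweet_index <- min(4L, state$sweet_index + 1L)
    state$consecutive_correct <- 0L
  }
  state
}

#' Posterior summaries of a UML track
#'
#' @param state A `uml` object.
#' @return Named vector of posterior means `(alpha, beta, lambda)`.
#' @export
uml_estimate <- function(state) {
  stopifnot(inherits(state, "uml"))
  w <- exp(state$log_post - max(state$log_post))
  w <- w / sum(w)
  g <- state$grids
  c(alpha = sum(apply(w, 1, sum) * g$alpha),
    beta = sum(apply(w, 2, sum) * g$beta),
    lambda = sum(apply(w, 3, sum) * g$lambda))
}

#' Compute the four UML sweetpoints
#'
#' Given the current posterior-mean parameter estimate, each sweetpoint
#' is the stimulus value minimizing the asymptotic variance proxy
#' `p(x)(1 - p(x)) / (dp/dtheta)^2` of one parameter's estimator: one
#' sweetpoint for the midpoint, two for the slope (one on either side of
#' the midpoint, where the derivative with respect to the slope vanishes),
#' and one high-performance point for the lapse rate (the variance proxy
#' for the lapse decreases monotonically with performance, so it sits at
#' the upper stimulus bound). Minimization is numerical, over a dense
#' lattice spanning the task bounds; all points are clipped to bounds and
#' returned sorted ascending.
#'
#' @param state A `uml` object.
#' @param n_lattice Lattice resolution (default 1001).
#' @return Sorted numeric vector of four stimulus values.
#' @export
uml_sweetpoints <- function(state, n_lattice = 1001) {
  stopifnot(inherits(state, "uml"))
  est <- uml_estimate(state)
  w <- exp(state$log_post - max(state$log_post))
  if (sum(w > 1e-12) == 1) {
    idx <- which(w > 1e-12, arr.ind = TRUE)[1, ]
    if (any(idx == 1L) || any(idx == dim(w)))
      warning("degenerate posterior concentrated at a grid edge; ",
              "sweetpoints clipped to bounds")
  }
  g <- state$guess
  a <- est[["alpha"]]
  b <- est[["beta"]]
  l <- est[["lambda"]]
  x <- seq(state$bounds[1], state$bounds[2], length.out = n_lattice)
  F <- stats::plogis(b * (x - a))
  dF <- F * (1 - F)
  psi <- g + (1 - g - l) * F
  num <- psi * (1 - psi)
  v_alpha <- num / ((1 - g - l) * b * dF)^2
  v_beta <- num / ((1 - g - l) * (x - a) * dF)^2
  v_lambda <- num / F^2
  sp_alpha <- x[which.min(v_alpha)]
  lo <- x < a
  hi <- x > a
  sp_beta_lo <- if (any(lo)) x[lo][which.min(v_beta[lo])] else x[1]
  sp_beta_hi <- if (any(hi)) x[hi][which.min(v_beta[hi])] else
    x[n_lattice]
  sp_lambda <- x[which.min(v_lambda)]
  sort(pmin(pmax(c(sp_beta_lo, sp_alpha, sp_beta_hi, sp_lambda),
                 state$bounds[1]), state$bounds[2]))
}

#' Next stimulus proposed by a UML track
#'
#' Before any trial has been run the starting stimulus is returned;
#' afterwards the sweetpoint currently selected by the 2-down 1-up rule.
#' The proposal always lies within the task bounds.
#'
#' @param state A `uml` object.
#' @return A single stimulus value.
#' @export
uml_next_stimulus <- function(state) {
  stopifnot(inherits(state, "uml"))
  if (nrow(state$history) == 0) return(state$start)
  uml_sweetpoints(state)[state$sweet_index]
}

#' Run a complete UML track against a simulated observer
#'
#' Simulates one adaptive block: on each trial the UML proposal is
#' presented, the observer's response is drawn Bernoulli from its
#' psychometric function, and the posterior is updated. A practice block,
#' if requested, is run first with its own throwaway UML state (its
#' trials are flagged `is_practice` and are not part of the returned
#' main-track posterior), mirroring how familiarization blocks are
#' excluded from analysis.
#'
#' @param observer A [psyfun] observer on the same stimulus axis.
#' @param config List with elements `prior`, `grids`, `bounds`, `start`
#'   (see [uml_init]); typically `task_spec(task)$uml` plus the task's
#'   `bounds`/`start`/`guess`.
#' @param n_trials Number of main trials (e.g. 160 = two blocks of 80).
#' @param n_practice Number of practice trials (default 0; 25 in the
#'   standard protocol).
#' @param guess Guess rate; defaults to the observer's.
#' @return A list with the final `state` and a data frame `log` with
#'   columns `trial_index`, `stimulus`, `response`, `sweetpoint_index`,
#'   `is_practice`.
#' @export
uml_run <- function(observer, config, n_trials, n_practice = 0,
                    guess = observer$guess) {
  run_block <- function(n) {
    st <- uml_init(config$prior, config$grids, config$bounds,
                   config$start, guess)
    stim <- resp <- numeric(n)
    spi <- integer(n)
    for (i in seq_len(n)) {
      x <- uml_next_stimulus(st)
      r <- simulate_response(observer, x)
      spi[i] <- st$sweet_index
      st <- uml_update(st, x, r)
      stim[i] <- x
      resp[i] <- r
    }
    list(state = st,
         log = data.frame(trial_index = seq_len(n), stimulus = stim,
                          response = as.logical(resp),
                          sweetpoint_index = spi))
  }
  logs <- NULL
  if (n_practice > 0) {
    pr <- run_block(n_practice)
    pr$log$is_practice <- TRUE
    logs <- pr$log
  }
  main <- run_block(n_trials)
  main$log$is_practice <- FALSE
  if (!is.null(logs)) {
    main$log$trial_index <- main$log$trial_index + n_practice
    logs <- rbind(logs, main$log)
  } else logs <- main$log
  list(state = main$state, log = logs)
}
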