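#' Total cumulative noise exposure (TCNE) units
#'
#' One unit of noise exposure corresponds to an eight-hour daily
#' exposure, five days a week, 52 weeks, for one year, at 90 dBA (2080
#' hours at 90 dBA). Exposure is summed across activities on an
#' equal-energy basis: each activity contributes
#' `(hours * days * weeks * years / 2080) * 10^((level - 90) / 10)`
#' units, so a +10 dBA level difference is a tenfold energy difference.
#'
#' @param level Numeric vector of activity noise levels in dBA.
#' @param hours_per_day,days_per_week,weeks_per_year,years Durations per
#'   activity; all must be non-negative.
#' @return Total exposure in TCNE units (scalar).
#' @examples
#' tcne_units(90, 8, 5, 52, 1)  # the reference exposure: exactly 1
#' @export
tcne_units <- function(level, hours_per_day, days_per_week,
                       weeks_per_year, years) {
  n <- length(level)
  stopifnot(all(is.finite(level)),
            length(hours_per_day) == n, length(days_per_week) == n,
            length(weeks_per_year) == n, length(years) == n)
  if (n == 0) stop("at least one activity record is required")
  dur <- cbind(hours_per_day, days_per_week, weeks_per_year, years)
  if (any(dur < 0)) stop("durations must be non-negative")
  sum(hours_per_day * days_per_week * weeks_per_year * years / 2080 *
        10^((level - 90) / 10))
}

#' Base-10 log of TCNE units
#'
#' A unit difference on this scale is a tenfold difference in noise
#' exposure energy.
#'
#' @param units Positive exposure in TCNE units.
#' @return `log10(units)`.
#' @export
log_tcne <- function(units) {
  if (any(!is.finite(units) | units <= 0))
    stop("TCNE units must be positive to take the base-10 log")
  log10(units)
}

#' Equal-temperament frequency arithmetic
#'
#' Frequency reached from a root by a number of 100-cent (semitone)
#' steps on the equal-temperament scale: `root * 2^(steps / 12)`. The
#' dyad-rating roots span D3 (146.83 Hz) to A3 (220 Hz), i.e. steps 0-7.
#'
#' @param root_hz Root frequency in Hz.
#' @param steps Number of 100-cent steps (may be fractional).
#' @return Frequency in Hz.
#' @export
et_frequency <- function(root_hz, steps) {
  stopifnot(all(is.finite(root_hz)), all(is.finite(steps)))
  root_hz * 2^(steps / 12)
}

#' Consonance preference from dyad pleasantness ratings
#'
#' Each listener rates the pleasantness (-3 to +3) of dyads forming
#' either a consonant perfect fifth (700 cents) or a dissonant tritone
#' (600 cents), over eight equal-temperament root notes and two dyad
#' levels. Ratings are z-scored within listener across all of that
#' listener's (non-practice) ratings, then averaged across root notes
#' within interval x level; consonance preference at each level is the
#' mean z for the perfect fifth minus the mean z for the tritone.
#'
#' @param ratings Data frame with columns `subject`, `interval` (values
#'   `"P5"`/`"TT"`), `dyad_level`, `root_f0`, `rating`, and optionally
#'   `is_practice` (practice rows are dropped).
#' @return A list with `preference` (data frame `subject`, `dyad_level`,
#'   `preference`) and `ratings_z` (per subject x interval x level mean
#'   z, averaged across roots, column `rating_z`). Listeners who give
#'   every dyad the same rating have no within-listener spread; their
#'   rows are returned as `NA` with a warning.
#' @export
consonance_preference <- function(ratings) {
  need <- c("subject", "interval", "dyad_level", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss))
    stop("ratings table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(ratings$interval %in% c("P5", "TT")))
    stop("interval must be 'P5' or 'TT'")
  if ("is_practice" %in% names(ratings))
    ratings <- ratings[!ratings$is_practice, , drop = FALSE]
  sd0 <- tapply(ratings$rating, ratings$subject, stats::sd)
  flat <- names(sd0)[!is.na(sd0) & sd0 == 0]
  if (length(flat))
    warning("zero rating variance for subject(s) ",
            paste(flat, collapse = ", "),
            "; their preference is undefined (NA)")
  z <- stats::ave(ratings$rating, ratings$subject,
                  FUN = function(r) (r - mean(r)) / stats::sd(r))
  zr <- stats::aggregate(
    list(rating_z = z),
    by = list(subject = ratings$subject, interval = ratings$interval,
              dyad_level = ratings$dyad_level),
    FUN = mean)
  p5 <- zr[zr$interval == "P5", ]
  tt <- zr[zr$interval == "TT", ]
  pref <- merge(p5[, c("subject", "dyad_level", "rating_z")],
                tt[, c("subject", "dyad_level", "rating_z")],
                by = c("subject", "dyad_level"),
                suffixes = c("_p5", "_tt"))
  pref$preference <- pref$rating_z_p5 - pref$rating_z_tt
  list(preference = pref[, c("subject", "dyad_level", "preference")],
       ratings_z = zr)
}

#' Principal components of cognitive test scores
#'
#' Standardizes each test score (sample mean, n-1 sample standard
#' deviation) and eigendecomposes the correlation matrix. Loadings are
#' oriented so that each component's largest-magnitude loading is
#' positive. The first two components are conventionally retained as
#' regression predictors.
#'
#' @param scores Numeric matrix or data frame, subjects x tests (no
#'   missing values).
#' @return An object of class `cognitive_pca`: list with `scores`
#'   (subjects x components), `loadings` (tests x components),
#'   `eigenvalues`, and `variance_fraction` (sums to 1).
#' @export
cognitive_pca <- function(scores) {
  X <- as.matrix(scores)
  if (anyNA(X)) stop("cognitive scores must have no missing values")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant test score column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  sc <- Z %*% L
  structure(list(scores = sc, loadings = L, eigenvalues = e$values,
                 variance_fraction = e$values / sum(e$values)),
            class = "cognitive_pca")
}

#' @export
print.cognitive_pca <- function(x, ...) {
  cat("Cognitive-score PCA\n  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cube-root transform for years of musical practice
#'
#' Years of musical practice are right skewed; a cube-root transform is
#' applied before analysis.
#'
#' @param years Non-negative years of practice.
#' @return `years^(1/3)`.
#' @export
music_transform <- function(years) {
  if (any(!is.finite(years) | years < 0))
    stop("years of musical practice must be non-negative")
  years^(1 / 3)
}

#' Mean SSQ12 score
#'
#' Self-reported hearing ability: the mean across the 12 questionnaire
#' items.
#'
#' @param items Numeric vector of 12 item scores, or a matrix/data frame
#'   with 12 columns (one row per respondent).
#' @return Scalar or per-row mean.
#' @export
ssq_mean <- function(items) {
  if (is.null(dim(items))) {
    stopifnot(length(items) == 12)
    return(mean(items))
  }
  stopifnot(ncol(items) == 12)
  rowMeans(as.matrix(items))
}
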