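#' Task and condition registry
#'
#' The test battery comprises five psychophysical tasks and two
#' speech-reception tasks, each run at a low and a high stimulus level.
#' `task_spec()` returns the parameters that define how a task's adaptive
#' track operates: the tracked stimulus dimension and its axis (`linear`
#' dB-like dimensions vs `log10`-transformed ratio-like dimensions), the
#' guess rate implied by the number of response alternatives, the starting
#' stimulus, the physical bounds of the stimulus dimension, the condition
#' grid, and default priors/grids for the UML procedure.
#'
#' Tracked dimensions and forced-choice structure:
#' \describe{
#'   \item{`am`}{AM-depth detection, 3I-3AFC (guess 1/3). Depth in dB
#'     (`20 log10 m`); start and cap at 0 dB (100% depth). Conditions:
#'     carrier level 40/80 dB SPL x modulation rate 25/50/100 Hz.}
#'   \item{`fd`}{Pure-tone frequency discrimination, 2I-2AFC. Percent
#'     frequency difference tracked as log10(%); start 10%, cap 99%.
#'     Conditions: frequency 0.6/2 kHz x level 40/80 dB SPL.}
#'   \item{`f0d`}{F0 discrimination for unresolved complex tones, 2I-2AFC.
#'     log10(% F0 difference); start 80%, cap 99%. Conditions: level
#'     40/80 dB SPL.}
#'   \item{`ipd_mod`}{Envelope interaural-phase detection, 2I-2AFC.
#'     log10(IPD in degrees); start and cap 180 deg. Conditions: carrier
#'     0.6/2 kHz x level 40/80 dB SPL.}
#'   \item{`ipd_pt`}{Fine-structure IPD detection for 0.6-kHz pure tones,
#'     2I-2AFC; start and cap 180 deg. Conditions: level 40/80 dB SPL.}
#'   \item{`crm`}{Competing-sentence speech reception; response is one of
#'     4 colors x 4 numbers (guess 1/16). Target SNR in dB, start +7 dB.
#'     Conditions: masker level 42/77 dB SPL x masker offset
#'     colocated/offset.}
#'   \item{`dtt`}{Digit-triplet reception in noise; triplets drawn from
#'     the digits 1-9 excluding 7, no within-triplet repeats, so 8*7*6
#'     ordered triplets (guess 1/336 for whole-triplet scoring). SNR in
#'     dB, start +10 dB. Conditions: masker level 45/80 dB SPL.}
#' }
#'
#' UML prior and grid defaults are package configuration (chosen to be
#' broad relative to the plausible threshold range of each task) and can
#' be overridden per run.
#'
#' @param task One of `"am"`, `"fd"`, `"f0d"`, `"ipd_mod"`, `"ipd_pt"`,
#'   `"crm"`, `"dtt"`.
#' @return A list with elements `task`, `dimension`, `unit`, `scale`,
#'   `guess`, `start`, `bounds`, `conditions` (data frame), and `uml`
#'   (default prior/grid specification, see [uml_init]).
#' @export
task_spec <- function(task = c("am", "fd", "f0d", "ipd_mod", "ipd_pt",
                               "crm", "dtt")) {
  task <- match.arg(task)
  reg <- .task_registry()
  reg[[task]]
}

#' @rdname task_spec
#' @export
task_names <- function() names(.task_registry())

.task_registry <- function() {
  uml_default <- function(mid_mean, mid_sd, bounds,
                          slope_shape = 2, slope_rate = NULL,
                          slope_mean = NULL, slope_range) {
    if (is.null(slope_rate)) slope_rate <- slope_shape / slope_mean
    list(
      prior = list(midpoint = c(mean = mid_mean, sd = mid_sd),
                   slope = c(shape = slope_shape, rate = slope_rate),
                   lapse = c(shape = 1.2, rate = 12)),
      grids = list(alpha = seq(bounds[1], bounds[2], length.out = 61),
                   beta = seq(slope_range[1], slope_range[2],
                              length.out = 41),
                   lambda = seq(0, 0.2, length.out = 5)))
  }
  list(
    am = list(
      task = "am", dimension = "AM depth", unit = "dB re 100% depth",
      scale = "linear", guess = 1 / 3, start = 0, bounds = c(-40, 0),
      conditions = expand.grid(level = c(40, 80),
                               modfreq = c(25, 50, 100)),
      uml = uml_default(-15, 10, c(-40, 0), slope_mean = 0.4,
                        slope_range = c(0.02, 2))),
    fd = list(
      task = "fd", dimension = "frequency difference",
      unit = "log10(% difference)", scale = "log",
      guess = 1 / 2, start = log10(10), bounds = c(-3, log10(99)),
      conditions = expand.grid(level = c(40, 80),
                               frequency = c(600, 2000)),
      uml = uml_default(-0.5, 1, c(-3, log10(99)), slope_mean = 2,
                        slope_range = c(0.2, 8))),
    f0d = list(
      task = "f0d", dimension = "F0 difference",
      unit = "log10(% difference)", scale = "log",
      guess = 1 / 2, start = log10(80), bounds = c(-2, log10(99)),
      conditions = expand.grid(level = c(40, 80)),
      uml = uml_default(0.3, 1, c(-2, log10(99)), slope_mean = 2,
                        slope_range = c(0.2, 8))),
    ipd_mod = list(
      task = "ipd_mod", dimension = "interaural phase difference",
      unit = "log10(degrees)", scale = "log",
      guess = 1 / 2, start = log10(180), bounds = c(-1, log10(180)),
      conditions = expand.grid(level = c(40, 80),
                               carrier = c(600, 2000)),
      uml = uml_default(1.2, 1, c(-1, log10(180)), slope_mean = 2,
                        slope_range = c(0.2, 8))),
    ipd_pt = list(
      task = "ipd_pt", dimension = "interaural phase difference",
      unit = "log10(degrees)", scale = "log",
      guess = 1 / 2, start = log10(180), bounds = c(-1, log10(180)),
      conditions = expand.grid(level = c(40, 80)),
      uml = uml_default(1, 1, c(-1, log10(180)), slope_mean = 2,
                        slope_range = c(0.2, 8))),
    crm = list(
      task = "crm", dimension = "target-to-masker SNR", unit = "dB",
      scale = "linear", guess = 1 / 16, start = 7, bounds = c(-40, 20),
      conditions = expand.grid(level = c(42, 77),
                               offset = c("colocated", "offset"),
                               stringsAsFactors = FALSE),
      uml = uml_default(-8, 8, c(-40, 20), slope_mean = 0.5,
                        slope_range = c(0.05, 2))),
    dtt = list(
      task = "dtt", dimension = "digits-to-masker SNR", unit = "dB",
      scale = "linear", guess = 1 / 336, start = 10, bounds = c(-30, 15),
      conditions = expand.grid(level = c(45, 80)),
      uml = uml_default(-8, 8, c(-30, 15), slope_mean = 0.5,
                        slope_range = c(0.05, 2))))
}

#' Harmonic-rank arithmetic for bandpass-filtered complex tones
#'
#' Complex tones for F0 discrimination are bandpass filtered between 1.5
#' and 2.5 kHz so that only high-rank (unresolved) harmonics are audible.
#' The rank of the lowest audible harmonic is the smallest integer
#' multiple of the F0 that falls at or above the lower passband edge:
#' `ceiling(edge_hz / f0)`. At the standard F0 of 100 Hz this is 15; as
#' the comparison tone's F0 rises towards the 99% maximum difference, the
#' lowest rank falls, reaching its minimum of 8 at the cap.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param edge_hz Lower passband edge in Hz (default 1500).
#' @return Integer harmonic rank.
#' @export
lowest_harmonic_rank <- function(f0, edge_hz = 1500) {
  stopifnot(all(is.finite(f0)), all(f0 > 0), is.finite(edge_hz))
  as.integer(ceiling(edge_hz / f0))
}

#' @rdname lowest_harmonic_rank
#' @param base_f0 F0 of the standard tone in Hz (default 100).
#' @param max_increase_pct Maximum permitted F0 difference in percent
#'   (default 99, the adaptive track's cap).
#' @export
min_comparison_rank <- function(base_f0 = 100, max_increase_pct = 99,
                                edge_hz = 1500) {
  lowest_harmonic_rank(base_f0 * (1 + max_increase_pct / 100), edge_hz)
}

#' Sample a digit triplet
#'
#' Draws the three digits presented on one digit-triplet trial: digits in
#' 1-9 excluding 7 (the only two-syllable digit), with no repetitions
#' within a triplet.
#'
#' @param n Number of triplets.
#' @return An `n` x 3 integer matrix.
#' @export
sample_digit_triplet <- function(n = 1) {
  pool <- c(1:6, 8:9)
  t(vapply(seq_len(n), function(i) sample(pool, 3, replace = FALSE),
           integer(3)))
}
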