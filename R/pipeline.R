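#' The nine regression model families
#'
#' Declarative specifications of the analysis models, one per outcome
#' family: AM detection, frequency discrimination, F0 discrimination,
#' envelope IPD detection, pure-tone IPD detection, competing-sentence
#' speech reception, digit-triplet speech reception, musical-interval
#' ratings, and the SSQ12 questionnaire. Each spec names the outcome and
#' its transform, the continuous covariates (age, the task's audiometric
#' covariate, log10 noise exposure, two cognitive components, cube-root
#' musical practice), the condition factors, and the interaction list
#' (condition factors crossed with age, the audiometric covariate and
#' noise exposure; the competing-sentence and rating families
#' additionally cross masker offset / interval with the cognitive and
#' musical covariates). All models carry per-subject random intercepts
#' except the questionnaire family, which has one row per subject.
#'
#' @return Named list of family specs.
#' @export
model_families <- function() {
  covs <- function(audio) c("age", audio, "log_tcne", "cog1", "cog2",
                            "music_y3")
  ia <- function(factors, audio, extra = list())
    c(unlist(lapply(factors, function(f)
      lapply(c("age", audio, "log_tcne"), function(v) c(v, f))),
      recursive = FALSE), extra)
  list(
    am = list(name = "am", data = "thresholds", task = "am",
              outcome = "threshold", transform = "identity",
              audio = "pt2", factors = c("level", "modfreq"),
              continuous = covs("pt2"),
              interactions = ia(c("level", "modfreq"), "pt2"),
              subject = TRUE),
    fd = list(name = "fd", data = "thresholds", task = "fd",
              outcome = "threshold", transform = "log",
              audio = "pt_match", factors = c("level", "frequency"),
              continuous = covs("pt_match"),
              interactions = ia(c("level", "frequency"), "pt_match"),
              subject = TRUE),
    f0d = list(name = "f0d", data = "thresholds", task = "f0d",
               outcome = "threshold", transform = "log",
               audio = "pt2", factors = "level",
               continuous = covs("pt2"),
               interactions = ia("level", "pt2"), subject = TRUE),
    ipd_mod = list(name = "ipd_mod", data = "thresholds",
                   task = "ipd_mod", outcome = "threshold",
                   transform = "log", audio = "pt_match",
                   factors = c("level", "carrier"),
                   continuous = covs("pt_match"),
                   interactions = ia(c("level", "carrier"), "pt_match"),
                   subject = TRUE),
    ipd_pt = list(name = "ipd_pt", data = "thresholds",
                  task = "ipd_pt", outcome = "threshold",
                  transform = "log", audio = "pt05",
                  factors = "level", continuous = covs("pt05"),
                  interactions = ia("level", "pt05"), subject = TRUE),
    crm = list(name = "crm", data = "thresholds", task = "crm",
               outcome = "threshold", transform = "identity",
               audio = "pta_low", factors = c("level", "offset"),
               continuous = covs("pta_low"),
               interactions = ia(c("level", "offset"), "pta_low",
                                 list(c("cog1", "offset"),
                                      c("cog2", "offset"),
                                      c("music_y3", "offset"))),
               subject = TRUE),
    dtt = list(name = "dtt", data = "thresholds", task = "dtt",
               outcome = "threshold", transform = "identity",
               audio = "pta_low", factors = "level",
               continuous = covs("pta_low"),
               interactions = ia("level", "pta_low"), subject = TRUE),
    consonance = list(name = "consonance", data = "ratings",
                      outcome = "rating_z", transform = "identity",
                      audio = "pta_low",
                      factors = c("dyad_level", "interval"),
                      continuous = covs("pta_low"),
                      interactions = ia(c("dyad_level", "interval"),
                                        "pta_low",
                                        list(c("cog1", "interval"),
                                             c("cog2", "interval"),
                                             c("music_y3", "interval"))),
                      subject = TRUE),
    ssq = list(name = "ssq", data = "ssq", outcome = "ssq12_mean",
               transform = "identity", audio = "pta_low",
               factors = character(),
               continuous = c("age", "pta_low", "pta_high", "log_tcne",
                              "cog1", "cog2", "music_y3"),
               interactions = list(), subject = FALSE))
}

#' Assemble the analysis table for one model family
#'
#' Joins the per-condition outcome table to the cohort covariates and
#' constructs any per-row audiometric covariate (`pt_match`: the 0.5-kHz
#' threshold for 0.6-kHz stimuli, the 2-kHz threshold for 2-kHz
#' stimuli).
#'
#' @param family One element of [model_families()].
#' @param cohort A cohort table.
#' @param thresholds Long threshold table (for threshold families).
#' @param ratings Dyad rating table (for the rating family).
#' @param ssq SSQ item table (for the questionnaire family).
#' @return Data frame ready for [build_design], with attribute
#'   `design_args` holding the matching `build_design` arguments.
#' @export
prepare_family_data <- function(family, cohort, thresholds = NULL,
                                ratings = NULL, ssq = NULL) {
  cov_cols <- c("subject", "age", "pt05", "pt2", "pta_low", "pta_high",
                "log_tcne", "cog1", "cog2", "music_y3")
  base <- cohort[, cov_cols]
  if (family$data == "thresholds") {
    stopifnot(!is.null(thresholds))
    d <- thresholds[thresholds$task == family$task, , drop = FALSE]
    d <- d[, c("subject", family$factors, "threshold")]
    d <- merge(d, base, by = "subject")
  } else if (family$data == "ratings") {
    stopifnot(!is.null(ratings))
    zr <- consonance_preference(ratings)$ratings_z
    d <- merge(zr, base, by = "subject")
  } else {
    stopifnot(!is.null(ssq))
    sm <- stats::aggregate(list(ssq12_mean = ssq$score),
                           by = list(subject = ssq$subject), FUN = mean)
    d <- merge(sm, base, by = "subject")
  }
  if (family$audio == "pt_match") {
    key <- if ("frequency" %in% names(d)) d$frequency else d$carrier
    d$pt_match <- ifelse(as.numeric(as.character(key)) <= 1000,
                         d$pt05, d$pt2)
  }
  for (f in family$factors) d[[f]] <- factor(d[[f]])
  attr(d, "design_args") <- list(
    outcome = family$outcome, continuous = family$continuous,
    factors = family$factors, interactions = family$interactions,
    subject = if (family$subject) "subject" else NULL,
    outcome_transform = family$transform)
  d
}

#' Fit one model family end to end
#'
#' @param family One element of [model_families()] (or its name).
#' @param cohort,thresholds,ratings,ssq Data tables (see
#'   [prepare_family_data]).
#' @param priors A [prior_config].
#' @param settings See [regression_settings].
#' @param seed Integer seed.
#' @return A [fit_robust] result.
#' @export
fit_family <- function(family, cohort, thresholds = NULL,
                       ratings = NULL, ssq = NULL,
                       priors = prior_config(),
                       settings = regression_settings(), seed = 1) {
  if (is.character(family)) family <- model_families()[[family]]
  d <- prepare_family_data(family, cohort, thresholds, ratings, ssq)
  design <- do.call(build_design,
                    c(list(data = d), attr(d, "design_args")))
  fit_robust(design, priors = priors, settings = settings, seed = seed)
}

#' Pipeline run configuration
#'
#' A run is reproducible from the configuration and seed alone.
#'
#' @param seed Master seed.
#' @param n Cohort size.
#' @param tasks Tasks to track and analyse.
#' @param families Model families to fit.
#' @param n_trials,n_practice Adaptive-track lengths.
#' @param use_tracks Simulate trial-level adaptive tracks and refit
#'   psychometric functions (`TRUE`), or regress directly on generated
#'   thresholds (`FALSE`, much faster).
#' @param pf_settings,reg_settings,priors MCMC and prior settings.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n = 102, tasks = "dtt",
                       families = "dtt", n_trials = 160,
                       n_practice = 25, use_tracks = FALSE,
                       pf_settings = pf_fit_settings(),
                       reg_settings = regression_settings(),
                       priors = prior_config(), out_dir = NULL) {
  structure(list(seed = seed, n = n, tasks = tasks,
                 families = families, n_trials = n_trials,
                 n_practice = n_practice, use_tracks = use_tracks,
                 pf_settings = pf_settings,
                 reg_settings = reg_settings, priors = priors,
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a table against a required schema
#'
#' @param df Data frame.
#' @param required Required column names.
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; errors naming the missing column(s).
#' @export
validate_schema <- function(df, required, what = "table") {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

.cohort_schema <- c("subject", "age", "pt05", "pt2", "pta_low",
                    "pta_high", "log_tcne", "cog1", "cog2", "music_y3")

#' Read and write pipeline tables
#'
#' All pipeline artifacts are delimited text (CSV with header) plus
#' JSON sidecars; readers validate the schema and round-trip with full
#' fidelity.
#'
#' @param df Data frame.
#' @param path File path.
#' @return `read_cohort`/`read_trials` return validated data frames.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  validate_schema(df, .cohort_schema, "cohort table")
  df
}

#' @rdname write_table
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  validate_schema(df, c("subject", "task", "trial_index", "stimulus",
                        "response", "sweetpoint_index", "is_practice"),
                  "trial log")
  df
}

#' Fit psychometric functions for every subject x condition
#'
#' Groups a trial log by task and condition, centres the midpoint and
#' slope priors on across-subject preliminary ML fits, refits each
#' subject's pooled (non-practice) responses by MCMC, and tabulates the
#' threshold posterior. Thresholds for ratio-scale tasks are reported in
#' natural units.
#'
#' @param tracks Trial log from [generate_tracks] (or read from disk).
#' @param settings See [pf_fit_settings].
#' @param fraction Fraction of dynamic range defining the threshold
#'   (default 0.5, the midpoint; 0.25 for quarter-point re-analyses).
#' @param seed Integer seed.
#' @return Data frame: `subject`, `task`, condition columns,
#'   `threshold_median`, `ci99_lo`, `ci99_hi`, `rhat_max`, `ess_min`,
#'   `converged`, plus `threshold` (alias of the median, in natural
#'   units) for downstream regression.
#' @export
fit_all_pfs <- function(tracks, settings = pf_fit_settings(),
                        fraction = 0.5, seed = 1) {
  tracks <- tracks[!tracks$is_practice, , drop = FALSE]
  out <- list()
  for (task in unique(tracks$task)) {
    spec <- task_spec(task)
    cond_cols <- names(spec$conditions)
    tt <- tracks[tracks$task == task, , drop = FALSE]
    key <- do.call(paste, c(tt[cond_cols], sep = "|"))
    for (kv in unique(key)) {
      sub <- tt[key == kv, , drop = FALSE]
      by_subj <- split(sub, sub$subject)
      centers <- suppressWarnings(
        empirical_prior_centers(by_subj, guess = spec$guess))
      pri <- pf_prior_spec(
        midpoint_mean = centers[["midpoint"]],
        midpoint_sd = diff(spec$bounds) / 4,
        slope_shape = 2, slope_rate = 2 / centers[["slope"]],
        guess = spec$guess)
      for (sj in names(by_subj)) {
        fit <- fit_pf(by_subj[[sj]], pri, settings = settings,
                      seed = seed + nchar(sj))
        th <- pf_threshold(fit, fraction = fraction)
        nat <- function(v) if (spec$scale == "log") 10^v else v
        row <- data.frame(subject = sj, task = task)
        for (cc in cond_cols) row[[cc]] <- sub[[cc]][1]
        row$threshold_median <- nat(th$median)
        row$ci99_lo <- nat(th$lo)
        row$ci99_hi <- nat(th$hi)
        row$rhat_max <- if (all(is.na(fit$rhat))) NA else
          max(fit$rhat, na.rm = TRUE)
        row$ess_min <- min(fit$ess)
        row$converged <- fit$converged
        out[[length(out) + 1]] <- row
      }
    }
  }
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) {
    for (v in setdiff(nm, names(d))) d[[v]] <- NA
    d[nm]
  })
  res <- do.call(rbind, out)
  res$threshold <- res$threshold_median
  res
}

#' Run the full pipeline: generate, track, fit, score, regress
#'
#' Executes the end-to-end study simulation and analysis described by a
#' [run_config]: synthetic cohort, adaptive tracks (or direct threshold
#' generation), psychometric refits, derived scores, robust regression
#' per requested family, and age contrasts across the stimulus-level
#' factor. Returns a manifest of what was run plus all stage outputs;
#' with `out_dir` set, writes each table as CSV and the manifest and
#' truth sidecar as JSON.
#'
#' @param config A [run_config].
#' @return List with `manifest`, `cohort`, `thresholds`, `tracks`
#'   (if simulated), `fits` (per family), `contrasts` (per family).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- cohort_truth()
  cohort <- generate_cohort(config$n, seed = config$seed,
                            truth = truth)
  tracks <- NULL
  if (config$use_tracks) {
    tracks <- generate_tracks(cohort, tasks = config$tasks,
                              truth = truth, seed = config$seed,
                              n_trials = config$n_trials,
                              n_practice = config$n_practice)
    thresholds <- fit_all_pfs(tracks, settings = config$pf_settings,
                              seed = config$seed)
  } else {
    thresholds <- generate_thresholds(cohort, tasks = config$tasks,
                                      truth = truth,
                                      seed = config$seed)
  }
  needs_ratings <- "consonance" %in% config$families
  needs_ssq <- "ssq" %in% config$families
  ratings <- if (needs_ratings)
    generate_ratings(cohort, truth, seed = config$seed) else NULL
  ssq <- if (needs_ssq)
    generate_ssq(cohort, truth, seed = config$seed) else NULL
  fams <- model_families()[config$families]
  fits <- list()
  contrasts <- list()
  for (fam in fams) {
    fit <- fit_family(fam, cohort, thresholds = thresholds,
                      ratings = ratings, ssq = ssq,
                      priors = config$priors,
                      settings = config$reg_settings,
                      seed = config$seed)
    fits[[fam$name]] <- fit
    if (length(fam$factors) > 0)
      contrasts[[fam$name]] <- derived_contrasts(
        fit, "age", factors = fam$factors[1], per_unit = 10,
        exponentiate = fam$transform == "log")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("audaging")),
    seed = config$seed, n = config$n, tasks = config$tasks,
    families = config$families, use_tracks = config$use_tracks,
    n_rows = list(cohort = nrow(cohort),
                  thresholds = nrow(thresholds),
                  tracks = if (is.null(tracks)) 0L else nrow(tracks)),
    diagnostics = lapply(fits, function(f)
      list(converged = f$converged,
           rhat_max = if (all(is.na(f$rhat))) NA else
             max(f$rhat, na.rm = TRUE),
           ess_min = min(f$ess))))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(cohort, file.path(config$out_dir, "cohort.csv"))
    write_table(thresholds, file.path(config$out_dir,
                                      "thresholds.csv"))
    if (!is.null(tracks))
      write_table(tracks, file.path(config$out_dir, "trials.csv"))
    for (nm in names(fits))
      write_table(summarize_ci(fits[[nm]]),
                  file.path(config$out_dir,
                            paste0("fit_", nm, "_ci.csv")))
    for (nm in names(contrasts))
      write_table(contrasts[[nm]],
                  file.path(config$out_dir,
                            paste0("contrasts_", nm, ".csv")))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(manifest = manifest, cohort = cohort, thresholds = thresholds,
       tracks = tracks, fits = fits, contrasts = contrasts)
}
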