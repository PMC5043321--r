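REPORT_SCHEMA_VERSION <- "1.0"

load_analysis_inputs <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  need <- function(rel, what) {
    p <- file.path(base, rel)
    if (!file.exists(p))
      stop(sprintf("config error: %s file missing: %s", what, p), call. = FALSE)
    p
  }
  vs <- read_visual_system(need(cfg$visual_system, "visual system"))
  backgrounds <- lapply(cfg$backgrounds, function(rel)
    read_spectrum(need(rel, "background spectrum"), "quantum_radiance"))
  rewarded <- read_spectrum(need(cfg$rewarded_stimulus, "rewarded stimulus"),
                            "quantum_radiance")
  trials <- utils::read.csv(need(cfg$trials, "trial table"),
                            stringsAsFactors = FALSE)
  list(vs = vs, backgrounds = backgrounds, rewarded = rewarded,
       trials = trials,
       detection_background = cfg$detection_background %||% NA_character_,
       criterion = cfg$criterion %||% "auto")
}

#' Run the full analysis pipeline
#'
#' Orchestrates spectra -> background contrasts -> psychometric fits ->
#' thresholds -> linear threshold model -> dipper summary. Input is either a
#' config file on disk (see [write_experiment()] for the layout) or an
#' in-memory experiment from [simulate_experiment()]. Per condition the
#' threshold criterion is derived from the trial count by
#' [binomial_criterion()] unless the config fixes a proportion.
#'
#' @param config Path to a `config.yaml`, or `NULL`.
#' @param experiment Result of [simulate_experiment()], or `NULL` to
#'   simulate one with `seed`.
#' @param seed Seed used only when both `config` and `experiment` are
#'   `NULL`.
#' @param out_json Optional path; the report is written as JSON.
#' @return The report: a list with `schema_version`, `settings`,
#'   `background_contrasts`, `conditions` (per subject x background fit
#'   summaries), `points`, `threshold_models` (per subject), and
#'   `dipper` (per subject).
#' @export
run_full_analysis <- function(config = NULL, experiment = NULL, seed = 1L,
                              out_json = NULL) {
  if (!is.null(config)) {
    inp <- load_analysis_inputs(config)
  } else {
    if (is.null(experiment)) experiment <- simulate_experiment(seed)
    inp <- list(vs = experiment$vs, backgrounds = experiment$backgrounds,
                rewarded = experiment$rewarded, trials = experiment$trials,
                detection_background = "grey_detection", criterion = "auto")
  }
  trials <- inp$trials
  req <- c("subject", "background", "level", "n_trials", "n_correct")
  if (!all(req %in% names(trials)))
    stop("trial table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)

  bg_contrast <- vapply(inp$backgrounds, function(bg)
    stimulus_background_contrast(inp$rewarded, bg, inp$vs), numeric(1))

  conditions <- list()
  points <- NULL
  for (sub in unique(trials$subject)) {
    for (bgname in unique(trials$background[trials$subject == sub])) {
      d <- trials[trials$subject == sub & trials$background == bgname, ]
      fit <- fit_psychometric(d, criterion = inp$criterion)
      is_det <- identical(bgname, inp$detection_background)
      xc <- if (is_det) 0 else {
        if (!bgname %in% names(bg_contrast))
          stop("config error: no background spectrum for condition '",
               bgname, "'", call. = FALSE)
        unname(bg_contrast[[bgname]])
      }
      conditions[[paste(sub, bgname, sep = ".")]] <- list(
        subject = sub, background = bgname,
        task = if (is_det) "detection" else "discrimination",
        background_contrast_jnd = xc,
        a = fit$a, b = fit$b, lapse = fit$lapse,
        loglik = fit$loglik, converged = fit$converged,
        criterion = fit$criterion, threshold_jnd = fit$threshold,
        flag = fit$flag)
      if (!is.na(fit$threshold)) {
        # a negative interpolated threshold means performance above criterion
        # at every level: the behavioural threshold is at or below zero JND
        points <- rbind(points, threshold_point(
          sub, if (is_det) "detection" else "discrimination",
          xc, max(0, fit$threshold)))
      }
    }
  }

  models <- list()
  dippers <- list()
  for (sub in unique(points$subject)) {
    psub <- points[points$subject == sub, ]
    if (sum(psub$task == "discrimination") >= 3L) {
      m <- fit_threshold_line(psub)
      models[[sub]] <- list(slope = m$slope, intercept = m$intercept,
                            one_jnd_crossing = m$one_jnd_crossing,
                            r_squared = m$r_squared, pearson_p = m$pearson_p,
                            n_points = m$n_points)
    }
    if (any(psub$task == "detection") && sum(psub$task == "discrimination") >= 2L)
      dippers[[sub]] <- dipper_summary(psub)
  }

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    settings = list(
      criterion_policy = inp$criterion,
      noise_scaling = inp$vs$noise_scaling,
      weber_lws = inp$vs$weber_lws,
      abundances = as.list(inp$vs$abundances),
      detection_background = inp$detection_background),
    background_contrasts = as.list(bg_contrast),
    conditions = conditions,
    points = points,
    threshold_models = models,
    dipper = dippers)

  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  report
}
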