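#' Synthetic three-primary monitor model
#'
#' Gaussian-shaped primaries on a wavelength grid. The default peaks
#' (~450, 550, 610 nm), bandwidths and radiance scale are deliberately
#' generic monitor-like values — a labelled synthetic stand-in for a
#' measured display, adequate because every chromatic quantity downstream is
#' adaptation- and scale-normalized.
#'
#' A broadband backlight-leak term (a wide Gaussian scaled by the mean drive
#' level) gives every stimulus a small shared continuum, as real LCD panels
#' do; without it the deep-blue and ultraviolet catches of strongly coloured
#' stimuli would be implausibly close to zero.
#'
#' @param peaks Primary peak wavelengths (nm), >= 3 primaries.
#' @param bandwidths Gaussian sigma per primary (nm).
#' @param max_radiance Peak quantum radiance per primary at full drive
#'   (quanta s^-1 cm^-2 nm^-1 sr^-1).
#' @param leak_radiance Peak quantum radiance of the broadband leak at full
#'   mean drive (0 disables it).
#' @param leak_peak,leak_bandwidth Centre (nm) and sigma (nm) of the leak.
#' @param grid Wavelength grid (nm).
#' @return An object of class `monitor_model`.
#' @export
monitor_model <- function(peaks = c(450, 550, 610),
                          bandwidths = c(35, 45, 40),
                          max_radiance = c(2.5e11, 3.0e11, 3.0e11),
                          leak_radiance = 1.5e10, leak_peak = 500,
                          leak_bandwidth = 160,
                          grid = canonical_grid()) {
  if (length(peaks) < 3L)
    stop("monitor needs at least 3 primaries", call. = FALSE)
  if (length(bandwidths) != length(peaks) ||
      length(max_radiance) != length(peaks))
    stop("peaks, bandwidths and max_radiance must have equal length", call. = FALSE)
  if (any(c(peaks, bandwidths, max_radiance) <= 0))
    stop("all monitor parameters must be positive", call. = FALSE)
  if (leak_radiance < 0 || leak_peak <= 0 || leak_bandwidth <= 0)
    stop("invalid leak parameters", call. = FALSE)
  structure(list(peaks = peaks, bandwidths = bandwidths,
                 max_radiance = max_radiance,
                 leak_radiance = leak_radiance, leak_peak = leak_peak,
                 leak_bandwidth = leak_bandwidth, grid = grid),
            class = "monitor_model")
}

#' Synthesize a monitor spectrum from primary drive levels
#'
#' Weighted sum of the Gaussian primaries; deterministic and linear in the
#' weights.
#'
#' @param model A `monitor_model`.
#' @param weights Drive level per primary, each in [0, 1].
#' @return `rnl_spectrum[quantum_radiance]`.
#' @export
synth_spectrum <- function(model, weights) {
  stopifnot(inherits(model, "monitor_model"))
  if (length(weights) != length(model$peaks))
    stop("need one weight per primary", call. = FALSE)
  if (any(weights < 0 | weights > 1))
    stop("weights must lie in [0, 1]", call. = FALSE)
  v <- numeric(length(model$grid))
  for (i in seq_along(weights)) {
    v <- v + weights[i] * model$max_radiance[i] *
      exp(-((model$grid - model$peaks[i]) / model$bandwidths[i])^2 / 2)
  }
  v <- v + mean(weights) * model$leak_radiance *
    exp(-((model$grid - model$leak_peak) / model$leak_bandwidth)^2 / 2)
  spectrum(model$grid, v, "quantum_radiance")
}

scale_spectrum <- function(spec, factor) {
  spectrum(spec$wl, spec$value * factor, spec$unit_role)
}

mix_spectra <- function(s1, s2, w) {
  # convex mixture (1-w) s1 + w s2 on s1's grid
  grid <- common_grid(s1, s2)
  spectrum(grid, (1 - w) * resample(s1, grid)$value +
             w * resample(s2, grid)$value, s1$unit_role)
}

#' Grey-to-red saturation series with JND ladder
#'
#' Convex mixtures between a grey and a red endpoint spectrum. Each element
#' is scored by its RNL contrast to the red endpoint and to the background,
#' with receptors adapted to the background. If `targets` is given, mixture
#' weights are solved (by root finding on the mixing weight) so the series
#' hits those JND contrasts to the red endpoint; otherwise `n_steps` equal
#' mixture steps spanning grey to red are used. With
#' `balance_intensity = TRUE` every element is rescaled to the double-cone
#' catch of the red endpoint so all pairwise Michelson contrasts are below
#' `michelson_max` (intensity-balanced stimuli isolate the chromatic cue).
#'
#' @param grey,red Endpoint spectra (`quantum_radiance`).
#' @param vs An `rnl_visual_system`.
#' @param background Adapting background spectrum.
#' @param n_steps Number of series elements (>= 2) when `targets` is `NULL`.
#' @param targets Optional JND contrasts to the red endpoint to calibrate
#'   the series to (decreasing saturation = increasing JND to red).
#' @param balance_intensity Rescale elements to equal double-cone catch.
#' @param michelson_max Post-condition bound checked after balancing.
#' @return List with `spectra` (list of `rnl_spectrum`), `jnd_to_red`,
#'   `jnd_to_background`, `mix_weights`.
#' @export
make_saturation_series <- function(grey, red, vs, background,
                                   n_steps = 6L, targets = NULL,
                                   balance_intensity = !is.null(vs$double_cone),
                                   michelson_max = 0.04) {
  if (is.null(targets) && n_steps < 2L)
    stop("n_steps must be at least 2", call. = FALSE)
  jnd_to_red <- function(w) colour_contrast(vs, mix_spectra(grey, red, w), red, background)
  if (is.null(targets)) {
    weights <- seq(0, 1, length.out = n_steps)
  } else {
    max_jnd <- jnd_to_red(0)
    weights <- vapply(targets, function(t) {
      if (t > max_jnd + 1e-9)
        stop(sprintf("target %.3g JND exceeds the series maximum %.3g", t, max_jnd),
             call. = FALSE)
      if (t <= 0) return(1)
      stats::uniroot(function(w) jnd_to_red(w) - t, c(0, 1),
                     tol = 1e-10)$root
    }, numeric(1))
  }
  spectra <- lapply(weights, function(w) mix_spectra(grey, red, w))
  if (balance_intensity) {
    qd_ref <- double_cone_catch(vs, red)
    spectra <- lapply(spectra, function(s) {
      qd <- double_cone_catch(vs, s)
      if (qd <= 0) stop("cannot balance a zero double-cone catch", call. = FALSE)
      scale_spectrum(s, qd_ref / qd)
    })
    qds <- vapply(spectra, double_cone_catch, numeric(1), vs = vs)
    pair_mich <- outer(qds, qds, function(p, q) abs(p - q) / (p + q))
    if (max(pair_mich) >= michelson_max)
      stop("intensity balancing failed to reach the Michelson bound", call. = FALSE)
  }
  list(spectra = spectra,
       jnd_to_red = vapply(spectra, colour_contrast, numeric(1),
                           vs = vs, stim2 = red, background = background),
       jnd_to_background = vapply(spectra, stimulus_background_contrast,
                                  numeric(1), background = background, vs = vs),
       mix_weights = weights)
}

#' Constrained pseudo-random left/right reward schedule
#'
#' Balanced side sequence in which no side is rewarded more than `max_run`
#' times in a row (the classic guard against side-bias learning in
#' two-alternative tasks). Constructed by a quota sampler: each side is
#' drawn with probability proportional to its remaining quota, with a forced
#' switch when the current run reaches `max_run`; bounded deterministic
#' retries handle the rare dead end near the end of a sequence.
#'
#' @param n_trials Number of trials (>= 1).
#' @param max_run Longest permitted same-side run (>= 1).
#' @param seed Integer seed; the sequence is reproducible given the seed.
#' @return Character vector of `"left"`/`"right"`.
#' @export
fellows_schedule <- function(n_trials, max_run = 4L, seed = 1L) {
  if (n_trials < 1L || max_run < 1L)
    stop("n_trials and max_run must be at least 1", call. = FALSE)
  if (max_run == 1L && n_trials > 1L) {
    # strict alternation is the only solution; randomize the phase
    set.seed(seed)
    start <- sample(c("left", "right"), 1L)
    other <- setdiff(c("left", "right"), start)
    return(rep_len(c(start, other), n_trials))
  }
  quota <- c(left = ceiling(n_trials / 2), right = floor(n_trials / 2))
  for (attempt in 0:99) {
    set.seed(seed + attempt * 10007L)
    rem <- quota
    out <- character(n_trials)
    run <- 0L
    ok <- TRUE
    for (i in seq_len(n_trials)) {
      allowed <- names(rem)[rem > 0L]
      if (i > 1L && run >= max_run) allowed <- setdiff(allowed, out[i - 1L])
      if (length(allowed) == 0L) { ok <- FALSE; break }
      side <- if (length(allowed) == 1L) allowed else
        sample(allowed, 1L, prob = rem[allowed])
      out[i] <- side
      run <- if (i > 1L && side == out[i - 1L]) run + 1L else 1L
      rem[side] <- rem[side] - 1L
    }
    if (ok) {
      # guard: the forced single-side tail can still overrun
      r <- rle(out)
      if (max(r$lengths) <= max_run) return(out)
    }
  }
  stop("could not satisfy schedule constraints", call. = FALSE)
}

#' Define a simulated observer
#'
#' True psychometric parameters of a synthetic subject in the
#' two-alternative task.
#'
#' @param a True position parameter (stimulus units).
#' @param b True steepness (> 0).
#' @param lapse True lapse rate in [0, 0.25].
#' @param gamma Guess rate (0.5 for two alternatives).
#' @return An object of class `simulated_observer`.
#' @export
simulated_observer <- function(a, b, lapse = 0.02, gamma = 0.5) {
  if (b <= 0) stop("b must be positive", call. = FALSE)
  if (lapse < 0 || lapse > 0.25) stop("lapse must lie in [0, 0.25]", call. = FALSE)
  structure(list(a = a, b = b, lapse = lapse, gamma = gamma),
            class = "simulated_observer")
}

#' Position parameter for a wanted threshold
#'
#' Inverse bookkeeping for observer construction: given a target threshold
#' at a criterion, the position a that places the psychometric function's
#' criterion crossing exactly there.
#'
#' @param threshold Wanted threshold level.
#' @param b,lapse,gamma Remaining psychometric parameters.
#' @param criterion Correct-choice criterion the threshold refers to.
#' @return Scalar `a`.
#' @export
observer_position_for_threshold <- function(threshold, b, lapse = 0.02,
                                            gamma = 0.5, criterion = 2 / 3) {
  threshold + b * log((1 - gamma - lapse) / (criterion - gamma) - 1)
}

#' Simulate one session of binomial choice data
#'
#' Draws the number of correct choices at each level from
#' Binomial(n, psi(level)) under the observer's true psychometric function.
#'
#' @param obs A `simulated_observer`.
#' @param levels Stimulus levels.
#' @param trials_per_level Trials per level.
#' @param seed Integer seed.
#' @return Data frame with `level`, `n_trials`, `n_correct`.
#' @export
simulate_session <- function(obs, levels, trials_per_level = 30L, seed = 1L) {
  stopifnot(inherits(obs, "simulated_observer"), length(levels) >= 1L)
  p <- psi(levels, obs$a, obs$b, obs$gamma, obs$lapse)
  set.seed(seed)
  data.frame(level = levels,
             n_trials = trials_per_level,
             n_correct = stats::rbinom(length(levels), trials_per_level, p))
}

# Drive levels for the default experiment-shaped stimulus set (documented as arbitrary
# monitor-like choices; chromatic ordering, not the exact numbers, matters).
.STUDY_DRIVES <- list(
  red_disc     = c(0.120, 0.080, 0.900),
  grey_disc    = c(0.327, 0.409, 0.387),
  bg_grey      = c(0.177, 0.221, 0.209),
  bg_grey_brt  = c(0.177, 0.221, 0.209) * 1.316, # same chromaticity, brighter
  bg_yellow    = c(0.017, 0.228, 0.171),
  bg_green     = c(0.032, 0.385, 0.013),
  bg_medred    = c(0.108, 0.158, 0.332)
)

#' Simulate the full background-adaptation experiment
#'
#' Generates every input of the analysis pipeline in memory: a synthetic
#' monitor, five coloured backgrounds (grey, bright grey, yellow, green,
#' medium red), a grey-to-red saturation series calibrated on the grey
#' background to the discrimination ladder 0.1, 0.6, 2.1, 3.7, 5.2, 6.9 JND
#' (contrast to the rewarded red disc), a detection series calibrated to
#' 1.0, 1.7, 3.1, 4.8, 6.3, 6.8 JND against the grey background, Fellows
#' reward schedules, and two simulated observers whose true thresholds
#' follow linear background-contrast corrections (slopes 0.257 and 0.263
#' with 1-JND crossings 1.48 and 3.94) floored at 1 JND, with detection
#' thresholds of 2.7 and 3.0 JND. Thirty choices per contrast level.
#'
#' @param seed Integer seed controlling every random draw.
#' @param trials_per_level Trials per contrast level.
#' @param vs Optional `rnl_visual_system`; default is the packaged zebra
#'   finch-like configuration.
#' @return List with `vs`, `monitor`, `backgrounds`, `rewarded`, `series`,
#'   `detection_series`, `background_contrasts`, `observers`, `trials`,
#'   `schedule`.
#' @export
simulate_experiment <- function(seed = 1L, trials_per_level = 30L, vs = NULL) {
  if (is.null(vs)) {
    vs <- read_visual_system(system.file("extdata", "zebra_finch_vs.yaml",
                                         package = "rnlcolour"))
  }
  mon <- monitor_model()
  sp <- lapply(.STUDY_DRIVES, synth_spectrum, model = mon)
  backgrounds <- list(grey = sp$bg_grey, bright_grey = sp$bg_grey_brt,
                      yellow = sp$bg_yellow, green = sp$bg_green,
                      medium_red = sp$bg_medred)
  disc_targets <- c(0.1, 0.6, 2.1, 3.7, 5.2, 6.9)
  det_targets <- c(1.0, 1.7, 3.1, 4.8, 6.3, 6.8)

  series <- make_saturation_series(sp$grey_disc, sp$red_disc, vs,
                                   backgrounds$grey, targets = disc_targets)
  # detection: single discs scored against the background itself
  jnd_to_bg <- function(w) stimulus_background_contrast(
    mix_spectra(sp$grey_disc, sp$red_disc, w), backgrounds$grey, vs)
  det_weights <- vapply(det_targets, function(t)
    stats::uniroot(function(w) jnd_to_bg(w) - t, c(0, 1), tol = 1e-10)$root,
    numeric(1))
  detection_series <- list(
    spectra = lapply(det_weights, function(w) mix_spectra(sp$grey_disc, sp$red_disc, w)),
    jnd_to_background = vapply(det_weights, jnd_to_bg, numeric(1)),
    mix_weights = det_weights)

  bg_contrasts <- vapply(backgrounds, function(bg)
    stimulus_background_contrast(sp$red_disc, bg, vs), numeric(1))

  crit <- binomial_criterion(trials_per_level, 0.5, 0.05)$proportion
  observers <- list(
    y77 = list(line = threshold_model(0.257, crossing = 1.48),
               detection_threshold = 2.7, b = 0.8, lapse = 0.02),
    y82 = list(line = threshold_model(0.263, crossing = 3.94),
               detection_threshold = 3.0, b = 0.8, lapse = 0.02))

  trials <- list()
  sched <- list()
  i <- 0L
  for (sub in names(observers)) {
    ob <- observers[[sub]]
    for (bgname in names(backgrounds)) {
      i <- i + 1L
      t_true <- predict_threshold(ob$line, bg_contrasts[[bgname]])
      a <- observer_position_for_threshold(t_true, ob$b, ob$lapse,
                                           criterion = crit)
      so <- simulated_observer(a, ob$b, ob$lapse)
      d <- simulate_session(so, disc_targets, trials_per_level,
                            seed = seed + 131L * i)
      d$subject <- sub; d$background <- bgname; d$task <- "discrimination"
      trials[[length(trials) + 1L]] <- d
      sched[[paste(sub, bgname, sep = ".")]] <-
        fellows_schedule(trials_per_level * length(disc_targets),
                         max_run = 4L, seed = seed + 977L * i)
    }
    # detection series on the grey background
    i <- i + 1L
    a <- observer_position_for_threshold(ob$detection_threshold, ob$b,
                                         ob$lapse, criterion = crit)
    so <- simulated_observer(a, ob$b, ob$lapse)
    d <- simulate_session(so, det_targets, trials_per_level,
                          seed = seed + 131L * i)
    d$subject <- sub; d$background <- "grey_detection"; d$task <- "detection"
    trials[[length(trials) + 1L]] <- d
  }

  list(vs = vs, monitor = mon, backgrounds = backgrounds,
       rewarded = sp$red_disc, series = series,
       detection_series = detection_series,
       background_contrasts = bg_contrasts,
       observers = observers,
       trials = do.call(rbind, trials),
       schedule = sched,
       criterion = crit,
       seed = seed)
}

#' Write a simulated experiment to disk as plain-text fixtures
#'
#' Emits spectra CSVs, the trial table, the reward schedules and a
#' `config.yaml` consumable by [run_full_analysis()].
#'
#' @param experiment Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The config file path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spectra_dir <- file.path(dir, "spectra")
  dir.create(spectra_dir, showWarnings = FALSE)
  for (nm in names(experiment$backgrounds))
    write_spectrum(experiment$backgrounds[[nm]],
                   file.path(spectra_dir, paste0("background_", nm, ".csv")))
  write_spectrum(experiment$rewarded, file.path(spectra_dir, "rewarded.csv"))
  utils::write.csv(experiment$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  sched_df <- data.frame(
    session = rep(names(experiment$schedule),
                  vapply(experiment$schedule, length, integer(1))),
    trial = unlist(lapply(experiment$schedule, seq_along), use.names = FALSE),
    side = unlist(experiment$schedule, use.names = FALSE))
  utils::write.csv(sched_df, file.path(dir, "schedule.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- list(
    visual_system = "visual_system.yaml",
    backgrounds = as.list(stats::setNames(
      paste0("spectra/background_", names(experiment$backgrounds), ".csv"),
      names(experiment$backgrounds))),
    rewarded_stimulus = "spectra/rewarded.csv",
    trials = "trials.csv",
    detection_background = "grey_detection",
    criterion = "auto")
  file.copy(system.file("extdata", "zebra_finch_vs.yaml", package = "rnlcolour"),
            file.path(dir, "visual_system.yaml"), overwrite = TRUE)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
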