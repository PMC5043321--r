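#' Assemble a threshold-vs-background-contrast point
#'
#' @param subject Subject identifier.
#' @param task `"discrimination"` or `"detection"`.
#' @param background_contrast_jnd JND contrast between the rewarded stimulus
#'   and the adapting background (0 for detection at the background
#'   chromaticity).
#' @param threshold_jnd Behavioural threshold in JND.
#' @return One-row data frame; rows from several calls can be `rbind`-ed.
#' @export
threshold_point <- function(subject, task, background_contrast_jnd,
                            threshold_jnd) {
  task <- match.arg(task, c("discrimination", "detection"))
  if (background_contrast_jnd < 0 || threshold_jnd < 0)
    stop("contrasts and thresholds must be non-negative", call. = FALSE)
  data.frame(subject = subject, task = task,
             background_contrast_jnd = background_contrast_jnd,
             threshold_jnd = threshold_jnd)
}

#' Construct a threshold model from known line parameters
#'
#' Useful for working with published slope/intercept (or slope/crossing)
#' pairs without refitting.
#'
#' @param slope Line slope (JND threshold per JND background contrast).
#' @param intercept Intercept in JND; supply either this or `crossing`.
#' @param crossing Background contrast at which the line crosses 1 JND;
#'   `intercept` is then back-derived as `1 - slope * crossing`.
#' @return An object of class `threshold_model`.
#' @export
threshold_model <- function(slope, intercept = NULL, crossing = NULL) {
  if (is.null(intercept) && is.null(crossing))
    stop("supply intercept or crossing", call. = FALSE)
  if (is.null(intercept)) intercept <- 1 - slope * crossing
  one_jnd <- if (slope != 0) (1 - intercept) / slope else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 one_jnd_crossing = one_jnd,
                 r_squared = NA_real_, pearson_p = NA_real_,
                 n_points = NA_integer_),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> threshold = %.4f + %.4f * background contrast\n",
              x$intercept, x$slope))
  cat(sprintf("  1-JND crossing at %.3f JND background contrast", x$one_jnd_crossing))
  if (!is.na(x$r_squared))
    cat(sprintf("; R^2 = %.3f, Pearson p = %.4g (n = %d)",
                x$r_squared, x$pearson_p, x$n_points))
  cat("\n")
  invisible(x)
}

#' Fit the linear threshold-vs-background-contrast model
#'
#' Ordinary least squares of discrimination thresholds on background
#' contrast. Detection points (the zero-pedestal regime of the dipper
#' function) are excluded: the line describes the rising, modest-to-strong
#' background-contrast regime only. Reports R-squared, the two-sided Pearson
#' correlation p-value (t transform), and the background contrast at which
#' the fitted line crosses the 1 JND floor.
#'
#' @param points Data frame with columns `task`, `background_contrast_jnd`,
#'   `threshold_jnd` (see [threshold_point()]).
#' @return A `threshold_model`.
#' @export
fit_threshold_line <- function(points) {
  d <- points[points$task == "discrimination", , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 discrimination points", call. = FALSE)
  x <- d$background_contrast_jnd; y <- d$threshold_jnd
  if (stats::sd(x) == 0)
    stop("zero variance in background contrast", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  m <- threshold_model(slope = unname(stats::coef(fit)[2L]),
                       intercept = unname(stats::coef(fit)[1L]))
  m$r_squared <- stats::cor(x, y)^2
  m$pearson_p <- ct$p.value
  m$n_points <- nrow(d)
  m
}

#' Background-corrected threshold prediction
#'
#' Predicted discrimination threshold at a given stimulus-background
#' contrast: the fitted line, floored at 1 JND (the theoretical limit of the
#' receptor-noise model — below the crossing the line would predict
#' impossibly low thresholds, and the dip region is deliberately not
#' modelled).
#'
#' @param model A `threshold_model`.
#' @param background_contrast Background contrast(s) in JND (>= 0).
#' @return Predicted threshold(s) in JND, never below 1.
#' @export
predict_threshold <- function(model, background_contrast) {
  stopifnot(inherits(model, "threshold_model"))
  if (any(background_contrast < 0))
    stop("background contrast must be non-negative", call. = FALSE)
  pmax(1, model$intercept + model$slope * background_contrast)
}

#' Dipper-function summary
#'
#' Compares the detection threshold (zero background contrast) with the
#' minimum discrimination threshold. A ratio above 1 — detection harder than
#' the best discrimination — is the signature dip of the threshold-versus-
#' pedestal function.
#'
#' @param points Data frame of threshold points containing at least one
#'   detection and two discrimination rows.
#' @return List with `detection_threshold` (mean over detection points),
#'   `min_discrimination`, `ratio` and logical `dip`.
#' @export
dipper_summary <- function(points) {
  det <- points$threshold_jnd[points$task == "detection"]
  dis <- points$threshold_jnd[points$task == "discrimination"]
  if (length(det) < 1L || length(dis) < 2L)
    stop("need >= 1 detection and >= 2 discrimination thresholds", call. = FALSE)
  detection <- mean(det)
  min_dis <- min(dis)
  list(detection_threshold = detection,
       min_discrimination = min_dis,
       ratio = detection / min_dis,
       dip = min_dis < detection)
}
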