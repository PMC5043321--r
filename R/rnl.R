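#' Quantum catch of one receptor
#'
#' Trapezoid integral of sensitivity times quantum radiance over the
#' overlapping wavelength range (canonically 300-700 nm). The catch is on an
#' arbitrary scale; only ratios and adapted catches matter downstream.
#'
#' @param R `rnl_spectrum[sensitivity]`.
#' @param L `rnl_spectrum[quantum_radiance]`.
#' @return Non-negative scalar.
#' @export
quantum_catch <- function(R, L) {
  assert_role(R, "sensitivity")
  assert_role(L, "quantum_radiance")
  grid <- common_grid(R, L)
  pracma::trapz(grid, resample(R, grid)$value * resample(L, grid)$value)
}

catches_raw <- function(vs, stim) {
  vapply(vs$sensitivities, quantum_catch, numeric(1), L = stim)
}

#' von Kries adaptation coefficients for a background
#'
#' One gain per receptor, \eqn{k_i = 1 / \int R_i(\lambda) L_b(\lambda)
#' d\lambda}, so that the adapting background itself yields unit catch in
#' every receptor.
#'
#' @param vs An `rnl_visual_system`.
#' @param background `rnl_spectrum[quantum_radiance]`.
#' @return Named numeric vector `k` over UVS, SWS, MWS, LWS.
#' @export
adaptation_coefficients <- function(vs, background) {
  stopifnot(inherits(vs, "rnl_visual_system"))
  bg <- catches_raw(vs, background)
  if (any(bg <= 0))
    stop("degenerate background: zero quantum catch in receptor(s) ",
         paste(names(bg)[bg <= 0], collapse = ", "), call. = FALSE)
  1 / bg
}

#' Quantum catches of a stimulus, optionally background-adapted
#'
#' @param vs An `rnl_visual_system`.
#' @param stim `rnl_spectrum[quantum_radiance]`.
#' @param background Optional adapting background
#'   (`rnl_spectrum[quantum_radiance]`); when supplied, catches are scaled by
#'   the von Kries coefficients of that background.
#' @param background_id Label stored with the catch set.
#' @return An object of class `rnl_catch_set`: named catches `Q`, logical
#'   `adapted`, and `background_id`.
#' @export
quantum_catches <- function(vs, stim, background = NULL,
                            background_id = if (is.null(background)) NA_character_ else "background") {
  Q <- catches_raw(vs, stim)
  adapted <- !is.null(background)
  if (adapted) Q <- Q * adaptation_coefficients(vs, background)
  structure(list(Q = Q, adapted = adapted, background_id = background_id),
            class = "rnl_catch_set")
}

#' @export
print.rnl_catch_set <- function(x, ...) {
  cat("<rnl_catch_set>", if (x$adapted) sprintf("adapted to '%s'", x$background_id)
      else "unadapted", "\n")
  print(x$Q)
  invisible(x)
}

#' Relative quantum catches (chromaticity coordinates)
#'
#' \eqn{q_i = Q_i / \sum_j Q_j}; intensity is discarded and the four
#' coordinates sum to one.
#'
#' @param catches An `rnl_catch_set` or a named non-negative vector.
#' @return Named numeric vector summing to 1.
#' @export
relative_catches <- function(catches) {
  Q <- if (inherits(catches, "rnl_catch_set")) catches$Q else catches
  if (any(Q < 0)) stop("catches must be non-negative", call. = FALSE)
  s <- sum(Q)
  if (s <= 0) stop("all quantum catches are zero", call. = FALSE)
  Q / s
}

#' Receptor-specific contrast between two stimuli
#'
#' \eqn{\Delta f_i = \ln(Q_{i,1} / Q_{i,2})} per receptor. Both catch sets
#' must be adapted to the same background (or both unadapted).
#'
#' @param c1,c2 `rnl_catch_set` objects (or named positive vectors).
#' @return Named numeric vector of log catch ratios.
#' @export
receptor_contrast <- function(c1, c2) {
  get_q <- function(x) if (inherits(x, "rnl_catch_set")) x$Q else x
  if (inherits(c1, "rnl_catch_set") && inherits(c2, "rnl_catch_set")) {
    if (!identical(c1$adapted, c2$adapted) ||
        !identical(c1$background_id, c2$background_id))
      stop("catch sets are adapted to different backgrounds", call. = FALSE)
  }
  Q1 <- get_q(c1); Q2 <- get_q(c2)
  if (any(Q1 <= 0) || any(Q2 <= 0))
    stop("receptor contrast requires strictly positive catches", call. = FALSE)
  log(Q1 / Q2)
}

#' Limiting Weber fractions from an LWS anchor and cone abundances
#'
#' Receptor noise is anchored by the Weber fraction of the most abundant
#' (LWS) mechanism; the single-cone noise-to-signal ratio v follows from
#' \eqn{\omega_{LWS} = v / \sqrt{\eta_{LWS}}} and each mechanism gets
#' \eqn{\omega_i = v / \sqrt{\eta_i}} (noise averages over the cones of a
#' receptive field). `scaling = "linear"` uses \eqn{v / \eta_i} instead.
#'
#' @param weber_lws Weber fraction of the LWS mechanism (> 0).
#' @param abundances Named positive vector of relative cone abundances.
#' @param scaling `"sqrt"` (default) or `"linear"`.
#' @return Named numeric vector of Weber fractions, class `rnl_noise`.
#' @export
weber_fractions <- function(weber_lws = 0.1,
                            abundances = c(UVS = 1, SWS = 1.5, MWS = 2, LWS = 3),
                            scaling = c("sqrt", "linear")) {
  scaling <- match.arg(scaling)
  if (weber_lws <= 0) stop("weber_lws must be positive", call. = FALSE)
  if (any(abundances <= 0)) stop("abundances must be positive", call. = FALSE)
  f <- if (scaling == "sqrt") sqrt else identity
  v <- weber_lws * f(abundances[["LWS"]])
  omega <- v / f(abundances)
  structure(omega, class = "rnl_noise")
}

#' Tetrachromatic receptor-noise-limited colour distance
#'
#' Closed form of the RNL model for four receptor channels:
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\omega_k \omega_l)^2 (\Delta f_i -
#' \Delta f_j)^2}{\sum_k (\prod_{i \ne k} \omega_i)^2}}
#' where for each receptor pair (i, j) the weight uses the two remaining
#' receptors (k, l). The result is in JND units: 1 JND is the discrimination
#' threshold. Pure intensity shifts (equal \eqn{\Delta f} in all receptors)
#' give 0.
#'
#' @param df Named numeric vector of receptor contrasts
#'   (UVS, SWS, MWS, LWS), as from [receptor_contrast()].
#' @param noise Named Weber fractions, as from [weber_fractions()].
#' @return Non-negative scalar (JND).
#' @export
delta_S <- function(df, noise) {
  df <- df[RECEPTORS]; w <- unclass(noise)[RECEPTORS]
  if (anyNA(df) || length(df) != 4L)
    stop("the tetrachromatic closed form needs contrasts for exactly UVS, SWS, MWS, LWS",
         call. = FALSE)
  if (anyNA(w) || any(w <= 0))
    stop("noise model must provide positive Weber fractions for all four receptors",
         call. = FALSE)
  u <- w[["UVS"]]; s <- w[["SWS"]]; m <- w[["MWS"]]; l <- w[["LWS"]]
  fU <- df[["UVS"]]; fS <- df[["SWS"]]; fM <- df[["MWS"]]; fL <- df[["LWS"]]
  num <- (u * s)^2 * (fL - fM)^2 +
         (u * m)^2 * (fL - fS)^2 +
         (u * l)^2 * (fM - fS)^2 +
         (s * m)^2 * (fL - fU)^2 +
         (s * l)^2 * (fM - fU)^2 +
         (m * l)^2 * (fS - fU)^2
  den <- (u * s * m)^2 + (u * s * l)^2 + (u * m * l)^2 + (s * m * l)^2
  sqrt(num / den)
}

#' RNL colour distance for any number of receptors
#'
#' The chromatic RNL distance is the noise-weighted distance of the contrast
#' vector from the achromatic (equal-shift) axis:
#' \eqn{\Delta S^2 = \min_c \sum_i (\Delta f_i - c)^2 / \omega_i^2}, solved
#' in closed form by the precision-weighted mean. Agrees with [delta_S()]
#' for four receptors.
#'
#' @param df Numeric vector of receptor contrasts (any length >= 2).
#' @param omega Positive Weber fractions, same length.
#' @return Non-negative scalar (JND).
#' @export
delta_S_general <- function(df, omega) {
  omega <- unclass(omega)
  if (length(df) != length(omega) || length(df) < 2L)
    stop("df and omega must have equal length >= 2", call. = FALSE)
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  w <- 1 / omega^2
  cc <- sum(w * df) / sum(w)
  sqrt(sum(w * (df - cc)^2))
}

#' Michelson contrast between two double-cone catches
#'
#' \eqn{C = (Q_{max} - Q_{min}) / (Q_{max} + Q_{min})}, the achromatic
#' contrast of the double-cone channel; symmetric in argument order and
#' invariant to common scaling.
#'
#' @param qd1,qd2 Non-negative double-cone quantum catches, not both zero.
#' @return Contrast in [0, 1].
#' @export
michelson_contrast <- function(qd1, qd2) {
  if (qd1 < 0 || qd2 < 0) stop("catches must be non-negative", call. = FALSE)
  if (qd1 + qd2 == 0) stop("both catches are zero", call. = FALSE)
  (max(qd1, qd2) - min(qd1, qd2)) / (qd1 + qd2)
}

#' Double-cone quantum catch of a stimulus
#'
#' @param vs An `rnl_visual_system` with a double-cone sensitivity.
#' @param stim `rnl_spectrum[quantum_radiance]`.
#' @return Scalar catch.
#' @export
double_cone_catch <- function(vs, stim) {
  stopifnot(inherits(vs, "rnl_visual_system"))
  if (is.null(vs$double_cone))
    stop("visual system has no double-cone sensitivity", call. = FALSE)
  quantum_catch(vs$double_cone, stim)
}

#' JND colour contrast between two stimuli under background adaptation
#'
#' Composition of the full chromatic pipeline: von Kries adaptation to the
#' background, quantum catches, receptor contrasts, and the tetrachromatic
#' RNL distance.
#'
#' @param vs An `rnl_visual_system`.
#' @param stim1,stim2 `rnl_spectrum[quantum_radiance]` stimuli.
#' @param background Adapting background (`rnl_spectrum[quantum_radiance]`).
#' @return JND distance (scalar).
#' @export
colour_contrast <- function(vs, stim1, stim2, background) {
  c1 <- quantum_catches(vs, stim1, background)
  c2 <- quantum_catches(vs, stim2, background)
  delta_S(receptor_contrast(c1, c2), vs$omega)
}

#' JND contrast between a stimulus and the background it sits on
#'
#' The background-contrast axis of the threshold analysis: the RNL distance
#' between a stimulus and the adapting background, with receptors adapted to
#' that background.
#'
#' @param stim `rnl_spectrum[quantum_radiance]`.
#' @param background `rnl_spectrum[quantum_radiance]`.
#' @param vs An `rnl_visual_system`.
#' @return JND distance (scalar).
#' @export
stimulus_background_contrast <- function(stim, background, vs) {
  colour_contrast(vs, stim, background, background)
}
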