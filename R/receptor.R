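#' Visual pigment absorbance from the A1 rhodopsin template
#'
#' Govardovskii-type A1 template: an alpha band
#' \deqn{\alpha(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with \eqn{x = \lambda_{max}/\lambda}, A = 69.7, B = 28, C = -14.9,
#' D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}},
#' plus a Gaussian beta band with amplitude 0.26 peaking at
#' \eqn{189 + 0.315\,\lambda_{max}} nm with bandwidth
#' \eqn{-40.5 + 0.195\,\lambda_{max}} nm. The sum is normalized so the value
#' at `lambda_max` is exactly 1.
#'
#' @param lambda_max Peak wavelength in nm (300-700).
#' @param grid Wavelength grid (nm); must contain `lambda_max` in its range.
#' @param beta Include the beta band (default `TRUE`).
#' @return An `rnl_spectrum` with `unit_role = "sensitivity"`.
#' @export
pigment_absorbance <- function(lambda_max, grid = canonical_grid(), beta = TRUE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      lambda_max < 300 || lambda_max > 700)
    stop("lambda_max must be a single wavelength in [300, 700] nm", call. = FALSE)
  if (lambda_max < min(grid) || lambda_max > max(grid))
    stop("lambda_max lies outside the wavelength grid", call. = FALSE)
  template <- function(lambda) {
    x <- lambda_max / lambda
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
    if (beta) {
      lmb <- 189 + 0.315 * lambda_max
      bwb <- -40.5 + 0.195 * lambda_max
      alpha <- alpha + 0.26 * exp(-((lambda - lmb) / bwb)^2)
    }
    alpha
  }
  v <- template(grid) / template(lambda_max)
  spectrum(grid, v, "sensitivity")
}

#' Oil-droplet transmittance as a long-pass cut-off filter
#'
#' Avian cone oil droplets act as long-pass filters in front of the visual
#' pigment. Variants: `"exponential_cutoff"` is a Gompertz sigmoid
#' \eqn{T(\lambda) = \exp(-\exp(-s(\lambda - \lambda_{cut})))}, smooth,
#' monotone non-decreasing, 0 far below and 1 far above the cut-off;
#' `"hard_step"` is 0 below `lambda_cut` and 1 at or above it; `"none"`
#' returns unit transmittance (UVS/VS droplets are unpigmented).
#'
#' @param lambda_cut Cut-off wavelength in nm (ignored for `"none"`).
#' @param slope Steepness in nm^-1 (>= 0; exponential variant only).
#' @param grid Wavelength grid (nm).
#' @param variant One of `"exponential_cutoff"`, `"hard_step"`, `"none"`.
#' @return An `rnl_spectrum` with `unit_role = "transmittance"`.
#' @export
droplet_transmittance <- function(lambda_cut, slope = 0.08,
                                  grid = canonical_grid(),
                                  variant = c("exponential_cutoff",
                                              "hard_step", "none")) {
  variant <- match.arg(variant)
  if (variant == "none")
    return(spectrum(grid, rep(1, length(grid)), "transmittance"))
  if (!is.numeric(lambda_cut) || length(lambda_cut) != 1L)
    stop("lambda_cut must be a single wavelength", call. = FALSE)
  if (variant == "hard_step") {
    v <- as.numeric(grid >= lambda_cut)
  } else {
    if (slope < 0) stop("slope must be non-negative", call. = FALSE)
    v <- exp(-exp(-slope * (grid - lambda_cut)))
  }
  spectrum(grid, v, "transmittance")
}

#' Default ocular media transmittance template
#'
#' A smooth synthetic stand-in for measured ocular media transmittance of a
#' small passerine eye: a logistic rise through the near-UV,
#' \eqn{T(\lambda) = 1/(1 + e^{-(\lambda - \lambda_{50})/s})}, essentially
#' transparent above ~400 nm. This is a labelled synthetic template, not a
#' measurement; supply your own table for quantitative work on a real eye.
#'
#' @param grid Wavelength grid (nm).
#' @param lambda_50 Wavelength of half-maximal transmittance (nm).
#' @param slope_nm Logistic width parameter (nm).
#' @return An `rnl_spectrum` with `unit_role = "transmittance"`.
#' @export
ocular_media_default <- function(grid = canonical_grid(), lambda_50 = 325,
                                 slope_nm = 12) {
  v <- 1 / (1 + exp(-(grid - lambda_50) / slope_nm))
  spectrum(grid, v, "transmittance")
}

#' Cone spectral sensitivity
#'
#' Pointwise product of pigment absorbance, oil-droplet transmittance and
#' ocular media transmittance (self-screening is treated as negligible, so
#' the sensitivity is exactly this triple product). Operands are resampled to
#' their coarsest common grid first.
#'
#' @param pigment `rnl_spectrum[sensitivity]`.
#' @param droplet `rnl_spectrum[transmittance]`, or `NULL` for an unpigmented
#'   droplet (identity filter).
#' @param ocular `rnl_spectrum[transmittance]`, or `NULL` for none.
#' @return An `rnl_spectrum` with `unit_role = "sensitivity"`.
#' @export
cone_sensitivity <- function(pigment, droplet = NULL, ocular = NULL) {
  assert_role(pigment, "sensitivity")
  grid <- pigment$wl
  v <- pigment$value
  for (filt in list(droplet, ocular)) {
    if (is.null(filt)) next
    assert_role(filt, "transmittance")
    grid2 <- common_grid(spectrum(grid, v, "sensitivity"), filt)
    v <- resample(spectrum(grid, v, "sensitivity"), grid2)$value *
      resample(filt, grid2)$value
    grid <- grid2
  }
  spectrum(grid, v, "sensitivity")
}

RECEPTORS <- c("UVS", "SWS", "MWS", "LWS")

#' Assemble a tetrachromatic visual system
#'
#' @param sensitivities Named list of four `rnl_spectrum[sensitivity]` objects
#'   (`UVS`, `SWS`, `MWS`, `LWS`), the single-cone sensitivities.
#' @param double_cone Optional `rnl_spectrum[sensitivity]` for the double
#'   cone, used only by the achromatic (Michelson) channel.
#' @param weber_lws Limiting Weber fraction of the LWS mechanism (> 0).
#' @param abundances Named positive vector of relative cone abundances per
#'   receptive field, in receptor order.
#' @param noise_scaling Passed to [weber_fractions()].
#' @return An object of class `rnl_visual_system` with elements
#'   `sensitivities`, `double_cone`, `weber_lws`, `abundances`, `omega`.
#' @export
visual_system <- function(sensitivities, double_cone = NULL, weber_lws = 0.1,
                          abundances = c(UVS = 1, SWS = 1.5, MWS = 2, LWS = 3),
                          noise_scaling = c("sqrt", "linear")) {
  noise_scaling <- match.arg(noise_scaling)
  if (!setequal(names(sensitivities), RECEPTORS))
    stop("sensitivities must be named UVS, SWS, MWS, LWS", call. = FALSE)
  sensitivities <- sensitivities[RECEPTORS]
  for (s in sensitivities) assert_role(s, "sensitivity")
  if (!is.null(double_cone)) assert_role(double_cone, "sensitivity")
  if (!setequal(names(abundances), RECEPTORS))
    stop("abundances must be named UVS, SWS, MWS, LWS", call. = FALSE)
  abundances <- abundances[RECEPTORS]
  if (any(abundances <= 0)) stop("abundances must be positive", call. = FALSE)
  if (weber_lws <= 0) stop("weber_lws must be positive", call. = FALSE)
  omega <- weber_fractions(weber_lws, abundances, scaling = noise_scaling)
  structure(list(sensitivities = sensitivities, double_cone = double_cone,
                 weber_lws = weber_lws, abundances = abundances,
                 omega = omega, noise_scaling = noise_scaling),
            class = "rnl_visual_system")
}

#' @export
print.rnl_visual_system <- function(x, ...) {
  cat("<rnl_visual_system>\n")
  cat("  receptors:", paste(RECEPTORS, collapse = ", "),
      if (!is.null(x$double_cone)) "(+ double cone)" else "", "\n")
  cat("  omega:", paste(sprintf("%s=%.4f", RECEPTORS, x$omega), collapse = ", "), "\n")
  invisible(x)
}

#' Build a visual system from a YAML configuration
#'
#' The config holds pigment peaks, droplet cut-offs/slopes, an ocular media
#' source (`default`, or a CSV path relative to the config file), the LWS
#' Weber fraction and cone abundances. Alternatively a `sensitivity_dir`
#' entry names a directory of tabulated per-cone sensitivity CSVs
#' (`UVS.csv`, ..., `LWS.csv`, optionally `double.csv`), bypassing the
#' template model entirely.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "zebra_finch_vs.yaml", package = "rnlcolour")`.
#' @param grid Wavelength grid for template-built sensitivities.
#' @return An `rnl_visual_system`.
#' @export
read_visual_system <- function(path, grid = canonical_grid()) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  weber_lws <- cfg$weber_lws %||% 0.1
  ab <- cfg$abundances %||% list(UVS = 1, SWS = 1.5, MWS = 2, LWS = 3)
  abundances <- vapply(RECEPTORS, function(r) as.numeric(ab[[r]]), numeric(1))
  scaling <- cfg$noise_scaling %||% "sqrt"

  if (!is.null(cfg$sensitivity_dir)) {
    dir <- file.path(base, cfg$sensitivity_dir)
    sens <- lapply(RECEPTORS, function(r)
      read_spectrum(file.path(dir, paste0(r, ".csv")), "sensitivity"))
    names(sens) <- RECEPTORS
    dc_path <- file.path(dir, "double.csv")
    dc <- if (file.exists(dc_path)) read_spectrum(dc_path, "sensitivity") else NULL
    return(visual_system(sens, dc, weber_lws, abundances,
                         noise_scaling = scaling))
  }

  ocular <- if (is.null(cfg$ocular) || identical(cfg$ocular, "default")) {
    ocular_media_default(grid)
  } else {
    resample(read_spectrum(file.path(base, cfg$ocular), "transmittance"),
             grid, fill = NULL)
  }
  build_cone <- function(entry) {
    pig <- pigment_absorbance(as.numeric(entry$lambda_max), grid)
    drop <- if (is.null(entry$lambda_cut)) {
      droplet_transmittance(NA, grid = grid, variant = "none")
    } else {
      droplet_transmittance(as.numeric(entry$lambda_cut),
                            slope = as.numeric(entry$slope %||% 0.08),
                            grid = grid)
    }
    cone_sensitivity(pig, drop, ocular)
  }
  sens <- lapply(RECEPTORS, function(r) build_cone(cfg$cones[[r]]))
  names(sens) <- RECEPTORS
  dc <- if (!is.null(cfg$double_cone)) build_cone(cfg$double_cone) else NULL
  visual_system(sens, dc, weber_lws, abundances, noise_scaling = scaling)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
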