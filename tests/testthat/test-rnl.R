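test_that("quantum catch is a trapezoid integral, linear in the stimulus", {
  R <- flat_spectrum(0.5, "sensitivity")
  L <- flat_spectrum(2, "quantum_radiance")
  expect_equal(quantum_catch(R, L), 400)           # 0.5 * 2 * (700 - 300)
  expect_equal(quantum_catch(R, flat_spectrum(0, "quantum_radiance")), 0)
  L2 <- flat_spectrum(4, "quantum_radiance")
  expect_equal(quantum_catch(R, L2), 2 * quantum_catch(R, L))
  expect_error(quantum_catch(R, flat_spectrum(1, "sensitivity")), "unit_role")
})

test_that("von Kries adaptation normalizes the background to unit catch", {
  vs <- fixture_vs()
  st <- fixture_stimuli()
  q <- quantum_catches(vs, st$bg_grey, st$bg_grey)
  expect_equal(unname(q$Q), rep(1, 4), tolerance = 1e-12)

  # homogeneity: doubling the background halves every coefficient
  bg2 <- spectrum(st$bg_grey$wl, st$bg_grey$value * 2, "quantum_radiance")
  expect_equal(adaptation_coefficients(vs, bg2),
               adaptation_coefficients(vs, st$bg_grey) / 2)

  # a background and itself are zero JND apart
  expect_equal(colour_contrast(vs, st$bg_grey, st$bg_grey, st$bg_grey), 0)

  expect_error(adaptation_coefficients(vs, flat_spectrum(0, "quantum_radiance")),
               "degenerate")
})

test_that("relative catches form chromaticity coordinates summing to one", {
  expect_equal(unname(relative_catches(c(UVS = 1, SWS = 1, MWS = 1, LWS = 1))),
               rep(0.25, 4))
  expect_equal(unname(relative_catches(c(UVS = 0, SWS = 1, MWS = 1, LWS = 2))),
               c(0, 0.25, 0.25, 0.5))
  q <- c(UVS = 0.3, SWS = 1.2, MWS = 2, LWS = 0.9)
  expect_equal(relative_catches(q * 7.3), relative_catches(q))
  expect_equal(sum(relative_catches(q)), 1)
  expect_error(relative_catches(c(UVS = 0, SWS = 0, MWS = 0, LWS = 0)), "zero")
})

test_that("receptor contrast is an antisymmetric log ratio", {
  q1 <- c(UVS = 2, SWS = 1, MWS = 1, LWS = 1)
  q2 <- c(UVS = 1, SWS = 1, MWS = 1, LWS = 1)
  df <- receptor_contrast(q1, q2)
  expect_equal(unname(df), c(log(2), 0, 0, 0))
  expect_equal(receptor_contrast(q2, q1), -df)
  expect_error(receptor_contrast(c(UVS = 0, SWS = 1, MWS = 1, LWS = 1), q2),
               "positive")
})

test_that("Weber fractions follow the square-root abundance convention", {
  om <- weber_fractions(0.1, c(UVS = 1, SWS = 1.5, MWS = 2, LWS = 3))
  expect_equal(unname(unclass(om)),
               c(0.1 * sqrt(3), 0.1 * sqrt(2), 0.1 * sqrt(1.5), 0.1),
               tolerance = 1e-12)
  # equal abundances: all omegas equal the anchor
  expect_equal(unname(unclass(weber_fractions(0.07, c(UVS = 2, SWS = 2, MWS = 2, LWS = 2)))),
               rep(0.07, 4))
  # quadrupling every abundance halves every omega
  om4 <- weber_fractions(0.1 / 2, c(UVS = 4, SWS = 6, MWS = 8, LWS = 12))
  expect_equal(unclass(om4), unclass(om) / 2)
  expect_error(weber_fractions(-0.1), "positive")
  # linear variant
  lin <- weber_fractions(0.1, scaling = "linear")
  expect_equal(unname(unclass(lin)), 0.1 * 3 / c(1, 1.5, 2, 3))
})

test_that("tetrachromatic closed form agrees with the minimization oracle", {
  om_names <- c("UVS", "SWS", "MWS", "LWS")
  set.seed(101)
  worst <- 0
  for (i in 1:10000) {
    df <- stats::setNames(runif(4, -1, 1), om_names)
    om <- stats::setNames(runif(4, 0.05, 0.3), om_names)
    d1 <- delta_S(df, om)
    d2 <- delta_S_oracle(df, om)
    worst <- max(worst, abs(d1 - d2))
  }
  expect_lt(worst, 1e-10)
})

test_that("delta_S is intensity-blind, homogeneous in noise, and a pseudometric", {
  om <- weber_fractions()
  nm <- c("UVS", "SWS", "MWS", "LWS")
  # pure intensity change
  expect_equal(delta_S(stats::setNames(rep(0.37, 4), nm), om), 0)
  set.seed(7)
  for (i in 1:200) {
    df <- stats::setNames(runif(4, -1, 1), nm)
    base <- delta_S(df, om)
    # adding a constant to all contrasts changes nothing
    expect_equal(delta_S(df + 0.83, om), base, tolerance = 1e-12)
    # scaling all omegas by t scales distance by 1/t
    t <- runif(1, 0.5, 3)
    expect_equal(delta_S(df, structure(unclass(om) * t, class = "rnl_noise")),
                 base / t, tolerance = 1e-10)
  }
  # symmetry and triangle inequality on random catch triples
  set.seed(8)
  for (i in 1:200) {
    fx <- stats::setNames(runif(4, -1, 1), nm)
    fy <- stats::setNames(runif(4, -1, 1), nm)
    fz <- stats::setNames(runif(4, -1, 1), nm)
    dxy <- delta_S(fx - fy, om); dyx <- delta_S(fy - fx, om)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_lte(delta_S(fx - fz, om),
               dxy + delta_S(fy - fz, om) + 1e-12)
  }
  expect_error(delta_S(c(UVS = 1, SWS = 0, MWS = 0), om), "exactly")
})

test_that("delta_S_general reduces to the tetrachromatic closed form", {
  nm <- c("UVS", "SWS", "MWS", "LWS")
  om <- weber_fractions()
  set.seed(9)
  for (i in 1:100) {
    df <- stats::setNames(runif(4, -1, 1), nm)
    expect_equal(delta_S_general(df[nm], om[nm]), delta_S(df, om),
                 tolerance = 1e-12)
  }
})

test_that("Michelson contrast is a symmetric bounded ratio", {
  expect_equal(michelson_contrast(3, 3), 0)
  expect_equal(michelson_contrast(3, 1), 0.5)
  expect_equal(michelson_contrast(1, 3), 0.5)
  expect_equal(michelson_contrast(300, 100), 0.5)  # scale invariance
  expect_error(michelson_contrast(0, 0), "zero")
  expect_error(michelson_contrast(-1, 2), "non-negative")
})

test_that("chromatic JNDs are invariant to per-receptor normalization of R_i", {
  vs <- fixture_vs()
  st <- fixture_stimuli()
  # rescale each sensitivity to unit area instead of unit peak
  sens2 <- lapply(vs$sensitivities, function(s)
    spectrum(s$wl, s$value / spectrum_integral(s), "sensitivity"))
  vs2 <- visual_system(sens2, vs$double_cone, vs$weber_lws, vs$abundances)
  expect_equal(colour_contrast(vs2, st$red, st$grey_disc, st$bg_grey),
               colour_contrast(vs, st$red, st$grey_disc, st$bg_grey),
               tolerance = 1e-10)
  expect_equal(stimulus_background_contrast(st$red, st$bg_green, vs2),
               stimulus_background_contrast(st$red, st$bg_green, vs),
               tolerance = 1e-10)
})

test_that("stimulus-background contrast behaves like a chromatic distance", {
  vs <- fixture_vs()
  st <- fixture_stimuli()
  expect_equal(stimulus_background_contrast(st$bg_grey, st$bg_grey, vs), 0)
  # invariant to uniform intensity scaling of the stimulus
  red_dim <- spectrum(st$red$wl, st$red$value * 0.31, "quantum_radiance")
  expect_equal(stimulus_background_contrast(red_dim, st$bg_grey, vs),
               stimulus_background_contrast(st$red, st$bg_grey, vs),
               tolerance = 1e-10)
  # monotone under chromatic exaggeration along a fixed direction in catch
  # space: mixtures moving from the background towards the red disc
  jnds <- vapply(seq(0.1, 1, 0.1), function(w) {
    mix <- spectrum(st$bg_grey$wl,
                    (1 - w) * st$bg_grey$value + w * st$red$value,
                    "quantum_radiance")
    stimulus_background_contrast(mix, st$bg_grey, vs)
  }, numeric(1))
  expect_true(all(diff(jnds) > 0))
})
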