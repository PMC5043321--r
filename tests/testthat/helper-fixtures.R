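# Shared fixtures, built in code at test time.

fixture_vs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- read_visual_system(system.file("extdata", "zebra_finch_vs.yaml",
                                               package = "rnlcolour"))
    cache
  }
})

fixture_monitor <- function() monitor_model()

fixture_stimuli <- function() {
  mon <- fixture_monitor()
  list(red = synth_spectrum(mon, c(0.120, 0.080, 0.900)),
       grey_disc = synth_spectrum(mon, c(0.327, 0.409, 0.387)),
       bg_grey = synth_spectrum(mon, c(0.177, 0.221, 0.209)),
       bg_green = synth_spectrum(mon, c(0.032, 0.385, 0.013)))
}

flat_spectrum <- function(value, role = "quantum_radiance",
                          grid = canonical_grid()) {
  spectrum(grid, rep(value, length(grid)), role)
}

# Numerical minimization oracle for the RNL distance: scalar search for the
# best common (achromatic) shift, independent of the closed form under test.
delta_S_oracle <- function(df, omega) {
  obj <- function(cc) sum((df - cc)^2 / omega^2)
  opt <- stats::optimize(obj, range(df) + c(-1, 1), tol = 1e-12)
  sqrt(obj(opt$minimum))
}
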