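# shared fixtures: small media and fast transport settings for unit tests

fixture_table <- function() default_chromophores()

# homogeneous medium with mua ~ 0.01 mm^-1 at 760 nm, musp 1.0, g 0.9, n 1.4
fixture_homog_layer <- function(water = 0) {
  tissue_layer(Inf, hb_total = 40.69, so2 = 50, water_fraction = water,
               musp_ref = 1.0, musp_slope = 0, g = 0.9, n_refr = 1.4)
}

fixture_homog_medium <- function(water = 0) {
  layered_medium(list(fixture_homog_layer(water)), n_ambient = 1.0)
}

fixture_two_layer <- function(sup_so2 = 70, brain_so2 = 70) {
  make_neonatal_preset(superficial_so2 = sup_so2,
                       brain_so2 = brain_so2)$medium
}

fast_settings <- function(n_photons = 5e4, seed = 1L, ...) {
  transport_settings(n_photons = n_photons, seed = seed, ...)
}
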