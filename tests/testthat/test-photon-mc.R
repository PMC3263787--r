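# The engine tests run at reduced photon counts; statistical assertions use
# the run's own Monte Carlo standard errors.

test_that("identical settings and seed give bit-identical results", {
  med <- fixture_homog_medium()
  tab <- fixture_table()
  st <- fast_settings(n_photons = 2e4, seed = 123)
  a <- run_transport(med, tab, c(760, 850), c(10, 20), st)
  b <- run_transport(med, tab, c(760, 850), c(10, 20), st)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- run_transport(med, tab, c(760, 850), c(10, 20),
                      fast_settings(n_photons = 2e4, seed = 124))
  expect_false(identical(a$reflectance, c_$reflectance))
})

test_that("energy bookkeeping closes to within 1e-6 with absorption and roulette", {
  med <- fixture_homog_medium(water = 0.8)
  st <- fast_settings(n_photons = 2e4, seed = 5, max_pathlength = 500)
  r <- run_transport(med, fixture_table(), c(760, 850), 15, st)
  tot <- attr(r, "totals")
  balance <- tot$specular + tot$diffuse + tot$absorbed + tot$roulette_net +
    tot$cap_killed
  expect_true(all(abs(balance - 1) < 1e-6))
  expect_true(all(tot$absorbed > 0))
})

test_that("a non-absorbing matched-boundary half-space returns all light", {
  lay <- tissue_layer(Inf, 0, 50, 0, musp_ref = 1.0, musp_slope = 0,
                      g = 0, n_refr = 1.0)
  med <- layered_medium(list(lay), n_ambient = 1.0)
  st <- transport_settings(n_photons = 5e3, seed = 42, max_pathlength = 2e7)
  r <- suppressWarnings(run_transport(med, fixture_table(), 760, 10, st))
  tot <- attr(r, "totals")
  expect_identical(tot$specular, 0)
  # SEM of total diffuse reflectance: only pathlength-capped packets differ
  f <- tot$cap_killed
  sem <- sqrt(f * (1 - f) / st$n_photons)
  expect_lt(abs(tot$diffuse - 1), max(3 * sem, 1e-12))
})

test_that("zero detection yields a warning and an empty record, not a crash", {
  med <- fixture_homog_medium()
  st <- fast_settings(n_photons = 1e3, seed = 1)
  expect_warning(r <- run_transport(med, fixture_table(), 760, 80, st),
                 "zero packets")
  expect_identical(r$n_detected, 0)
  expect_identical(r$reflectance, 0)
  expect_error(mean_partial_pathlength(r, 1), "zero")
})

test_that("reflectance decreases with distance beyond 5 mm", {
  med <- fixture_two_layer()
  st <- fast_settings(n_photons = 2e5, seed = 8, max_pathlength = 600)
  r <- run_transport(med, fixture_table(), 760, c(5, 10, 15, 20), st)
  for (i in seq_len(nrow(r) - 1)) {
    gap <- r$reflectance[i] - r$reflectance[i + 1]
    expect_gt(gap, -3 * sqrt(r$sem[i]^2 + r$sem[i + 1]^2))
    expect_gt(gap, 0)
  }
})

test_that("raising brain absorption dims every distance", {
  tab <- fixture_table()
  dark <- fixture_two_layer(brain_so2 = 70)
  # raise brain haemoglobin: more absorber at both wavelengths
  dark$layers[[2]]$hb_total <- 120
  st <- fast_settings(n_photons = 1e5, seed = 21, max_pathlength = 600)
  base <- run_transport(fixture_two_layer(), tab, 760, c(10, 20, 30), st)
  dim <- run_transport(dark, tab, 760, c(10, 20, 30), st)
  expect_true(all(dim$reflectance <
                    base$reflectance +
                    3 * sqrt(dim$sem^2 + base$sem^2)))
  expect_true(all(dim$reflectance < base$reflectance))
})

test_that("partial pathlengths: single layer owns the whole path; deep probes see more brain", {
  med <- fixture_homog_medium()
  st <- fast_settings(n_photons = 5e4, seed = 3, max_pathlength = 600)
  r <- run_transport(med, fixture_table(), 760, c(10, 20), st)
  expect_equal(brain_fraction(r), c(1, 1))
  expect_true(all(mean_partial_pathlength(r, 1) > 0))

  two <- fixture_two_layer()
  r2 <- run_transport(two, fixture_table(), 760, c(11, 35),
                      fast_settings(n_photons = 2e5, seed = 31,
                                    max_pathlength = 800))
  bf <- brain_fraction(r2)
  expect_gt(bf[r2$distance == 35], bf[r2$distance == 11])

  # a superficial layer far thicker than any probing depth starves the brain
  deep_skin <- layered_medium(list(
    tissue_layer(60, 60, 70, 0.7, musp_ref = 1.4, g = 0.9, n_refr = 1.4),
    tissue_layer(Inf, 50, 70, 0.85, musp_ref = 0.7, g = 0.9, n_refr = 1.4)))
  r3 <- run_transport(deep_skin, fixture_table(), 760, 15,
                      fast_settings(n_photons = 5e4, seed = 12,
                                    max_pathlength = 400))
  expect_lt(brain_fraction(r3), 0.01)
})

test_that("white-run reweighting reproduces the absorbing engine", {
  tab <- fixture_table()
  med <- fixture_homog_medium(water = 0.5)
  dists <- c(10, 20)
  st <- fast_settings(n_photons = 1e5, seed = 77, max_pathlength = 800)
  direct <- run_transport(med, tab, 760, dists, st)
  white <- run_transport(med, tab, 760, dists,
                         fast_settings(n_photons = 1e5, seed = 1077,
                                       max_pathlength = 800),
                         white = TRUE)
  rw <- reweight_white(attr(white, "paths")[["760"]],
                       mua(med$layers[[1]], tab, 760), dists,
                       attr(white, "settings"))
  for (k in seq_along(dists)) {
    gap <- abs(rw$reflectance[k] - direct$reflectance[k])
    expect_lt(gap, 3 * sqrt(rw$sem[k]^2 + direct$sem[k]^2))
  }
})

test_that("nonphysical settings are rejected", {
  expect_error(transport_settings(n_photons = 10), "1000")
  expect_error(transport_settings(roulette_survival = 1), "roulette")
  expect_error(transport_settings(detector_half_width = 0), "half_width")
  med <- fixture_homog_medium()
  expect_error(run_transport(med, fixture_table(), 760, c(-5),
                             fast_settings()), "positive")
})
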