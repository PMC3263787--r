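test_that("attenuation slope matches two-point arithmetic and rejects bad input", {
  expect_equal(attenuation_slope(c(11, 18), c(1.0, 1.8)), 0.8 / 7)
  expect_equal(attenuation_slope(c(11, 18), c(1.3, 1.3)), 0)
  # three points on a line: least squares recovers the line's slope
  expect_equal(attenuation_slope(c(10, 20, 30), 0.5 + 0.11 * c(10, 20, 30)),
               0.11)
  expect_error(attenuation_slope(c(11, 11), c(1, 2)), "distinct")
  expect_error(attenuation_slope(11, 1), "two distances")
  expect_error(attenuation_slope(c(11, 18), c(1, Inf)), "finite")
})

test_that("scaled absorption implements the SRS slope-to-mua form", {
  res <- scaled_mua(0.1143, rho_bar = 14.5, musp_assumed = 1.0)
  expect_equal(res$k_mua, (log(10) * 0.1143 - 2 / 14.5)^2 / 3,
               tolerance = 1e-12)
  expect_equal(res$k_mua, 0.00523, tolerance = 1e-3)
  expect_false(res$shallow)
  # boundary: slope exactly at the 2/rho_bar geometric term
  at_zero <- scaled_mua((2 / 20) / log(10), rho_bar = 20, musp_assumed = 1)
  expect_equal(at_zero$k_mua, 0)
  expect_true(at_zero$shallow)
})

test_that("slope on oracle data matches the diffusion asymptote", {
  m <- homogeneous_medium(mua = 0.01, musp = 1.0, n_rel = 1.4)
  rho <- c(28, 32)  # rho_bar = 30
  A <- -log10(diffusion_reflectance(m, rho))
  sl <- attenuation_slope(rho, A)
  expect_equal(log(10) * sl, mueff(m) + 2 / 30, tolerance = 0.03)
})

test_that("saturation inversion hits the pure and mixed endpoints", {
  tab <- default_chromophores()
  pure <- sto2_from_scaled_mua(0.37 * tab$eps_hbo2, tab)
  expect_equal(pure$sto2, 100)
  mixed <- sto2_from_scaled_mua(2.1 * (tab$eps_hbo2 + tab$eps_hhb), tab)
  expect_equal(mixed$sto2, 50)
  # all-deoxy with a sign flip: raw value preserved, flagged when x+y <= 0
  neg <- sto2_from_scaled_mua(-0.5 * (tab$eps_hbo2 + tab$eps_hhb), tab)
  expect_true(neg$flagged)
})

test_that("StO2 is invariant to per-wavelength coupling and to a global scattering scale", {
  tab <- default_chromophores()
  des <- probe_design(5)
  lay <- tissue_layer(Inf, 50, 65, 0, musp_ref = 0.7, musp_slope = 6.3e-4,
                      n_refr = 1.4)
  recs <- do.call(rbind, lapply(c(760, 850), function(wl) {
    hm <- homogeneous_medium(mua(lay, tab, wl), musp(lay, wl), 1.4)
    data.frame(wavelength = wl, distance = c(des$c, des$d),
               reflectance = diffusion_reflectance(hm, c(des$c, des$d)))
  }))
  msp <- musp(lay, c(760, 850))
  ref <- srs_estimate(recs, des, tab, msp)

  # multiply all reflectances at one wavelength by an arbitrary coupling
  scaled <- recs
  scaled$reflectance[scaled$wavelength == 850] <-
    scaled$reflectance[scaled$wavelength == 850] * 17.3
  expect_equal(srs_estimate(scaled, des, tab, msp)$sto2, ref$sto2,
               tolerance = 1e-12)

  # wavelength-independent error in the assumed scattering cancels
  off <- srs_estimate(recs, des, tab, 2.6 * msp)
  expect_equal(off$sto2, ref$sto2, tolerance = 1e-10)
})

test_that("multi-site aggregation reports mean and agreement", {
  agg <- multisite_aggregate(c(60, 62, 64, 66))
  expect_equal(agg$mean, 63)
  expect_equal(agg$range, 6)
  expect_equal(agg$sd, sd(c(60, 62, 64, 66)))
  same <- multisite_aggregate(rep(71.5, 4))
  expect_equal(same$mean, 71.5)
  expect_equal(same$range, 0)
  expect_error(multisite_aggregate(70), "two site values")
})

test_that("site spread shrinks as measurement noise shrinks", {
  des <- probe_design(6)
  spread_at <- function(noise, seed) {
    vals <- vapply(1:4, function(site) {
      syn <- synth_attenuation(des, 70, noise_sd_od = noise,
                               seed = seed + site)
      p <- make_neonatal_preset()
      brain <- p$medium$layers[[2]]
      est <- srs_estimate(syn, des, p$table, musp(brain, c(760, 850)))
      est$sto2
    }, numeric(1))
    multisite_aggregate(vals)$sd
  }
  noises <- c(0.02, 0.005, 0)
  spreads <- vapply(seq_along(noises), function(i) spread_at(noises[i], 40),
                    numeric(1))
  expect_true(all(diff(spreads) < 0))
  expect_equal(spreads[3], 0)
})

test_that("the seven candidate designs are the expected distance pairs", {
  tab <- probe_designs()
  expect_equal(tab$c, c(7, 8, 11, 13, 15, 20, 25))
  expect_equal(tab$d, c(11, 13, 18, 20, 25, 30, 35))
  expect_true(all(tab$c < tab$d))
  expect_error(probe_design(9), "unknown")
  expect_error(probe_design(8, c = 30, d = 20), "0 < c < d")
})
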