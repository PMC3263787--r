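test_that("absorption is the hand-computed chromophore combination", {
  tab <- default_chromophores()
  lay <- tissue_layer(Inf, hb_total = 50, so2 = 70, water_fraction = 0.85,
                      musp_ref = 0.7)
  # spreadsheet-style recomputation on the same constants
  hbo2 <- 50 * 0.70
  hhb <- 50 * 0.30
  expect_equal(mua(lay, tab, 760),
               log(10) * (5.86e-5 * hbo2 + 1.5485e-4 * hhb) + 0.85 * 2.6e-3)
  expect_equal(mua(lay, tab, 850),
               log(10) * (1.058e-4 * hbo2 + 6.913e-5 * hhb) + 0.85 * 4.3e-3)
})

test_that("absorption endpoints behave: empty medium and full saturation", {
  tab <- default_chromophores()
  empty <- tissue_layer(Inf, hb_total = 0, so2 = 50, water_fraction = 0,
                        musp_ref = 1)
  expect_identical(mua(empty, tab, c(760, 850)), c(0, 0))

  sat <- tissue_layer(Inf, hb_total = 40, so2 = 100, water_fraction = 0.5,
                      musp_ref = 1)
  expect_equal(mua(sat, tab, 760),
               log(10) * tab$eps_hbo2[1] * 40 + 0.5 * tab$mua_water[1])
})

test_that("absorption is linear in haemoglobin and convex in saturation", {
  tab <- default_chromophores()
  # linearity in hb_total concerns the haemoglobin term, so no water here
  make <- function(hb, so2, w = 0) tissue_layer(Inf, hb, so2, w,
                                                musp_ref = 1)
  for (wl in c(760, 850)) {
    expect_equal(mua(make(80, 63), tab, wl), 2 * mua(make(40, 63), tab, wl))
    # the convex combination across saturation holds with water present
    s <- 37
    mixed <- s / 100 * mua(make(40, 100, 0.3), tab, wl) +
      (1 - s / 100) * mua(make(40, 0, 0.3), tab, wl)
    expect_equal(mua(make(40, s, 0.3), tab, wl), mixed)
  }
})

test_that("unknown wavelengths and invalid layers are rejected by name", {
  tab <- default_chromophores()
  lay <- tissue_layer(Inf, 50, 70, 0.5, musp_ref = 1)
  expect_error(mua(lay, tab, 800), "800")
  expect_error(tissue_layer(Inf, -1, 70, 0.5, musp_ref = 1), "haemoglobin")
  expect_error(tissue_layer(Inf, 50, 101, 0.5, musp_ref = 1), "so2")
  expect_error(tissue_layer(Inf, 50, 70, 1.2, musp_ref = 1), "water")
})

test_that("reduced scattering follows the linear wavelength model", {
  flat <- tissue_layer(Inf, 50, 70, 0.5, musp_ref = 2.0, musp_slope = 0)
  expect_equal(musp(flat, c(700, 760, 900)), rep(2.0, 3))

  sloped <- tissue_layer(Inf, 50, 70, 0.5, musp_ref = 1.0,
                         musp_slope = 6.3e-4)
  expect_identical(musp(sloped, 760), 1.0)           # reference identity
  expect_equal(musp(sloped, 850), 0.9433)            # 1 - 6.3e-4 * 90
  steep <- tissue_layer(Inf, 50, 70, 0.5, musp_ref = 1.0, musp_slope = 0.02)
  expect_error(musp(steep, 850), "non-positive")
})

test_that("media must end in a semi-infinite layer and only there", {
  l_fin <- tissue_layer(4, 50, 70, 0.5, musp_ref = 1)
  l_inf <- tissue_layer(Inf, 50, 70, 0.5, musp_ref = 1)
  expect_error(layered_medium(list(l_fin)), "semi-infinite")
  expect_error(layered_medium(list(l_inf, l_inf)), "deepest")
  expect_s3_class(layered_medium(list(l_fin, l_inf)), "layered_medium")
})

test_that("degenerate chromophore tables are rejected", {
  expect_error(chromophore_table(c(850, 760), c(1, 1) * 1e-4,
                                 c(1, 1) * 1e-4, c(0, 0)), "increasing")
  expect_error(chromophore_table(c(760, 850), c(1e-4, 1e-4),
                                 c(2e-4, 2e-4), c(0, 0)), "singular")
  expect_error(chromophore_table(c(760, 850), c(-1e-4, 1e-4),
                                 c(2e-4, 1e-4), c(0, 0)), "positive")
})
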