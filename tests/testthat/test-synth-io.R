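test_that("the neonatal preset validates and round-trips through config", {
  p <- make_neonatal_preset()
  expect_s3_class(p$medium, "layered_medium")
  expect_length(p$medium$layers, 2)
  expect_true(is.infinite(p$medium$layers[[2]]$thickness))
  expect_equal(mua(p$medium$layers[[2]], p$table, 760),
               log(10) * (5.86e-5 * 35 + 1.5485e-4 * 15) + 0.85 * 2.6e-3)

  path <- tempfile(fileext = ".yaml")
  write_medium_config(p$medium, p$table, p$wavelengths, path)
  back <- read_medium_config(path)
  expect_equal(back$medium, p$medium)
  expect_equal(back$table, p$table)
  expect_equal(back$wavelengths, p$wavelengths)
  unlink(path)
})

test_that("malformed configs fail with explicit messages", {
  path <- tempfile(fileext = ".yaml")
  writeLines("medium:\n  layers: []\n", path)
  expect_error(read_medium_config(path), "no layers|missing")
  writeLines("wavelengths: [760, 850]\n", path)
  expect_error(read_medium_config(path), "medium")
  unlink(path)
})

test_that("noise-free synthetic attenuation matches the forward model", {
  des <- probe_design(7)
  p <- make_neonatal_preset()
  syn <- synth_attenuation(des, 70, preset = p, noise_sd_od = 0, seed = 1)
  deep <- p$medium$layers[[2]]
  for (wl in p$wavelengths) {
    hm <- homogeneous_medium(mua(deep, p$table, wl), musp(deep, wl), 1.4)
    expect_equal(syn$attenuation[syn$wavelength == wl],
                 -log10(diffusion_reflectance(hm, c(des$c, des$d))))
  }
  # seeded reproducibility of the noisy path
  a <- synth_attenuation(des, 70, noise_sd_od = 0.01, seed = 9)
  b <- synth_attenuation(des, 70, noise_sd_od = 0.01, seed = 9)
  expect_identical(a, b)
})

test_that("estimator scatter grows with the OD noise level", {
  des <- probe_design(7)
  p <- make_neonatal_preset()
  msp <- musp(p$medium$layers[[2]], p$wavelengths)
  est_sd <- function(noise) {
    vals <- vapply(1:60, function(i) {
      syn <- synth_attenuation(des, 70, preset = p, noise_sd_od = noise,
                               seed = 100 + i)
      srs_estimate(syn, des, p$table, msp)$sto2_raw
    }, numeric(1))
    sd(vals)
  }
  s <- vapply(c(0.001, 0.01), est_sd, numeric(1))
  expect_lt(s[1], s[2])
})

test_that("noisy replicates stay centred on the noise-free estimate", {
  des <- probe_design(6)
  p <- make_neonatal_preset()
  msp <- musp(p$medium$layers[[2]], p$wavelengths)
  clean <- srs_estimate(synth_attenuation(des, 70, preset = p), des,
                        p$table, msp)$sto2_raw
  vals <- vapply(1:200, function(i) {
    syn <- synth_attenuation(des, 70, preset = p, noise_sd_od = 0.003,
                             seed = 2000 + i)
    srs_estimate(syn, des, p$table, msp)$sto2_raw
  }, numeric(1))
  expect_lt(abs(mean(vals) - clean), 3 * sd(vals) / sqrt(length(vals)) + 0.2)
})

test_that("simulated trial outcomes have the requested structure", {
  full <- synth_trial_outcomes(500, delta = 5, sd = 15, mortality = 0,
                               seed = 2)
  expect_true(all(full$survived))
  expect_false(anyNA(full$score))

  out <- synth_trial_outcomes(1e5, delta = 5, sd = 15, mortality = 0.2,
                              seed = 3)
  expect_equal(mean(!out$survived), 0.2, tolerance = 0.02)
  means <- tapply(out$score, out$arm, mean, na.rm = TRUE)
  expect_equal(unname(means["intervention"] - means["control"]), 5,
               tolerance = 0.1)
  expect_identical(out, synth_trial_outcomes(1e5, 5, 15, 0.2, seed = 3))
})

test_that("TSV round trip preserves data and metadata", {
  df <- data.frame(a = c(1.5, 2.25), b = c("x", "y"),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_table_tsv(df, path, meta = list(seed = 42, note = "fixture"))
  back <- read_table_tsv(path)
  expect_equal(back$a, df$a)
  expect_equal(back$b, df$b)
  meta <- attr(back, "meta")
  expect_equal(unname(meta["seed"]), "42")
  expect_true(startsWith(unname(meta["package"]), "neonirs"))
  unlink(path)
})
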