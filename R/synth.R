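#' Default neonatal head preset
#'
#' A two-layer head model with optical and physiological parameters chosen
#' from the tissue-optics literature to be typical of a neonate of about
#' 30-31 weeks gestational age: a combined skin/scalp(+skull) superficial
#' layer of 4 mm over a semi-infinite brain.  All values are
#' implementer-chosen defaults (the design experiments are robust to
#' plausible variations) and every one can be overridden through the
#' constructors or the config file.
#'
#' Superficial layer: 4 mm, 60 uM total haemoglobin, SO2 70\%, water
#' fraction 0.70, musp 1.4 mm^-1 at 760 nm.  Brain: semi-infinite, 50 uM,
#' SO2 70\%, water fraction 0.85, musp 0.7 mm^-1 at 760 nm.  Both layers:
#' scattering slope 6.3e-4 per nm, g = 0.9, n = 1.4; ambient n = 1.0.
#'
#' @param superficial_so2,brain_so2 starting saturations, percent.
#' @return list with \code{medium} (\code{\link{layered_medium}}),
#'   \code{table} (\code{\link{chromophore_table}}), \code{wavelengths}
#'   (760 and 850 nm) and \code{reference_wavelength} (760 nm).
#' @export
#' @examples
#' p <- make_neonatal_preset()
#' p$medium
make_neonatal_preset <- function(superficial_so2 = 70, brain_so2 = 70) {
  medium <- layered_medium(list(
    tissue_layer(thickness = 4, hb_total = 60, so2 = superficial_so2,
                 water_fraction = 0.70, musp_ref = 1.4,
                 musp_slope = 6.3e-4, g = 0.9, n_refr = 1.4),
    tissue_layer(thickness = Inf, hb_total = 50, so2 = brain_so2,
                 water_fraction = 0.85, musp_ref = 0.7,
                 musp_slope = 6.3e-4, g = 0.9, n_refr = 1.4)),
    n_ambient = 1.0)
  list(medium = medium, table = default_chromophores(),
       wavelengths = c(760, 850), reference_wavelength = 760)
}

#' Synthesize a noisy multi-distance attenuation record
#'
#' Evaluates a forward model at the two distances of a probe design and all
#' wavelengths for a given brain saturation, converts to attenuation
#' (optical density) and adds independent Gaussian OD noise per channel --
#' the test harness for the SRS estimator.
#'
#' @param design one row of \code{\link{probe_designs}}.
#' @param true_so2_brain percent; applied to the deepest layer.
#' @param preset as returned by \code{\link{make_neonatal_preset}}.
#' @param noise_sd_od standard deviation of the additive OD noise, >= 0.
#' @param seed integer seed.
#' @param forward \code{"diffusion"} (homogeneous closed form from the
#'   deepest layer) or \code{"monte_carlo"}.
#' @param settings \code{\link{transport_settings}} for the Monte Carlo
#'   forward model.
#' @return data frame with columns \code{wavelength}, \code{distance},
#'   \code{attenuation} (OD) and \code{reflectance} (noise applied in OD
#'   space, reflectance back-transformed consistently).
#' @export
synth_attenuation <- function(design, true_so2_brain,
                              preset = make_neonatal_preset(),
                              noise_sd_od = 0, seed = 1L,
                              forward = c("diffusion", "monte_carlo"),
                              settings = transport_settings(n_photons = 1e5,
                                                            seed = seed)) {
  forward <- match.arg(forward)
  if (noise_sd_od < 0) stop("noise_sd_od must be non-negative",
                            call. = FALSE)
  medium <- set_layer_so2(preset$medium, length(preset$medium$layers),
                          true_so2_brain)
  dists <- c(design$c, design$d)
  if (forward == "diffusion") {
    deep <- medium$layers[[length(medium$layers)]]
    recs <- do.call(rbind, lapply(preset$wavelengths, function(wl) {
      hm <- homogeneous_medium(
        mua = mua(deep, preset$table, wl),
        musp = musp(deep, wl, preset$reference_wavelength),
        n_rel = deep$n_refr / medium$n_ambient)
      data.frame(wavelength = wl, distance = dists,
                 reflectance = diffusion_reflectance(hm, dists))
    }))
  } else {
    recs <- run_transport(medium, preset$table, preset$wavelengths, dists,
                          settings, preset$reference_wavelength)
    recs <- as.data.frame(recs)[, c("wavelength", "distance", "reflectance")]
  }
  set.seed(seed)
  A <- -log10(recs$reflectance) + stats::rnorm(nrow(recs), 0, noise_sd_od)
  data.frame(wavelength = recs$wavelength, distance = recs$distance,
             attenuation = A, reflectance = 10^(-A))
}

#' Simulate per-infant outcomes of a two-arm trial
#'
#' Per-infant rows for a randomized trial with mortality and a continuous
#' cognitive score among survivors: survival is Bernoulli(1 - mortality) in
#' both arms, and survivors' scores are normal with a mean difference of
#' \code{delta} favouring the intervention arm.
#'
#' @param n_per_group infants randomized per arm.
#' @param delta true mean score difference (points).
#' @param sd score standard deviation (points).
#' @param mortality probability of death before outcome assessment, [0, 1).
#' @param seed integer seed.
#' @param mean_control mean score in the control arm (points).
#' @return data frame with columns \code{id}, \code{arm}
#'   (\code{"control"}/\code{"intervention"}), \code{survived} (logical),
#'   \code{score} (\code{NA} for non-survivors).
#' @export
synth_trial_outcomes <- function(n_per_group, delta, sd, mortality = 0,
                                 seed = 1L, mean_control = 100) {
  if (mortality < 0 || mortality >= 1)
    stop("mortality must lie in [0, 1)", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  set.seed(seed)
  n <- n_per_group
  arm <- rep(c("control", "intervention"), each = n)
  survived <- stats::runif(2 * n) >= mortality
  score <- rep(NA_real_, 2 * n)
  mu <- ifelse(arm == "intervention", mean_control + delta, mean_control)
  score[survived] <- stats::rnorm(sum(survived), mu[survived], sd)
  data.frame(id = seq_len(2 * n), arm = arm, survived = survived,
             score = score)
}
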