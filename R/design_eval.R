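#' Specify a saturation sweep across probe designs
#'
#' The two design experiments: vary the brain oxygen saturation with the
#' superficial (skin/scalp) saturation fixed, or vary the superficial
#' saturation with the brain fixed, and estimate StO2 with every candidate
#' probe design at each grid point.
#'
#' @param varied_layer \code{"brain"} (deepest layer) or
#'   \code{"superficial"} (surface layer).
#' @param so2_grid percent, >= 2 points in [0, 100].
#' @param fixed_so2 percent, saturation of the non-varied layer.
#' @param designs data frame of designs (default all seven of
#'   \code{\link{probe_designs}}).
#' @param forward \code{"monte_carlo"} (layered transport, white-run
#'   reweighting across the grid) or \code{"diffusion"} (homogeneous
#'   semi-infinite closed form built from the deepest layer -- only
#'   meaningful when the medium is effectively homogeneous).
#' @param replicate_seeds integer seeds for independent Monte Carlo
#'   replicates per design; estimates are averaged across replicates and
#'   their dispersion reported.
#' @return An object of class \code{"sweep_spec"}.
#' @export
sweep_spec <- function(varied_layer = c("brain", "superficial"), so2_grid,
                       fixed_so2 = 70, designs = probe_designs(),
                       forward = c("monte_carlo", "diffusion"),
                       replicate_seeds = 1:3) {
  varied_layer <- match.arg(varied_layer)
  forward <- match.arg(forward)
  if (length(so2_grid) < 2L)
    stop("so2_grid needs at least two points", call. = FALSE)
  if (any(so2_grid < 0 | so2_grid > 100) || fixed_so2 < 0 || fixed_so2 > 100)
    stop("saturations must lie in [0, 100]", call. = FALSE)
  structure(list(varied_layer = varied_layer, so2_grid = sort(so2_grid),
                 fixed_so2 = fixed_so2, designs = designs,
                 forward = forward, replicate_seeds = replicate_seeds),
            class = "sweep_spec")
}

#' Run a saturation sweep over probe designs
#'
#' For every design and grid point, evaluates the forward model at the
#' design's two distances and all wavelengths, applies the SRS estimator,
#' and aggregates over Monte Carlo replicates.  With the Monte Carlo
#' forward model one pure-scattering (white) run per design, wavelength and
#' replicate is reweighted exactly to every saturation on the grid, so all
#' grid points of one replicate share the same photon paths: comparisons
#' along the grid are paired, which is what lets monotonicity emerge
#' cleanly at modest photon counts.
#'
#' @param spec a \code{\link{sweep_spec}}.
#' @param medium two-layer \code{\link{layered_medium}} template; its
#'   saturations are overwritten per condition.
#' @param table a \code{\link{chromophore_table}}.
#' @param wavelengths nm; default the table's.
#' @param settings \code{\link{transport_settings}} for the Monte Carlo
#'   forward model (its \code{seed} is ignored; \code{replicate_seeds}
#'   rule).
#' @param reference_wavelength nm for the scattering model.
#' @param white_runs optional precomputed white runs (as built internally,
#'   one list of replicate runs per design id); lets several sweeps over the
#'   same designs share transport work, since a white run is independent of
#'   every saturation.  \code{\link{run_design_experiment}} uses this.
#' @return data frame with one row per design x grid point:
#'   \code{design_id}, \code{c}, \code{d}, \code{varied_layer}, \code{so2},
#'   \code{sto2_est} (replicate mean, clamped), \code{sto2_raw}
#'   (replicate mean, unclamped), \code{sto2_sd} (across replicates),
#'   \code{brain_mpp_fraction} (deepest-layer pathlength fraction, averaged
#'   over the two distances and replicates; \code{NA} for the diffusion
#'   forward model), \code{n_detected_min}.
#' @export
run_sweep <- function(spec, medium, table = default_chromophores(),
                      wavelengths = table$wavelengths,
                      settings = transport_settings(
                        n_photons = 1.5e5, max_pathlength = 600,
                        detector_half_width = 1.0),
                      reference_wavelength = 760, white_runs = NULL) {
  stopifnot(inherits(spec, "sweep_spec"), inherits(medium, "layered_medium"))
  L <- length(medium$layers)
  varied_idx <- if (spec$varied_layer == "brain") L else 1L
  fixed_idx <- if (spec$varied_layer == "brain") 1L else L
  brain <- medium$layers[[L]]
  musp_assumed <- musp(brain, wavelengths, reference_wavelength)

  rows <- list()
  for (di in seq_len(nrow(spec$designs))) {
    design <- spec$designs[di, ]
    dists <- c(design$c, design$d)
    if (spec$forward == "monte_carlo") {
      # one white run per wavelength x replicate, shared across the grid
      # (and reusable across sweeps: absorption never enters a white run)
      runs <- if (!is.null(white_runs)) {
        white_runs[[as.character(design$design_id)]]
      } else {
        make_white_runs(design, medium, table, wavelengths, settings,
                        reference_wavelength, spec$replicate_seeds)
      }
    }
    base <- set_layer_so2(medium, fixed_idx, spec$fixed_so2)
    for (so2 in spec$so2_grid) {
      med_c <- set_layer_so2(base, varied_idx, so2)
      mua_layers <- vapply(med_c$layers, function(l)
        mua(l, table, wavelengths), numeric(length(wavelengths)))
      mua_layers <- matrix(mua_layers, nrow = length(wavelengths))
      if (spec$forward == "monte_carlo") {
        per_rep <- lapply(runs, function(run) {
          paths <- attr(run, "paths")
          recs <- do.call(rbind, lapply(seq_along(wavelengths), function(wi) {
            rw <- reweight_white(paths[[wi]], mua_layers[wi, ], dists,
                                 attr(run, "settings"))
            cbind(wavelength = wavelengths[wi], rw)
          }))
          est <- srs_estimate(recs, design, table, musp_assumed)
          bf <- mean(brain_fraction(recs))
          c(sto2 = est$sto2, raw = est$sto2_raw, bf = bf,
            nmin = min(recs$n_detected))
        })
        m <- do.call(rbind, per_rep)
        rows[[length(rows) + 1L]] <- data.frame(
          design_id = design$design_id, c = design$c, d = design$d,
          varied_layer = spec$varied_layer, so2 = so2,
          sto2_est = mean(m[, "sto2"]), sto2_raw = mean(m[, "raw"]),
          sto2_sd = stats::sd(m[, "sto2"]),
          brain_mpp_fraction = mean(m[, "bf"]),
          n_detected_min = min(m[, "nmin"]))
      } else {
        deep <- med_c$layers[[L]]
        recs <- do.call(rbind, lapply(seq_along(wavelengths), function(wi) {
          hm <- homogeneous_medium(
            mua = mua(deep, table, wavelengths[wi]),
            musp = musp(deep, wavelengths[wi], reference_wavelength),
            n_rel = deep$n_refr / medium$n_ambient)
          data.frame(wavelength = wavelengths[wi], distance = dists,
                     reflectance = diffusion_reflectance(hm, dists))
        }))
        est <- srs_estimate(recs, design, table, musp_assumed)
        rows[[length(rows) + 1L]] <- data.frame(
          design_id = design$design_id, c = design$c, d = design$d,
          varied_layer = spec$varied_layer, so2 = so2,
          sto2_est = est$sto2, sto2_raw = est$sto2_raw, sto2_sd = 0,
          brain_mpp_fraction = NA_real_, n_detected_min = NA_integer_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

# white (zero-absorption) replicate runs for one design
make_white_runs <- function(design, medium, table, wavelengths, settings,
                            reference_wavelength, replicate_seeds) {
  lapply(replicate_seeds, function(sd0) {
    s <- settings
    s$seed <- as.integer((sd0 * 7919 + design$design_id * 1009) %%
                           2147483647)
    run_transport(medium, table, wavelengths, c(design$c, design$d), s,
                  reference_wavelength, white = TRUE)
  })
}

#' Run the full probe-design evaluation experiment
#'
#' The complete two-sweep experiment over a set of candidate designs: a
#' brain-saturation sweep at fixed superficial saturation, a superficial
#' (skin/scalp) sweep at fixed brain saturation, and the per-design summary
#' metrics.  With the Monte Carlo forward model the pure-scattering white
#' runs are computed once per design and shared by both sweeps, since
#' absorption enters only through the reweighting.
#'
#' @param medium two-layer \code{\link{layered_medium}} template.
#' @param table a \code{\link{chromophore_table}}.
#' @param brain_grid,skin_grid saturation grids, percent.
#' @param fixed_so2 saturation of the non-varied layer, percent.
#' @param designs data frame of designs.
#' @param forward \code{"monte_carlo"} or \code{"diffusion"}.
#' @param replicate_seeds Monte Carlo replicate seeds.
#' @param wavelengths,settings,reference_wavelength as in
#'   \code{\link{run_sweep}}.
#' @return list with \code{brain} and \code{skin} sweep tables and
#'   \code{metrics} (see \code{\link{compute_metrics}}).
#' @export
run_design_experiment <- function(medium, table = default_chromophores(),
                                  brain_grid = c(30, 50, 70, 90),
                                  skin_grid = seq(50, 90, 10),
                                  fixed_so2 = 70, designs = probe_designs(),
                                  forward = "monte_carlo",
                                  replicate_seeds = 1:3,
                                  wavelengths = table$wavelengths,
                                  settings = transport_settings(
                                    n_photons = 1.5e5, max_pathlength = 600,
                                    detector_half_width = 1.0),
                                  reference_wavelength = 760) {
  whites <- NULL
  if (forward == "monte_carlo") {
    whites <- lapply(seq_len(nrow(designs)), function(i)
      make_white_runs(designs[i, ], medium, table, wavelengths, settings,
                      reference_wavelength, replicate_seeds))
    names(whites) <- as.character(designs$design_id)
  }
  brain <- run_sweep(
    sweep_spec("brain", brain_grid, fixed_so2, designs, forward,
               replicate_seeds),
    medium, table, wavelengths, settings, reference_wavelength,
    white_runs = whites)
  skin <- run_sweep(
    sweep_spec("superficial", skin_grid, fixed_so2, designs, forward,
               replicate_seeds),
    medium, table, wavelengths, settings, reference_wavelength,
    white_runs = whites)
  list(brain = brain, skin = skin, metrics = compute_metrics(brain, skin))
}

#' Per-design responsiveness, bias and robustness metrics
#'
#' Reduces the two sweeps to the quantities that decide a probe design:
#' how strongly the estimate follows the brain (responsiveness), how far it
#' sits from the true brain value at the physiological operating point
#' (bias at 70\%), and how much it moves when only the skin/scalp changes
#' (skin sensitivity).  The deepest-layer partial-pathlength fraction is the
#' transport-level explanation of all three.
#'
#' @param brain_sweep sweep table from \code{\link{run_sweep}} with
#'   \code{varied_layer == "brain"}; its grid must contain 70\%.
#' @param skin_sweep sweep table with \code{varied_layer == "superficial"}.
#' @return data frame, one row per design: \code{design_id},
#'   \code{responsiveness} (dStO2_est/dSO2_brain, least-squares slope over
#'   the brain grid), \code{responsiveness_se}, \code{bias_at_70}
#'   (StO2_est - 70 at brain SO2 = 70, percentage points),
#'   \code{skin_sensitivity} (max - min StO2_est over the skin sweep),
#'   \code{brain_mpp_fraction} (at brain SO2 = 70).
#' @export
compute_metrics <- function(brain_sweep, skin_sweep) {
  if (is.null(brain_sweep) || is.null(skin_sweep))
    stop("both sweeps are required", call. = FALSE)
  if (!all(brain_sweep$varied_layer == "brain") ||
      !all(skin_sweep$varied_layer == "superficial"))
    stop("sweeps must vary the brain and superficial layers respectively",
         call. = FALSE)
  ids <- sort(unique(brain_sweep$design_id))
  if (!setequal(ids, unique(skin_sweep$design_id)))
    stop("sweeps cover different designs", call. = FALSE)
  out <- lapply(ids, function(id) {
    b <- brain_sweep[brain_sweep$design_id == id, ]
    s <- skin_sweep[skin_sweep$design_id == id, ]
    fit <- stats::lm(sto2_est ~ so2, data = b)
    at70 <- b$sto2_est[b$so2 == 70]
    if (length(at70) != 1L)
      stop("brain sweep must include SO2 = 70% for the bias metric",
           call. = FALSE)
    data.frame(design_id = id,
               responsiveness = unname(stats::coef(fit)[2]),
               responsiveness_se = summary(fit)$coefficients[2, 2],
               bias_at_70 = at70 - 70,
               skin_sensitivity = max(s$sto2_est) - min(s$sto2_est),
               brain_mpp_fraction = b$brain_mpp_fraction[b$so2 == 70])
  })
  do.call(rbind, out)
}
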