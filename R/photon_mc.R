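#' Monte Carlo transport settings
#'
#' @param n_photons photon packets launched per wavelength (>= 1000).
#' @param seed integer seed for the engine's deterministic random stream;
#'   identical settings give bit-identical results.
#' @param roulette_threshold packet weight below which Russian roulette is
#'   played.
#' @param roulette_survival survival probability in Russian roulette, in
#'   (0, 1); survivors are reweighted by its inverse.
#' @param detector_half_width half-width of the annular detection bin
#'   centred on each nominal source-detector distance, mm.
#' @param max_pathlength safety cap on total packet pathlength, mm; weight
#'   terminated by the cap is tracked separately in the run totals.
#'
#' @return An object of class \code{"transport_settings"}.
#' @export
transport_settings <- function(n_photons = 1e6, seed = 1L,
                               roulette_threshold = 1e-4,
                               roulette_survival = 0.1,
                               detector_half_width = 0.25,
                               max_pathlength = 2000) {
  if (n_photons < 1e3) stop("n_photons must be at least 1000", call. = FALSE)
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)", call. = FALSE)
  if (roulette_threshold < 0)
    stop("roulette_threshold must be non-negative", call. = FALSE)
  if (detector_half_width <= 0)
    stop("detector_half_width must be positive", call. = FALSE)
  if (max_pathlength <= 0)
    stop("max_pathlength must be positive", call. = FALSE)
  structure(list(n_photons = n_photons, seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 detector_half_width = detector_half_width,
                 max_pathlength = max_pathlength),
            class = "transport_settings")
}

# per-layer optical coefficient vectors at one wavelength
layer_optics <- function(medium, table, wavelength, reference_wavelength,
                         white = FALSE) {
  layers <- medium$layers
  list(
    thickness = vapply(layers, `[[`, numeric(1), "thickness"),
    mua = if (white) rep(0, length(layers))
          else vapply(layers, mua, numeric(1), table, wavelength),
    mus = vapply(layers, function(l)
      musp(l, wavelength, reference_wavelength) / (1 - l$g), numeric(1)),
    g = vapply(layers, `[[`, numeric(1), "g"),
    n_refr = vapply(layers, `[[`, numeric(1), "n_refr"))
}

#' Run layered Monte Carlo photon transport
#'
#' Launches a pencil beam normally onto the surface of \code{medium} and
#' scores spatially resolved diffuse reflectance in annular bins centred on
#' each requested source-detector distance, together with the mean partial
#' pathlength of detected packets in every layer.  Packets propagate with
#' exponential steps in the local interaction coefficient, deposit the
#' absorbed fraction of their weight at each collision, scatter by the
#' Henyey-Greenstein phase function, and undergo Fresnel
#' reflection/refraction at refractive-index mismatches; low-weight packets
#' play Russian roulette.
#'
#' @param medium a \code{\link{layered_medium}}.
#' @param table a \code{\link{chromophore_table}}.
#' @param wavelengths nm, each present in \code{table} (ignored when
#'   \code{white = TRUE}, where a single pure-scattering run per wavelength
#'   is still performed so that scattering dispersion is respected).
#' @param distances nominal source-detector distances, mm, all positive.
#' @param settings a \code{\link{transport_settings}}.
#' @param reference_wavelength nm, for the scattering model.
#' @param white if \code{TRUE}, run with all absorption set to zero and keep
#'   every detected packet's per-layer pathlengths, enabling exact
#'   "white Monte Carlo" reweighting to any absorption via
#'   \code{\link{reweight_white}}.
#' @param store_paths keep per-packet detection records (bin, exit weight,
#'   per-layer pathlengths) as attribute \code{"paths"}.
#'
#' @return A data frame of class \code{"reflectance_record"} with one row
#'   per wavelength x distance: \code{wavelength}, \code{distance},
#'   \code{reflectance} (detected weight fraction per mm^2 of annulus),
#'   \code{sem} (Monte Carlo standard error, same units),
#'   \code{n_detected}, and \code{mpp1 ... mppL} (mean partial pathlength
#'   per layer, mm; \code{NA} where nothing was detected).  Attributes:
#'   \code{"totals"} (per-wavelength energy bookkeeping: specular, diffuse,
#'   absorbed, roulette_net, cap_killed), \code{"paths"} (if requested, a
#'   list of per-wavelength matrices), \code{"settings"}, \code{"medium"}.
#' @export
run_transport <- function(medium, table, wavelengths, distances, settings,
                          reference_wavelength = 760, white = FALSE,
                          store_paths = FALSE) {
  stopifnot(inherits(medium, "layered_medium"),
            inherits(settings, "transport_settings"))
  if (any(distances <= 0)) stop("distances must be positive", call. = FALSE)
  L <- length(medium$layers)
  rows <- list()
  totals <- list()
  paths <- list()
  for (wi in seq_along(wavelengths)) {
    wl <- wavelengths[wi]
    opt <- layer_optics(medium, table, wl, reference_wavelength,
                        white = white)
    res <- mc_transport_cpp(
      thickness = opt$thickness, mua = opt$mua, mus = opt$mus, g = opt$g,
      n_refr = opt$n_refr, n_ambient = medium$n_ambient,
      distances = as.numeric(distances),
      half_width = settings$detector_half_width,
      n_photons = settings$n_photons, seed = settings$seed, stream = wi,
      w_threshold = settings$roulette_threshold,
      p_survival = settings$roulette_survival,
      max_path = settings$max_pathlength,
      store_paths = store_paths || white)
    rows[[wi]] <- summarise_bins(res, wl, distances, settings, L)
    totals[[wi]] <- data.frame(
      wavelength = wl, specular = res$specular, diffuse = res$diffuse,
      absorbed = res$absorbed, roulette_net = res$roulette_net,
      cap_killed = res$cap_killed)
    if (store_paths || white) paths[[wi]] <- res$paths
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_detected == 0))
    warning("zero packets detected at ",
            sum(out$n_detected == 0), " wavelength x distance bin(s); ",
            "increase n_photons or detector_half_width")
  attr(out, "totals") <- do.call(rbind, totals)
  if (store_paths || white) {
    names(paths) <- as.character(wavelengths)
    attr(out, "paths") <- paths
  }
  attr(out, "settings") <- settings
  attr(out, "medium") <- medium
  attr(out, "white") <- white
  class(out) <- c("reflectance_record", "data.frame")
  out
}

# turn raw engine accumulators into one row per detection bin
summarise_bins <- function(res, wavelength, distances, settings, L) {
  N <- res$n_photons
  area <- 4 * pi * distances * settings$detector_half_width
  m <- res$sumw / N
  v <- pmax(0, res$sumw2 - res$sumw^2 / N) / (N * max(N - 1, 1))
  df <- data.frame(wavelength = wavelength, distance = distances,
                   reflectance = m / area, sem = sqrt(v) / area,
                   n_detected = res$n_detected)
  mpp <- res$sumwL / ifelse(res$sumw > 0, res$sumw, NA_real_)
  colnames(mpp) <- paste0("mpp", seq_len(L))
  cbind(df, as.data.frame(mpp))
}

#' Mean partial pathlength in one layer
#'
#' The weight-averaged pathlength that detected packets spent inside the
#' given layer, per record (wavelength x distance).  The deepest-layer
#' fraction \code{mpp_brain / sum(mpp)} is the probe's brain-sensitivity
#' metric; see \code{\link{brain_fraction}}.
#'
#' @param records a \code{reflectance_record} data frame from
#'   \code{\link{run_transport}}.
#' @param layer_index 1-based layer index, surface first.
#' @return numeric vector, mm, one value per record row.
#' @export
mean_partial_pathlength <- function(records, layer_index) {
  col <- paste0("mpp", layer_index)
  if (!col %in% names(records))
    stop("no layer ", layer_index, " in these records", call. = FALSE)
  if (any(records$n_detected == 0))
    stop("mean partial pathlength is undefined for records with zero ",
         "detected packets", call. = FALSE)
  records[[col]]
}

#' Brain-layer (deepest-layer) pathlength fraction
#'
#' @param records a \code{reflectance_record} data frame.
#' @return fraction of the total detected-packet pathlength spent in the
#'   deepest layer, per record row.
#' @export
brain_fraction <- function(records) {
  cols <- grep("^mpp[0-9]+$", names(records), value = TRUE)
  tot <- rowSums(records[, cols, drop = FALSE])
  records[[cols[length(cols)]]] / tot
}

#' Reweight a white (zero-absorption) Monte Carlo run to a given absorption
#'
#' Applies the Beer-Lambert factor \eqn{\exp(-\sum_\ell \mu_{a,\ell}
#' L_\ell)} to every detected packet of a pure-scattering run, yielding an
#' unbiased estimate of the reflectance (and per-layer mean partial
#' pathlengths) the engine would produce with those absorption
#' coefficients.  Because all absorption levels reuse the same packet paths,
#' differences across absorption conditions are free of independent Monte
#' Carlo noise -- the natural way to sweep chromophore saturations.
#'
#' @param paths per-packet matrix from a \code{white = TRUE} run (columns:
#'   bin index, exit weight, pathlength per layer).
#' @param mua_layers absorption coefficient per layer, mm^-1.
#' @param distances the nominal distances of the run, mm.
#' @param settings the \code{\link{transport_settings}} of the run.
#' @return data frame with one row per distance: \code{reflectance},
#'   \code{sem}, \code{n_detected}, \code{mpp1...}.
#' @export
reweight_white <- function(paths, mua_layers, distances, settings) {
  L <- ncol(paths) - 2L
  if (length(mua_layers) != L)
    stop("need one absorption coefficient per layer", call. = FALSE)
  N <- settings$n_photons
  area <- 4 * pi * distances * settings$detector_half_width
  w <- paths[, 2] * exp(-as.matrix(paths[, 2 + seq_len(L), drop = FALSE]) %*%
                          mua_layers)[, 1]
  bin <- paths[, 1]
  out <- data.frame(distance = distances,
                    reflectance = NA_real_, sem = NA_real_,
                    n_detected = 0L)
  mpp <- matrix(NA_real_, length(distances), L,
                dimnames = list(NULL, paste0("mpp", seq_len(L))))
  for (k in seq_along(distances)) {
    sel <- bin == k
    sw <- sum(w[sel]); sw2 <- sum(w[sel]^2)
    out$reflectance[k] <- sw / N / area[k]
    out$sem[k] <- sqrt(max(0, sw2 - sw^2 / N) / (N * (N - 1))) / area[k]
    out$n_detected[k] <- sum(sel)
    if (sw > 0)
      mpp[k, ] <- colSums(paths[sel, 2 + seq_len(L), drop = FALSE] *
                            w[sel]) / sw
  }
  cbind(out, as.data.frame(mpp))
}
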