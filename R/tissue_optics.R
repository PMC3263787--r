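#' Chromophore extinction table
#'
#' Bundles the decadic molar extinction coefficients of oxy- and
#' deoxyhaemoglobin and the absorption of pure water at a set of
#' near-infrared wavelengths.  These are the only chromophores the package
#' models: the SRS oximeter deliberately inverts on haemoglobin alone, so
#' the water column exists to make the *forward* model realistic and thereby
#' expose the water-neglect bias of the estimator.
#'
#' @param wavelengths numeric, nm; strictly increasing, length >= 2.
#' @param eps_hbo2,eps_hhb decadic molar extinction coefficients of HbO2 and
#'   HHb, in mm^-1 uM^-1, one per wavelength.
#' @param mua_water absorption coefficient of pure water, mm^-1, per unit
#'   water volume fraction, one per wavelength.
#'
#' @return An object of class \code{"chromophore_table"}: a list with the
#'   four validated fields.
#' @export
#' @examples
#' tab <- default_chromophores()
#' tab$wavelengths
chromophore_table <- function(wavelengths, eps_hbo2, eps_hhb, mua_water) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L)
    stop("at least two wavelengths are required", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing and distinct", call. = FALSE)
  n <- length(wavelengths)
  for (nm in c("eps_hbo2", "eps_hhb", "mua_water")) {
    v <- get(nm)
    if (length(v) != n)
      stop(sprintf("'%s' must have one value per wavelength", nm),
           call. = FALSE)
  }
  if (any(eps_hbo2 <= 0) || any(eps_hhb <= 0))
    stop("extinction coefficients must be strictly positive", call. = FALSE)
  if (any(mua_water < 0))
    stop("water absorption must be non-negative", call. = FALSE)
  E <- cbind(eps_hbo2, eps_hhb)
  k <- kappa(E, exact = TRUE)
  if (!is.finite(k) || k > 1e8)
    stop("HbO2 and HHb extinction columns are (near-)linearly dependent; ",
         "the saturation inversion would be singular", call. = FALSE)
  structure(list(wavelengths = wavelengths,
                 eps_hbo2 = as.numeric(eps_hbo2),
                 eps_hhb = as.numeric(eps_hhb),
                 mua_water = as.numeric(mua_water)),
            class = "chromophore_table")
}

#' Built-in two-wavelength chromophore table
#'
#' Extinction coefficients of HbO2 and HHb at 760 and 850 nm and the
#' absorption of pure water at the same wavelengths, taken from the standard
#' published compilations of haemoglobin spectra (Prahl's tabulation) and
#' water absorption (Hale & Querry), converted to mm^-1 uM^-1 (decadic) and
#' mm^-1 respectively.  760/850 nm straddle the haemoglobin isosbestic point
#' near 800 nm, the classic pairing for a two-wavelength oximeter.
#'
#' @return A \code{\link{chromophore_table}}.
#' @export
default_chromophores <- function() {
  chromophore_table(
    wavelengths = c(760, 850),
    eps_hbo2  = c(5.86e-5, 1.058e-4),
    eps_hhb   = c(1.5485e-4, 6.913e-5),
    mua_water = c(2.6e-3, 4.3e-3))
}

#' Construct a tissue layer
#'
#' A single optically homogeneous layer described by its geometry, its
#' haemoglobin and water content, and its scattering properties.  Absorption
#' is derived from \code{hb_total}, \code{so2} and \code{water_fraction} via
#' \code{\link{mua}}; reduced scattering follows the linear wavelength model
#' of \code{\link{musp}}.
#'
#' @param thickness layer thickness in mm; \code{Inf} for the deepest
#'   (semi-infinite) layer.
#' @param hb_total total haemoglobin concentration, uM.
#' @param so2 haemoglobin oxygen saturation, percent in [0, 100].
#' @param water_fraction water volume fraction in [0, 1].
#' @param musp_ref reduced scattering coefficient at the reference
#'   wavelength, mm^-1.
#' @param musp_slope fractional decrease of reduced scattering per nm
#'   (dimensionless / nm).
#' @param g scattering anisotropy, in (-1, 1).
#' @param n_refr refractive index, >= 1.
#'
#' @return An object of class \code{"tissue_layer"}.
#' @export
tissue_layer <- function(thickness, hb_total, so2, water_fraction,
                         musp_ref, musp_slope = 0, g = 0.9, n_refr = 1.4) {
  if (!(thickness > 0)) stop("thickness must be positive", call. = FALSE)
  if (hb_total < 0) stop("haemoglobin concentration must be non-negative",
                         call. = FALSE)
  if (so2 < 0 || so2 > 100) stop("so2 must lie in [0, 100]", call. = FALSE)
  if (water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must lie in [0, 1]", call. = FALSE)
  if (musp_ref <= 0) stop("musp_ref must be positive", call. = FALSE)
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)", call. = FALSE)
  if (n_refr < 1) stop("refractive index must be >= 1", call. = FALSE)
  structure(list(thickness = thickness, hb_total = hb_total, so2 = so2,
                 water_fraction = water_fraction, musp_ref = musp_ref,
                 musp_slope = musp_slope, g = g, n_refr = n_refr),
            class = "tissue_layer")
}

#' Construct a layered medium
#'
#' An ordered stack of \code{\link{tissue_layer}}s, surface first, over a
#' semi-infinite deepest layer.  The engine supports any number of layers;
#' the probe-design experiments use two (skin/scalp(+skull) over brain).
#'
#' @param layers list of \code{tissue_layer}, surface first; exactly the
#'   last one must have infinite thickness.
#' @param n_ambient refractive index of the medium above the surface.
#'
#' @return An object of class \code{"layered_medium"}.
#' @export
layered_medium <- function(layers, n_ambient = 1.0) {
  if (length(layers) < 1L) stop("at least one layer is required",
                                call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), "tissue_layer")))
    stop("all elements of 'layers' must be tissue_layer objects",
         call. = FALSE)
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  if (is.finite(th[length(th)]))
    stop("the deepest layer must be semi-infinite (thickness = Inf)",
         call. = FALSE)
  if (any(is.infinite(th[-length(th)])))
    stop("only the deepest layer may have infinite thickness", call. = FALSE)
  if (n_ambient < 1) stop("n_ambient must be >= 1", call. = FALSE)
  structure(list(layers = layers, n_ambient = n_ambient),
            class = "layered_medium")
}

#' Absorption coefficient of a tissue layer
#'
#' Decomposes the layer's absorption into oxy-/deoxyhaemoglobin and water:
#' \deqn{\mu_a(\lambda) = \ln 10\,(\epsilon_{HbO_2} [HbO_2] +
#'   \epsilon_{HHb} [HHb]) + f_{water}\,\mu_{a,water}(\lambda)}
#' with \eqn{[HbO_2] = c_{Hb} SO_2/100} and
#' \eqn{[HHb] = c_{Hb} (1 - SO_2/100)}.  The \eqn{\ln 10} factor converts the
#' decadic extinction coefficients of the table to the natural-log absorption
#' used by photon transport.
#'
#' @param layer a \code{\link{tissue_layer}}.
#' @param table a \code{\link{chromophore_table}}.
#' @param wavelength nm; must be present in \code{table} (vectorized).
#'
#' @return Absorption coefficient(s), mm^-1.
#' @export
#' @examples
#' lay <- tissue_layer(Inf, hb_total = 50, so2 = 70, water_fraction = 0.85,
#'                     musp_ref = 0.7)
#' mua(lay, default_chromophores(), c(760, 850))
mua <- function(layer, table, wavelength) {
  stopifnot(inherits(layer, "tissue_layer"),
            inherits(table, "chromophore_table"))
  i <- match(wavelength, table$wavelengths)
  if (anyNA(i))
    stop("wavelength(s) not in chromophore table: ",
         paste(wavelength[is.na(i)], collapse = ", "), " nm", call. = FALSE)
  hbo2 <- layer$hb_total * layer$so2 / 100
  hhb <- layer$hb_total - hbo2
  log(10) * (table$eps_hbo2[i] * hbo2 + table$eps_hhb[i] * hhb) +
    layer$water_fraction * table$mua_water[i]
}

#' Reduced scattering coefficient of a tissue layer
#'
#' Linear wavelength model
#' \eqn{\mu_s'(\lambda) = \mu_{s,ref}'(1 - b(\lambda - \lambda_{ref}))},
#' the form assumed by the SRS oximeter for the wavelength dependence of
#' scattering; \code{b} is the layer's \code{musp_slope}.
#'
#' @param layer a \code{\link{tissue_layer}}.
#' @param wavelength nm (vectorized).
#' @param reference_wavelength nm at which \code{musp_ref} applies.
#'
#' @return Reduced scattering coefficient(s), mm^-1; errors if the linear
#'   model goes non-positive at any requested wavelength.
#' @export
musp <- function(layer, wavelength, reference_wavelength = 760) {
  stopifnot(inherits(layer, "tissue_layer"))
  out <- layer$musp_ref *
    (1 - layer$musp_slope * (wavelength - reference_wavelength))
  if (any(out <= 0))
    stop("reduced scattering model is non-positive at ",
         paste(wavelength[out <= 0], collapse = ", "),
         " nm (musp_slope too steep for this band)", call. = FALSE)
  out
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("Layered medium: %d layer(s), n_ambient = %.3g\n",
              length(x$layers), x$n_ambient))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf(
      "  [%d] thickness %s mm | Hb %g uM, SO2 %g%%, water %.2f | musp_ref %g mm^-1, g %.2f, n %.2f\n",
      i, ifelse(is.finite(l$thickness), format(l$thickness), "Inf"),
      l$hb_total, l$so2, l$water_fraction, l$musp_ref, l$g, l$n_refr))
  }
  invisible(x)
}

# replace the SO2 of one layer, returning a new medium
set_layer_so2 <- function(medium, layer_index, so2) {
  if (so2 < 0 || so2 > 100) stop("so2 must lie in [0, 100]", call. = FALSE)
  medium$layers[[layer_index]]$so2 <- so2
  medium
}
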