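#' Candidate probe designs
#'
#' The seven candidate two-source/one-detector probe geometries evaluated by
#' the design experiments, each a pair of source-detector distances
#' \code{(c, d)} in mm.  Larger separations interrogate deeper tissue at the
#' cost of a physically larger probe on a small preterm head.
#'
#' @return data frame with columns \code{design_id}, \code{c}, \code{d}
#'   (mm).
#' @export
#' @examples
#' probe_designs()
probe_designs <- function() {
  data.frame(design_id = 1:7,
             c = c(7, 8, 11, 13, 15, 20, 25),
             d = c(11, 13, 18, 20, 25, 30, 35))
}

#' A single probe design
#'
#' @param design_id integer 1-7 to pick a row of \code{\link{probe_designs}},
#'   or any id when \code{c} and \code{d} are given explicitly.
#' @param c,d source-detector distances, mm, with \code{0 < c < d}.
#' @return one-row data frame (\code{design_id}, \code{c}, \code{d}).
#' @export
probe_design <- function(design_id, c = NULL, d = NULL) {
  if (is.null(c) || is.null(d)) {
    tab <- probe_designs()
    row <- tab[tab$design_id == design_id, ]
    if (nrow(row) != 1L)
      stop("unknown design_id ", design_id, call. = FALSE)
    return(row)
  }
  if (!(c > 0 && d > c))
    stop("need 0 < c < d", call. = FALSE)
  data.frame(design_id = design_id, c = c, d = d)
}

#' Attenuation slope across source-detector distances
#'
#' Least-squares slope of attenuation (optical density,
#' \eqn{A = -\log_{10} R}) against distance; for exactly two distances this
#' is the finite difference \eqn{(A(d) - A(c))/(d - c)}.  This spatial slope
#' is the raw measurement of spatially resolved spectroscopy; it is
#' invariant to any distance-independent multiplicative factor on the
#' reflectances (source power, detector gain, coupling).
#'
#' @param distances mm, >= 2 distinct values.
#' @param attenuation optical density at each distance.
#' @return slope, OD mm^-1.
#' @export
#' @examples
#' attenuation_slope(c(11, 18), c(1.0, 1.8))  # 0.8 / 7
attenuation_slope <- function(distances, attenuation) {
  if (length(distances) < 2L)
    stop("at least two distances are required", call. = FALSE)
  if (anyDuplicated(distances))
    stop("distances must be distinct", call. = FALSE)
  if (length(attenuation) != length(distances))
    stop("one attenuation per distance is required", call. = FALSE)
  if (any(!is.finite(attenuation)))
    stop("attenuation must be finite (was a reflectance zero?)",
         call. = FALSE)
  unname(stats::lm.fit(cbind(1, distances), attenuation)$coefficients[2])
}

#' Scaled absorption from the SRS slope
#'
#' Converts the attenuation slope into a scaled absorption coefficient
#' under the semi-infinite homogeneous diffusion asymptote
#' \eqn{\ln 10 \cdot dA/d\rho \approx \mu_{eff} + 2/\bar\rho}:
#' \deqn{k\,\mu_a = \frac{(\ln 10 \cdot slope - 2/\bar\rho)^2}{3\,
#'   \mu_{s,assumed}'}}
#' The unknown scale \eqn{k} is common to all wavelengths and cancels in the
#' saturation ratio, so only the wavelength dependence of
#' \code{musp_assumed} matters downstream.
#'
#' @param slope attenuation slope, OD mm^-1.
#' @param rho_bar effective distance, mm; by convention the midpoint
#'   \code{(c + d)/2} of the design.
#' @param musp_assumed assumed reduced scattering at this wavelength,
#'   mm^-1.
#' @return list with \code{k_mua} (mm^-1, non-negative by construction) and
#'   \code{shallow} (\code{TRUE} when \eqn{\ln 10 \cdot slope \le
#'   2/\bar\rho}, i.e. the measured decay is too shallow for the asymptote
#'   -- the value is still returned but should be treated with suspicion).
#' @export
#' @examples
#' scaled_mua(0.1143, rho_bar = 14.5, musp_assumed = 1.0)
scaled_mua <- function(slope, rho_bar, musp_assumed) {
  if (rho_bar <= 0) stop("rho_bar must be positive", call. = FALSE)
  if (musp_assumed <= 0) stop("musp_assumed must be positive", call. = FALSE)
  x <- log(10) * slope - 2 / rho_bar
  list(k_mua = x^2 / (3 * musp_assumed), shallow = x <= 0)
}

#' Haemoglobin oxygen saturation from scaled absorptions
#'
#' Solves the two-chromophore linear system
#' \eqn{k \mu_a(\lambda) = \ln 10 (\epsilon_{HbO_2}(\lambda) x +
#' \epsilon_{HHb}(\lambda) y)} by least squares and reports
#' \eqn{StO_2 = 100\, x / (x + y)}.  The inversion deliberately uses only
#' the HbO2 and HHb columns -- water is ignored, exactly as in the SRS
#' oximeters this models -- and the unknown SRS scale \eqn{k} cancels in the
#' ratio.
#'
#' @param k_mua scaled absorption per wavelength, mm^-1.
#' @param table a \code{\link{chromophore_table}}.
#' @param wavelengths the wavelengths of \code{k_mua}; default all of the
#'   table's.
#' @return list with \code{sto2} (clamped to [0, 100]), \code{sto2_raw}
#'   (unclamped), \code{hbo2}, \code{hhb} (scaled concentrations) and
#'   \code{flagged} (\code{TRUE} when \eqn{x + y \le 0}).
#' @export
sto2_from_scaled_mua <- function(k_mua, table,
                                 wavelengths = table$wavelengths) {
  stopifnot(inherits(table, "chromophore_table"))
  i <- match(wavelengths, table$wavelengths)
  if (anyNA(i)) stop("wavelength(s) not in chromophore table", call. = FALSE)
  if (length(k_mua) < 2L)
    stop("at least two wavelengths are required", call. = FALSE)
  E <- log(10) * cbind(table$eps_hbo2[i], table$eps_hhb[i])
  xy <- stats::lm.fit(E, k_mua)$coefficients
  x <- unname(xy[1]); y <- unname(xy[2])
  tot <- x + y
  raw <- if (tot == 0) NA_real_ else 100 * x / tot
  list(sto2 = min(100, max(0, raw)), sto2_raw = raw,
       hbo2 = x, hhb = y, flagged = !is.na(tot) && tot <= 0)
}

#' End-to-end SRS StO2 estimate from reflectance records
#'
#' Applies the full spatially-resolved-spectroscopy chain to the two
#' distances of one probe design: attenuation at each wavelength and
#' distance, per-wavelength attenuation slope, scaled absorption at
#' \eqn{\bar\rho = (c+d)/2}, and the haemoglobin saturation inversion.
#'
#' @param records a data frame with columns \code{wavelength},
#'   \code{distance}, \code{reflectance} covering both design distances at
#'   every wavelength (e.g. from \code{\link{run_transport}} or
#'   \code{\link{diffusion_reflectance}}-based synthesis).
#' @param design one row of \code{\link{probe_designs}} (or
#'   \code{\link{probe_design}}).
#' @param table a \code{\link{chromophore_table}}.
#' @param musp_assumed assumed reduced scattering per wavelength, mm^-1
#'   (recycled if scalar).  Only its wavelength ratio affects the result.
#' @return An object of class \code{"srs_result"}: list with
#'   \code{design_id}, \code{wavelengths}, \code{slope} (OD mm^-1 per
#'   wavelength), \code{k_mua}, \code{sto2}, \code{sto2_raw},
#'   \code{shallow} (per-wavelength flags), \code{flagged}.
#' @export
srs_estimate <- function(records, design, table, musp_assumed) {
  wavelengths <- sort(unique(records$wavelength))
  dists <- c(design$c, design$d)
  musp_assumed <- rep_len(musp_assumed, length(wavelengths))
  slopes <- numeric(length(wavelengths))
  k <- numeric(length(wavelengths))
  shallow <- logical(length(wavelengths))
  rho_bar <- (design$c + design$d) / 2
  for (wi in seq_along(wavelengths)) {
    sub <- records[records$wavelength == wavelengths[wi] &
                     records$distance %in% dists, ]
    if (nrow(sub) < 2L)
      stop("records do not cover both distances of design ",
           design$design_id, " at ", wavelengths[wi], " nm", call. = FALSE)
    sub <- sub[order(sub$distance), ]
    A <- -log10(sub$reflectance)
    slopes[wi] <- attenuation_slope(sub$distance, A)
    sm <- scaled_mua(slopes[wi], rho_bar, musp_assumed[wi])
    k[wi] <- sm$k_mua
    shallow[wi] <- sm$shallow
  }
  inv <- sto2_from_scaled_mua(k, table, wavelengths)
  structure(list(design_id = design$design_id, wavelengths = wavelengths,
                 slope = slopes, k_mua = k, sto2 = inv$sto2,
                 sto2_raw = inv$sto2_raw, shallow = shallow,
                 flagged = inv$flagged),
            class = "srs_result")
}

#' @export
print.srs_result <- function(x, ...) {
  cat(sprintf("SRS StO2 estimate (design %s): %.1f%% (raw %.1f%%)\n",
              x$design_id, x$sto2, x$sto2_raw))
  if (any(x$shallow))
    cat("  note: attenuation slope too shallow for the diffusion asymptote at ",
        paste(x$wavelengths[x$shallow], collapse = ", "), " nm\n", sep = "")
  invisible(x)
}

#' Aggregate StO2 across multiple probe sites
#'
#' A multi-site probe (e.g. four source-detector pairs around a shared
#' detector pair) yields one StO2 per site; the mean serves as a global
#' cerebral value, while the agreement among sites indicates the
#' reliability of that mean at any moment.
#'
#' @param sto2_values numeric, percent; length >= 2.
#' @return list with \code{mean}, \code{range} (max - min) and \code{sd},
#'   all in percentage points.
#' @export
#' @examples
#' multisite_aggregate(c(60, 62, 64, 66))
multisite_aggregate <- function(sto2_values) {
  if (length(sto2_values) < 2L)
    stop("at least two site values are required", call. = FALSE)
  if (any(!is.finite(sto2_values)))
    stop("site values must be finite", call. = FALSE)
  list(mean = mean(sto2_values),
       range = max(sto2_values) - min(sto2_values),
       sd = stats::sd(sto2_values))
}
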