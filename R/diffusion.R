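#' Homogeneous semi-infinite medium for the diffusion model
#'
#' @param mua absorption coefficient, mm^-1, >= 0.
#' @param musp reduced scattering coefficient, mm^-1, > 0.
#' @param n_rel relative refractive index tissue/ambient, >= 1.
#' @return An object of class \code{"homogeneous_medium"}.
#' @export
homogeneous_medium <- function(mua, musp, n_rel = 1.4) {
  if (mua < 0) stop("mua must be non-negative", call. = FALSE)
  if (musp <= 0) stop("musp must be positive", call. = FALSE)
  if (mua == 0 && musp == 0) stop("no transport: mua = musp = 0",
                                  call. = FALSE)
  if (n_rel < 1) stop("n_rel must be >= 1", call. = FALSE)
  structure(list(mua = mua, musp = musp, n_rel = n_rel),
            class = "homogeneous_medium")
}

# internal-reflection parameter A(n) from the Groenhuis/Egan-Hilgeman
# polynomial fit: r_d = -1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n
internal_reflection_A <- function(n_rel) {
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}

#' Steady-state diffuse reflectance of a semi-infinite medium
#'
#' Closed-form dipole (extrapolated-boundary) solution of the diffusion
#' approximation: an isotropic source at depth \eqn{z_0 = 1/(\mu_a +
#' \mu_s')} and its negative image mirrored about the extrapolated boundary
#' at \eqn{-2 z_b}, with \eqn{z_b = 2 A D}, \eqn{D = 1/(3(\mu_a + \mu_s'))}
#' and \eqn{A} the internal-reflection parameter for the relative refractive
#' index.  Used as an independent oracle for the Monte Carlo engine and as
#' a fast forward model for the SRS estimator:
#' \deqn{R(\rho) = \frac{1}{4\pi}\left[z_0\left(\mu_{eff} +
#'   \frac{1}{r_1}\right)\frac{e^{-\mu_{eff} r_1}}{r_1^2} + (z_0 + 2
#'   z_b)\left(\mu_{eff} + \frac{1}{r_2}\right)
#'   \frac{e^{-\mu_{eff} r_2}}{r_2^2}\right]}
#' with \eqn{r_1 = \sqrt{z_0^2 + \rho^2}},
#' \eqn{r_2 = \sqrt{(z_0 + 2 z_b)^2 + \rho^2}} and
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}.
#'
#' @param medium a \code{\link{homogeneous_medium}}.
#' @param distance source-detector distance(s) rho, mm, > 0.
#' @return diffuse reflectance per unit area, mm^-2 (vectorized over
#'   \code{distance}).
#' @export
#' @examples
#' m <- homogeneous_medium(mua = 0.01, musp = 1.0, n_rel = 1.4)
#' diffusion_reflectance(m, c(20, 25, 30))
diffusion_reflectance <- function(medium, distance) {
  stopifnot(inherits(medium, "homogeneous_medium"))
  if (any(distance <= 0)) stop("distance must be positive", call. = FALSE)
  mut <- medium$mua + medium$musp
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  zb <- 2 * internal_reflection_A(medium$n_rel) * D
  mueff <- sqrt(3 * medium$mua * mut)
  r1 <- sqrt(z0^2 + distance^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + distance^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
                      (z0 + 2 * zb) * (mueff + 1 / r2) *
                        exp(-mueff * r2) / r2^2)
}

#' Effective attenuation coefficient
#'
#' @param medium a \code{\link{homogeneous_medium}}.
#' @return \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}, mm^-1.
#' @export
mueff <- function(medium) {
  stopifnot(inherits(medium, "homogeneous_medium"))
  sqrt(3 * medium$mua * (medium$mua + medium$musp))
}
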