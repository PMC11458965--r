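#' Shallow-water radiative forward model
#'
#' At-sensor radiance of a shallow-water pixel under the exponential
#' two-flow water-column model:
#' \deqn{L_i = L_{si} + a_i \, r_i \, e^{-f k_i z}}
#' where \eqn{r_i} is the bottom reflectance, \eqn{z} the depth in metres,
#' \eqn{L_{si}} the deep-water radiance, \eqn{a_i} a constant absorbing
#' atmospheric and surface effects, \eqn{k_i} the attenuation coefficient
#' and \eqn{f} the geometric path-length factor (2 for a two-flow model).
#' The radiance is strictly decreasing in depth when \eqn{a_i r_i > 0} and
#' tends to \eqn{L_{si}} as \eqn{z \to \infty}.
#'
#' @param r bottom reflectance in [0, 1] (vectorized).
#' @param z depth in metres, >= 0 (vectorized).
#' @param Ls deep-water radiance.
#' @param a surface/atmosphere constant.
#' @param k attenuation coefficient (1/m), > 0.
#' @param f geometric factor, default 2.
#' @return radiance, same shape as \code{r * z}.
#' @examples
#' radianceForward(r = 0.5, z = 5, Ls = 1, a = 1, k = 0.1)  # 1 + 0.5 * exp(-1)
#' @export
radianceForward <- function(r, z, Ls, a, k, f = 2) {
  if (any(z < 0, na.rm = TRUE)) stop("depth z must be >= 0")
  if (k <= 0) stop("attenuation coefficient k must be > 0")
  if (f <= 0) stop("geometric factor f must be > 0")
  Ls + a * r * exp(-f * k * z)
}

#' Construct forward-model parameters
#'
#' @param Ls,a,k named numeric vectors over bands (same names).
#' @param f geometric factor, default 2.
#' @param noiseSD per-band sensor noise sd; a scalar is recycled.
#' @return a \linkS4class{ForwardModelParams}.
#' @export
forwardModelParams <- function(Ls, a, k, f = 2, noiseSD = 0) {
  bands <- names(Ls)
  if (length(noiseSD) == 1L) noiseSD <- stats::setNames(rep(noiseSD, length(Ls)), bands)
  new("ForwardModelParams", Ls = Ls, a = a[bands], k = k[bands], f = f,
      noiseSD = noiseSD[bands])
}

#' Default Landsat-like forward-model parameters
#'
#' Band set B, G, R, NIR with clear-tropical-water attenuation (blue lowest,
#' red highest, NIR effectively opaque), path radiance decreasing with
#' wavelength, and sensor noise defaulting to 0.5\% of each band's dynamic
#' range (taken as \eqn{a_i \times 0.45}, the brightest bottom at the
#' surface).  Sun glint is treated as an additive offset already absorbed
#' into \code{Ls}, which is what dark-pixel subtraction removes.
#'
#' @param noiseFraction noise sd as a fraction of dynamic range (default 0.005).
#' @return a \linkS4class{ForwardModelParams}.
#' @export
defaultForwardParams <- function(noiseFraction = 0.005) {
  Ls <- c(B = 6, G = 4, R = 2, NIR = 1)
  a  <- c(B = 100, G = 110, R = 90, NIR = 120)
  k  <- c(B = 0.045, G = 0.065, R = 0.25, NIR = 4)
  forwardModelParams(Ls, a, k, f = 2, noiseSD = noiseFraction * a * 0.45)
}

#' Default bottom-reflectance library
#'
#' Visible-band reflectances typical of reef benthos: bright carbonate sand,
#' intermediate rubble, dark photosynthetic covers (coral, algae, seagrass)
#' with coral brighter than fleshy algae and seagrass.
#'
#' @return a \linkS4class{BottomLibrary}.
#' @export
defaultBottomLibrary <- function() {
  r <- rbind(
    coral    = c(B = 0.100, G = 0.120, R = 0.090, NIR = 0.30),
    sand     = c(B = 0.350, G = 0.400, R = 0.450, NIR = 0.45),
    algae    = c(B = 0.050, G = 0.100, R = 0.060, NIR = 0.35),
    rubble   = c(B = 0.200, G = 0.240, R = 0.260, NIR = 0.40),
    seagrass = c(B = 0.035, G = 0.070, R = 0.045, NIR = 0.30))
  new("BottomLibrary", reflectance = r)
}

#' Perturb site optical conditions
#'
#' Returns a copy of \code{params} with the attenuation coefficients,
#' surface/atmosphere constants and deep-water radiances rescaled —
#' emulating a site with different turbidity and atmospheric state — and a
#' copy of \code{bottoms} with multiplicative log-normal reflectance jitter
#' (sd on the log scale), emulating between-site differences in benthic
#' albedo.
#'
#' @param params a \linkS4class{ForwardModelParams}.
#' @param bottoms a \linkS4class{BottomLibrary}.
#' @param kScale scalar or per-band multiplier for k.
#' @param aScale,LsScale scalar multipliers.
#' @param reflJitterSD sd of the log-normal reflectance jitter.
#' @param seed integer seed for the jitter draw.
#' @return list with elements \code{params} and \code{bottoms}.
#' @export
perturbSiteConditions <- function(params, bottoms, kScale = 1, aScale = 1,
                                  LsScale = 1, reflJitterSD = 0, seed = 1L) {
  bands <- names(params@Ls)
  if (length(kScale) == 1L) kScale <- stats::setNames(rep(kScale, length(bands)), bands)
  p <- forwardModelParams(Ls = params@Ls * LsScale, a = params@a * aScale,
                          k = params@k * kScale[bands], f = params@f,
                          noiseSD = params@noiseSD)
  r <- bottoms@reflectance
  if (reflJitterSD > 0) {
    set.seed(as.integer(seed))
    jit <- matrix(exp(stats::rnorm(length(r), 0, reflJitterSD)), nrow(r), ncol(r))
    r <- pmin(pmax(r * jit, 1e-3), 1)
  }
  list(params = p, bottoms = new("BottomLibrary", reflectance = r))
}
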