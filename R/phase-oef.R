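#' Homodyne high-pass filter for phase maps
#'
#' Removes slowly varying background phase (e.g. the global shift from
#' oxygen accumulating in the frontal sinus and nasal cavity during
#' hyperoxia) by dividing the complex image by its Gaussian low-pass
#' filtered version and taking the phase of the quotient.  Compact dipolar
#' structure around a vessel survives; smooth background is suppressed.
#'
#' @param phase_map 2-D matrix of phase, radians.
#' @param magnitude_map 2-D matrix of magnitude, same dimensions.
#' @param fwhm Full width at half maximum of the Gaussian smoothing
#'   kernel, mm.
#' @param voxel_size Isotropic in-plane voxel size, mm.
#' @return Matrix of filtered phase, radians, wrapped to (-pi, pi].
#' @export
homodyne_highpass <- function(phase_map, magnitude_map, fwhm = 4,
                              voxel_size = 1) {
  if (!all(dim(phase_map) == dim(magnitude_map)))
    stop("phase and magnitude maps must have identical dimensions")
  if (fwhm <= 0) stop("fwhm must be positive")
  if (fwhm < voxel_size)
    warning("smoothing FWHM is below one voxel; filter will do little")
  z <- magnitude_map * exp(1i * phase_map)
  lp <- .gauss_blur(Re(z), fwhm, voxel_size) +
    1i * .gauss_blur(Im(z), fwhm, voxel_size)
  Arg(z * Conj(lp))
}

# separable Gaussian blur with edge renormalisation (kernel truncated at
# 3 sigma); small grids only, direct convolution is fine
.gauss_blur <- function(x, fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in -half:half) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)   # clamp at edges
      out <- out + k[j + half + 1] * m[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(x))))
}

#' Vessel phase line profile
#'
#' @param positions Position along the sampling line, mm.
#' @param phase_normoxia,phase_hyperoxia Phase values at the two gas
#'   states, radians (spatially unwrapped).
#' @param magnitude Magnitude values (used to exclude intravascular
#'   samples by intensity thresholding).
#' @param excluded Optional logical: samples to drop from fitting.
#' @return Data frame of class `phase_profile`.
#' @export
phase_profile <- function(positions, phase_normoxia, phase_hyperoxia,
                          magnitude, excluded = FALSE) {
  n <- length(positions)
  if (length(phase_normoxia) != n || length(phase_hyperoxia) != n ||
      length(magnitude) != n)
    stop("all profile columns must have equal length")
  structure(
    data.frame(position_mm = positions, phase_norm_rad = phase_normoxia,
               phase_hyper_rad = phase_hyperoxia, magnitude = magnitude,
               excluded = rep_len(excluded, n)),
    class = c("phase_profile", "data.frame")
  )
}

#' Hyperoxia:normoxia phase ratio by least squares
#'
#' Fits `phase_hyperoxia = a * phase_normoxia` (no intercept) over the
#' extravascular samples of a line profile.  Samples whose magnitude
#' exceeds `intensity_threshold` (default: the 98th percentile of the
#' profile magnitudes) are treated as intravascular and excluded, in
#' addition to any pre-existing exclusion flags.  Because the
#' extravascular field pattern scales linearly with the intravascular
#' susceptibility whatever the vessel geometry, `a` equals the
#' hyperoxia:normoxia ratio of blood susceptibility relative to tissue.
#'
#' @param profile A [phase_profile()].
#' @param intensity_threshold Magnitude above which samples are excluded;
#'   `NULL` for the 98th-percentile default.
#' @return List of class `phase_ratio_fit`: `a`, `residual_norm`,
#'   `n_points`, `intensity_threshold`.
#' @export
fit_phase_ratio <- function(profile, intensity_threshold = NULL) {
  stopifnot(inherits(profile, "phase_profile"))
  if (is.null(intensity_threshold))
    intensity_threshold <- stats::quantile(profile$magnitude, 0.98,
                                           names = FALSE)
  keep <- !profile$excluded & profile$magnitude <= intensity_threshold
  if (sum(keep) < 3)
    stop("fewer than 3 profile samples remain after exclusion")
  pn <- profile$phase_norm_rad[keep]
  ph <- profile$phase_hyper_rad[keep]
  denom <- sum(pn^2)
  if (denom < .Machine$double.eps * length(pn))
    stop("normoxia phase is essentially zero: ratio is ill-conditioned")
  a <- sum(pn * ph) / denom
  structure(
    list(a = a, residual_norm = sqrt(sum((ph - a * pn)^2)),
         n_points = sum(keep), intensity_threshold = intensity_threshold),
    class = "phase_ratio_fit"
  )
}

#' @export
print.phase_ratio_fit <- function(x, ...) {
  cat(sprintf(
    "Phase ratio fit: a = %.4f (%d points, residual norm %.3g)\n",
    x$a, x$n_points, x$residual_norm))
  invisible(x)
}

#' Resting deoxyhaemoglobin fraction from the phase ratio
#'
#' Inverts the linear blood-susceptibility model.  With blood
#' susceptibility (relative to tissue/water) linear in Q, the ratio `a` of
#' hyperoxia to normoxia extravascular phase satisfies
#' `chi(Q0) = dQ_h (dchi_oxy - dchi_deoxy) / (1 - a)`, giving
#' `1 - Q0 = (dQ_h (dchi_oxy - dchi_deoxy) / (1 - a) - dchi_deoxy) /
#' (dchi_oxy - dchi_deoxy)`.  The haematocrit cancels in the ratio.
#'
#' @param a Hyperoxia:normoxia phase ratio (must differ from 1).
#' @param dq_h Absolute hyperoxia change in venous deoxyhaemoglobin
#'   fraction (negative), from [hyperoxia_contrast()] (`dq_h` there is
#'   OEF-independent).
#' @param const A [gas_constants()] object.
#' @return Q0 (= OEF), a fraction in (0, 1).
#' @examples
#' # forward ratio for Q0 = 0.4, dQ_h = -0.068, then invert
#' a <- blood_chi(1 - (0.4 - 0.068)) / blood_chi(1 - 0.4)
#' q0_from_ratio(a, -0.068)
#' @export
q0_from_ratio <- function(a, dq_h, const = gas_constants()) {
  if (!is.finite(a) || a == 1)
    stop("phase ratio a = 1 carries no oxygenation contrast")
  if (!is.finite(dq_h) || dq_h >= 0)
    stop("dq_h must be negative (hyperoxia lowers venous dHb)")
  span <- const$dchi_oxy - const$dchi_deoxy
  one_minus_q0 <- (dq_h * span / (1 - a) - const$dchi_deoxy) / span
  q0 <- 1 - one_minus_q0
  if (!is.finite(q0) || q0 <= 0 || q0 >= 1)
    stop("infeasible Q0 = ", signif(q0, 4),
         " from a = ", signif(a, 4), ", dq_h = ", signif(dq_h, 4))
  q0
}

#' Synthetic extravascular phase maps around an infinite-cylinder vessel
#'
#' Generates matched normoxia/hyperoxia 2-D phase maps for a long
#' cylindrical vein of radius `radius_mm` tilted by `tilt_deg` to the main
#' field, using the standard infinite-cylinder dipole field.  Outside the
#' vessel the relative field offset is
#' `(dchi_SI / 2) (a/r)^2 sin^2(theta) cos(2 phi)`, linear in the blood
#' susceptibility from [blood_chi()]; phase is `gamma B0 TE` times the
#' offset and is returned unwrapped (real-valued).  A synthetic magnitude
#' map marks intravascular voxels as bright so the standard intensity
#' threshold excludes them.
#'
#' This is a fixture generator: the ratio estimator itself is deliberately
#' independent of any model of the field pattern around the vessel.
#'
#' @param q0 Resting venous deoxyhaemoglobin fraction.
#' @param dq_h Absolute hyperoxia change in Q (negative).
#' @param radius_mm Vessel radius, mm.
#' @param tilt_deg Angle between vessel axis and B0, degrees.
#' @param n Grid size (n x n voxels).
#' @param fov_mm Field of view, mm.
#' @param b0 Main field, tesla.
#' @param te Echo time, seconds.
#' @param vessel_brightness Magnitude of intravascular voxels relative to
#'   tissue (= 1).
#' @param const A [gas_constants()] object.
#' @return List of class `vessel_phase_maps`: matrices `phase_normoxia`,
#'   `phase_hyperoxia`, `magnitude`, logical `intravascular`, vector
#'   `positions_mm`, and the generating parameters.
#' @export
synth_vessel_phase <- function(q0 = 0.4, dq_h = -0.068, radius_mm = 3,
                               tilt_deg = 90, n = 96, fov_mm = 48,
                               b0 = 7, te = 0.025, vessel_brightness = 2,
                               const = gas_constants()) {
  stopifnot(radius_mm > 0, n >= 8, fov_mm > 0, b0 > 0, te > 0)
  vox <- fov_mm / n
  if (radius_mm < 2 * vox)
    stop("grid does not resolve the vessel: radius < 2 voxels")
  pos <- (seq_len(n) - (n + 1) / 2) * vox
  xx <- matrix(pos, n, n)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  cos2phi <- ifelse(r2 > 0, (xx^2 - yy^2) / r2, 0)
  theta <- tilt_deg * pi / 180
  gamma <- 2.675e8                       # proton gyromagnetic ratio, rad/s/T

  inside <- r2 <= radius_mm^2
  shape_out <- (radius_mm^2 / pmax(r2, radius_mm^2)) * sin(theta)^2 *
    cos2phi / 2
  shape_in <- (3 * cos(theta)^2 - 1) / 6
  shape <- ifelse(inside, shape_in, shape_out)

  phase_for <- function(q) {
    chi_si <- 4 * pi * blood_chi(1 - q, const) * 1e-6   # cgs 1e-6 -> SI
    gamma * b0 * te * chi_si * shape
  }
  mag <- matrix(1, n, n)
  mag[inside] <- vessel_brightness

  structure(
    list(phase_normoxia = phase_for(q0),
         phase_hyperoxia = phase_for(q0 + dq_h),
         magnitude = mag, intravascular = inside, positions_mm = pos,
         q0 = q0, dq_h = dq_h, radius_mm = radius_mm,
         tilt_deg = tilt_deg, voxel_mm = vox, b0 = b0, te = te),
    class = "vessel_phase_maps"
  )
}

#' Extract a line profile across synthetic (or measured) phase maps
#'
#' Takes one image row as the sampling line across the vessel, mirroring
#' the line-profile reading used on sagittal-sinus phase maps.
#'
#' @param maps A [synth_vessel_phase()] result, or a list with matrices
#'   `phase_normoxia`, `phase_hyperoxia`, `magnitude` and `positions_mm`.
#' @param row Image row to sample; default crosses the vessel centre.
#' @return A [phase_profile()].
#' @export
line_profile <- function(maps, row = NULL) {
  n <- nrow(maps$phase_normoxia)
  if (is.null(row)) row <- ceiling((n + 1) / 2)
  if (row < 1 || row > n) stop("row outside the map")
  phase_profile(maps$positions_mm,
                maps$phase_normoxia[row, ],
                maps$phase_hyperoxia[row, ],
                maps$magnitude[row, ])
}

#' Temporal phase unwrapping by nearest-multiple tracking
#'
#' Adds the multiple of 2 pi that keeps each successive sample closest to
#' its predecessor.  Spatial unwrapping is an input requirement, not
#' provided here.
#'
#' @param phase Numeric vector of wrapped phase samples, radians.
#' @return Unwrapped phase vector.
#' @export
unwrap_phase_temporal <- function(phase) {
  if (length(phase) < 2) return(phase)
  out <- phase
  for (k in 2:length(phase))
    out[k] <- phase[k] - 2 * pi * round((phase[k] - out[k - 1]) / (2 * pi))
  out
}
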