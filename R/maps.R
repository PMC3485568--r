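#' Voxelwise calibration maps
#'
#' Applies the full ROI pipeline ([calibrate_timecourse()]) independently
#' to every voxel inside a mask, producing maps of M, M', rvCBV and
#' q_act.  Voxels whose fit fails (zero variance, non-physical slope,
#' degenerate windows) are flagged `NA`.
#'
#' @param volume 4-D numeric array `[x, y, z, t]` of BOLD signal.
#' @param mask 3-D logical (or 0/1) array matching the spatial dimensions.
#' @param paradigm A [paradigm()]; volume frames are assumed sampled at
#'   its TR starting at time 0.
#' @param contrast Per-block gas contrast (see [calibrate_timecourse()]).
#' @param te Echo time, seconds.
#' @param qc_keep Optional per-trial keep flags.
#' @return List of class `calibration_maps` with 3-D arrays `m`,
#'   `m_prime`, `rvcbv`, `q_act` and the count `n_failed`.
#' @export
voxelwise_maps <- function(volume, mask, paradigm, contrast, te,
                           qc_keep = NULL) {
  d <- dim(volume)
  if (length(d) != 4) stop("volume must be a 4-D array [x, y, z, t]")
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!any(mask)) stop("mask is empty")
  times <- (seq_len(d[4]) - 1) * paradigm$tr
  base <- baseline_mask(paradigm, times)
  idx <- which(mask, arr.ind = TRUE)
  empty <- array(NA_real_, d[1:3])
  maps <- list(m = empty, m_prime = empty, rvcbv = empty, q_act = empty)
  n_failed <- 0L
  for (v in seq_len(nrow(idx))) {
    y <- volume[idx[v, 1], idx[v, 2], idx[v, 3], ]
    fit <- tryCatch({
      if (stats::sd(y) == 0) stop("zero-variance voxel")
      calibrate_timecourse(roi_timecourse(times, y), paradigm, contrast,
                           te, qc_keep = qc_keep, baseline = base)
    }, error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    maps$m[idx[v, , drop = FALSE]] <- fit$m
    maps$m_prime[idx[v, , drop = FALSE]] <- fit$m_prime
    maps$rvcbv[idx[v, , drop = FALSE]] <- fit$rvcbv
    maps$q_act[idx[v, , drop = FALSE]] <- fit$q_act
  }
  structure(c(maps, list(n_failed = n_failed, n_voxels = nrow(idx))),
            class = "calibration_maps")
}

#' @export
print.calibration_maps <- function(x, ...) {
  cat(sprintf("Calibration maps over %d voxels (%d failed)\n",
              x$n_voxels, x$n_failed))
  ok <- !is.na(x$rvcbv)
  if (any(ok))
    cat(sprintf("  median M = %.1f%%, rvCBV = %.1f%%, q_act = %.1f%%\n",
                stats::median(x$m[ok]), 100 * stats::median(x$rvcbv[ok]),
                100 * stats::median(x$q_act[ok])))
  invisible(x)
}

#' Write calibration maps as NIfTI volumes
#'
#' Writes one float32 NIfTI per map plus a JSON sidecar recording the fit
#' provenance (TE, paradigm variant, failure count).
#'
#' @param maps A [voxelwise_maps()] result.
#' @param dir Output directory (created if needed).
#' @param reference Optional NIfTI image or path supplying the spatial
#'   metadata (affine etc.).
#' @param prefix Filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_maps_nifti <- function(maps, dir, reference = NULL, prefix = "calib") {
  stopifnot(inherits(maps, "calibration_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("m", "m_prime", "rvcbv", "q_act")) {
    img <- maps[[nm]]
    if (!is.null(reference))
      img <- RNifti::asNifti(img, reference = reference)
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    RNifti::writeNifti(img, p, datatype = "float")
    paths <- c(paths, p)
  }
  side <- file.path(dir, paste0(prefix, "_maps.json"))
  jsonlite::write_json(
    list(maps = c("m", "m_prime", "rvcbv", "q_act"),
         units = list(m = "percent", m_prime = "percent",
                      rvcbv = "fraction", q_act = "fraction"),
         n_voxels = maps$n_voxels, n_failed = maps$n_failed),
    side, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, side))
}
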