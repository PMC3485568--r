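#' Read and write delimited timecourse and gas-trace files
#'
#' Timecourses are tab-separated with a header line.  ROI timecourses
#' need columns `time_s` and `signal`; end-tidal traces need `time_s`,
#' `peto2_mmHg` and `petco2_mmHg`; ASL files need `tag` and `control`;
#' phase profiles need `position_mm`, `phase_norm_rad`, `phase_hyper_rad`
#' and `magnitude` (optional `excluded`).  Missing columns raise an error
#' naming the column.
#'
#' @param path File path.
#' @return The corresponding validated object.
#' @name timecourse_io
NULL

.read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname timecourse_io
#' @export
read_timecourse <- function(path) {
  df <- .read_tsv_checked(path, c("time_s", "signal"))
  roi_timecourse(df$time_s, df$signal)
}

#' @rdname timecourse_io
#' @param tc Object to write.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "roi_timecourse"))
  utils::write.table(as.data.frame(tc), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname timecourse_io
#' @export
read_endtidal <- function(path) {
  df <- .read_tsv_checked(path, c("time_s", "peto2_mmHg", "petco2_mmHg"))
  endtidal_trace(df$time_s, df$peto2_mmHg, df$petco2_mmHg)
}

#' @rdname timecourse_io
#' @param trace Object to write.
#' @export
write_endtidal <- function(trace, path) {
  stopifnot(inherits(trace, "endtidal_trace"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname timecourse_io
#' @export
read_asl <- function(path) {
  df <- .read_tsv_checked(path, c("tag", "control"))
  list(tag = df$tag, control = df$control)
}

#' @rdname timecourse_io
#' @export
read_phase_profile <- function(path) {
  df <- .read_tsv_checked(path, c("position_mm", "phase_norm_rad",
                                  "phase_hyper_rad", "magnitude"))
  phase_profile(df$position_mm, df$phase_norm_rad, df$phase_hyper_rad,
                df$magnitude,
                if (is.null(df$excluded)) FALSE else as.logical(df$excluded))
}

#' @rdname timecourse_io
#' @param profile Object to write.
#' @export
write_phase_profile <- function(profile, path) {
  stopifnot(inherits(profile, "phase_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write paradigm descriptions as JSON
#'
#' The JSON carries `variant`, `tr`, a `blocks` table and a `trials`
#' table, mirroring the [paradigm()] constructor.
#'
#' @param path File path.
#' @return A [paradigm()].
#' @export
read_paradigm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("tr", "blocks", "trials"))
    if (is.null(j[[f]])) stop("paradigm JSON is missing field: ", f)
  paradigm(as.data.frame(j$blocks), as.data.frame(j$trials),
           tr = j$tr,
           variant = if (is.null(j$variant)) "custom" else j$variant)
}

#' @rdname read_paradigm
#' @param paradigm A [paradigm()] to write.
#' @export
write_paradigm <- function(paradigm, path) {
  stopifnot(inherits(paradigm, "paradigm"))
  jsonlite::write_json(
    list(variant = paradigm$variant, tr = paradigm$tr,
         blocks = paradigm$blocks[, c("label", "start", "end")],
         trials = paradigm$trials[, c("on_start", "on_s", "off_s",
                                      "usable")]),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a 4-D NIfTI volume
#'
#' @param path Path to a NIfTI file.
#' @return List with `data` (4-D array) and `image` (the `niftiImage`,
#'   carrying the affine and header).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop("expected a 4-D volume, got ", length(dim(img)), "-D")
  list(data = array(as.numeric(img), dim = dim(img)), image = img)
}

#' Serialise a calibration run to JSON
#'
#' Machine-facing output keeps fractions, with explicit `units` fields to
#' avoid percent/fraction confusion; the print methods use percent.
#'
#' @param run A [run_calibration()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path written.
#' @export
write_calibration_run <- function(run, dir) {
  stopifnot(inherits(run, "calibration_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fit <- run$fit
  payload <- list(
    q0 = run$q0, q0_source = run$q0_source, te_s = run$te,
    fit = list(
      m = fit$m, m_prime = fit$m_prime, se_m = fit$se_m,
      se_m_prime = fit$se_m_prime,
      rvcbv = fit$rvcbv, se_rvcbv = fit$se_rvcbv,
      q_act = fit$q_act, se_q_act = fit$se_q_act,
      n_points = fit$n_points,
      units = list(m = "percent", m_prime = "percent",
                   rvcbv = "fraction", q_act = "fraction")
    ),
    gas_contrast = run$contrast,
    qc_kept = as.list(run$qc)
  )
  if (!is.null(run$cmro2))
    payload$cmro2 <- list(rcbf = run$rcbf, q_act = run$cmro2$q_act,
                          rcmro2 = run$cmro2$rcmro2, units = "fraction")
  path <- file.path(dir, "calibration_run.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
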