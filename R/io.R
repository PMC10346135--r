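#' CSV import/export of device-style streams and angle traces
#'
#' The IMU export schema mirrors the device's cloud CSV: columns
#' `t, qw, qx, qy, qz, ax, ay, az, gx, gy, gz` at 30 Hz. The reference
#' export carries `t, angle_deg` plus an optional `marker_y` column with
#' the sync-marker trajectory. Both round-trip losslessly at the written
#' precision; malformed rows are rejected with their row number.
#'
#' @name session-io
NULL

IMU_CSV_COLS <- c("t", "qw", "qx", "qy", "qz",
                  "ax", "ay", "az", "gx", "gy", "gz")

fmt_num <- function(x, digits = 9) {
  formatC(x, digits = digits, format = "g")
}

#' Write an orientation stream to a device-style CSV
#' @param stream a [quat_stream]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_imu_csv <- function(stream, path) {
  stopifnot(inherits(stream, "quat_stream"))
  df <- data.frame(
    t = fmt_num(stream$t),
    qw = fmt_num(stream$quat[, 1]), qx = fmt_num(stream$quat[, 2]),
    qy = fmt_num(stream$quat[, 3]), qz = fmt_num(stream$quat[, 4]),
    ax = fmt_num(stream$accel[, 1]), ay = fmt_num(stream$accel[, 2]),
    az = fmt_num(stream$accel[, 3]),
    gx = fmt_num(stream$gyro[, 1]), gy = fmt_num(stream$gyro[, 2]),
    gz = fmt_num(stream$gyro[, 3]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a device-style CSV into an orientation stream
#'
#' Validates the column schema, strictly increasing time stamps, finiteness
#' of every field, and unit quaternion norms (tolerance `1e-3` against
#' write/read rounding); violations are reported with the offending data
#' row number.
#'
#' @param path CSV file with the [write_imu_csv()] schema
#' @param norm_tol allowed quaternion norm deviation (default 1e-3)
#' @return a [quat_stream]
#' @export
read_imu_csv <- function(path, norm_tol = 1e-3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(IMU_CSV_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  for (cc in IMU_CSV_COLS) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in column '%s' at data row %d", cc, bad[1]))
    }
  }
  if (any(diff(df$t) <= 0)) {
    stop(sprintf("non-monotone time stamps at data row %d",
                 which(diff(df$t) <= 0)[1] + 1L))
  }
  quat <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(quat^2))
  bad <- which(abs(nrm - 1) > norm_tol)
  if (length(bad)) {
    stop(sprintf("non-unit quaternion at data row %d (|q| = %.4f)",
                 bad[1], nrm[bad[1]]))
  }
  quat <- quat / nrm
  quat_stream(df$t, quat,
              accel = as.matrix(df[, c("ax", "ay", "az")]),
              gyro = as.matrix(df[, c("gx", "gy", "gz")]),
              rate = infer_rate(df$t))
}

#' Write a reference angle trace to CSV
#' @param trace an [angle_trace]
#' @param path output file path
#' @param marker_y optional sync-marker channel (same length as the trace)
#' @return `path`, invisibly
#' @export
write_mocap_csv <- function(trace, path, marker_y = NULL) {
  stopifnot(inherits(trace, "angle_trace"))
  df <- data.frame(t = fmt_num(trace_times(trace)),
                   angle_deg = fmt_num(trace$values),
                   stringsAsFactors = FALSE)
  if (!is.null(marker_y)) {
    stopifnot(length(marker_y) == length(trace$values))
    df$marker_y <- fmt_num(marker_y)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference angle trace from CSV
#'
#' @param path CSV with columns `t, angle_deg` (optional `marker_y`)
#' @param system system tag for the resulting trace (default `"MoCap"`)
#' @return an [angle_trace]; if a `marker_y` column is present it is
#'   attached as attribute `"marker_y"`
#' @export
read_mocap_csv <- function(path, system = "MoCap") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("t", "angle_deg"), names(df))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(df$angle_deg))
  if (length(bad)) {
    stop(sprintf("non-finite angle at data row %d", bad[1]))
  }
  if (any(diff(df$t) <= 0)) {
    stop(sprintf("non-monotone time stamps at data row %d",
                 which(diff(df$t) <= 0)[1] + 1L))
  }
  tr <- angle_trace(df$angle_deg, rate = infer_rate(df$t), t0 = df$t[1],
                    system = system)
  if ("marker_y" %in% names(df)) attr(tr, "marker_y") <- df$marker_y
  tr
}

# sampling rate from time stamps, snapped to integer Hz within write/read
# rounding error
infer_rate <- function(t) {
  rate <- 1 / stats::median(diff(t))
  if (abs(rate - round(rate)) < 1e-3) round(rate) else rate
}

# tiny FNV-1a hash of a serialized object (no external digest dependency)
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a validation-study report bundle to a directory
#'
#' Emits the study's tables as plain CSV plus a JSON manifest: per-task
#' summary (means/SDs, accuracy, RMSE, MCID), correlation table (PCC/CCC),
#' per-repetition ROM table, Bland-Altman point payloads, and the
#' misplacement comparison when present. All angle columns are written with
#' 2-decimal formatting; the per-repetition table is the source of record
#' from which every summary number is recomputable.
#'
#' @param bundle result of [run_validation_study()]
#' @param dir output directory (created if needed)
#' @param timestamp include a wall-clock timestamp in the manifest
#'   (default TRUE; disable for byte-identical reruns)
#' @return `dir`, invisibly
#' @export
write_report <- function(bundle, dir, timestamp = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  round2 <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 2))
    df
  }
  utils::write.csv(round2(bundle$summary),
                   file.path(dir, "summary_agreement.csv"), row.names = FALSE)
  utils::write.csv(round2(bundle$correlations),
                   file.path(dir, "summary_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(round2(bundle$per_rep),
                   file.path(dir, "rom_per_repetition.csv"), row.names = FALSE)
  ba <- do.call(rbind, lapply(names(bundle$reports), function(task) {
    pts <- bundle$reports[[task]]$bland_altman$points
    data.frame(task = task, participant = seq_len(nrow(pts)),
               mean = pts$mean, diff = pts$diff, stringsAsFactors = FALSE)
  }))
  utils::write.csv(round2(ba), file.path(dir, "bland_altman_points.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$misplacement)) {
    utils::write.csv(round2(bundle$misplacement),
                     file.path(dir, "summary_misplacement.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = bundle$config$seed,
    tasks = bundle$config$tasks,
    n = bundle$config$n,
    config_hash = config_hash(bundle$config),
    generated = if (timestamp) format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
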