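#' Per-sensor ADC scale factors
#'
#' SisFall devices record integer ADC counts; a linear factor converts counts
#' to physical units. Defaults are the published constants of the SisFall
#' acquisition board: ADXL345 accelerometer (+/-16 g, 13 bit), ITG3200
#' gyroscope (+/-2000 deg/s, 16 bit), MMA8451Q accelerometer (+/-8 g, 14 bit),
#' each computed as `2 * range / 2^bits`.
#'
#' @param accel1 g per count for the first accelerometer.
#' @param gyro deg/s per count for the gyroscope.
#' @param accel2 g per count for the second accelerometer.
#' @return A `channel_scale` list with one factor per sensor.
#' @export
sisfall_scales <- function(accel1 = 2 * 16 / 2^13,
                           gyro   = 2 * 2000 / 2^16,
                           accel2 = 2 * 8 / 2^14) {
  s <- list(accel1 = accel1, gyro = gyro, accel2 = accel2)
  for (nm in names(s)) {
    if (!is.numeric(s[[nm]]) || length(s[[nm]]) != 1L || !is.finite(s[[nm]]) ||
        s[[nm]] <= 0) {
      stop("scale factor '", nm, "' must be a single finite positive number",
           call. = FALSE)
    }
  }
  structure(s, class = "channel_scale")
}

#' Parse SisFall trial metadata from a file name
#'
#' SisFall files follow `<activity>_<subject>_R<trial>.txt`, e.g.
#' `F01_SA06_R02.txt`. Activity codes starting with `D` are ADLs and `F` are
#' fall-type trials; subject codes `SAxx` are young adults and `SExx` elderly.
#'
#' @param filename File name (directory part ignored).
#' @return List with `activity_code`, `activity_class` ("ADL"/"FALL"),
#'   `subject_id`, `subject_group` ("young"/"elderly"), `trial_index`.
#' @export
parse_sisfall_filename <- function(filename) {
  base <- sub("\\.txt$", "", basename(filename))
  m <- regmatches(base, regexec("^([DF][0-9]+)_((SA|SE)[0-9]+)_R([0-9]+)$", base))[[1]]
  if (length(m) == 0L) {
    stop("file name '", basename(filename),
         "' does not match the SisFall convention <activity>_<subject>_R<trial>.txt",
         call. = FALSE)
  }
  list(
    activity_code  = m[2],
    activity_class = if (startsWith(m[2], "D")) "ADL" else "FALL",
    subject_id     = m[3],
    subject_group  = if (m[4] == "SA") "young" else "elderly",
    trial_index    = as.integer(m[5])
  )
}

new_raw_trial <- function(samples, meta, sample_rate_hz = 200) {
  stopifnot(is.matrix(samples), nrow(samples) >= 1L, sample_rate_hz > 0)
  structure(
    list(
      subject_id     = meta$subject_id,
      subject_group  = meta$subject_group,
      activity_code  = meta$activity_code,
      activity_class = meta$activity_class,
      trial_index    = meta$trial_index,
      samples        = samples,
      sample_rate_hz = sample_rate_hz
    ),
    class = "raw_trial"
  )
}

#' Read one SisFall-style raw trial file
#'
#' Each line of the file is a comma- (or semicolon-) separated row of integer
#' ADC counts, nine per row for the full sensor set (accelerometer 1 xyz,
#' gyroscope xyz, accelerometer 2 xyz) or six when only one accelerometer and
#' the gyroscope were recorded. Counts are converted to physical units (g,
#' deg/s) by the per-sensor linear factors in `scale`. Trial metadata is
#' parsed from the file name.
#'
#' @param path Path to the `.txt` trial file.
#' @param scale A [sisfall_scales()] object.
#' @param sample_rate_hz Sampling rate of the recording (Hz).
#' @return A `raw_trial`: metadata plus a numeric `T x C` sample matrix.
#' @export
read_raw_trial <- function(path, scale = sisfall_scales(), sample_rate_hz = 200) {
  if (!inherits(scale, "channel_scale")) scale <- do.call(sisfall_scales, scale)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- parse_sisfall_filename(path)

  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("trial file is empty: ", path, call. = FALSE)

  fields <- strsplit(gsub(";", ",", lines), ",", fixed = TRUE)
  fields <- lapply(fields, function(f) trimws(f[nzchar(trimws(f))]))
  nf <- lengths(fields)
  C <- nf[1L]
  if (!(C %in% c(6L, 9L))) {
    stop("line ", line_no[1L], ": expected 6 or 9 fields, found ", C,
         call. = FALSE)
  }
  bad <- which(nf != C)
  if (length(bad) > 0L) {
    stop("line ", line_no[bad[1L]], ": expected ", C, " fields, found ",
         nf[bad[1L]], call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1L] / C)
    stop("line ", line_no[bad_row], ": non-numeric field", call. = FALSE)
  }
  samples <- matrix(vals, ncol = C, byrow = TRUE)

  fac <- if (C == 9L) {
    rep(c(scale$accel1, scale$gyro, scale$accel2), each = 3L)
  } else {
    rep(c(scale$accel1, scale$gyro), each = 3L)
  }
  samples <- sweep(samples, 2L, fac, `*`)
  colnames(samples) <- if (C == 9L) {
    c("ax1", "ay1", "az1", "gx", "gy", "gz", "ax2", "ay2", "az2")
  } else {
    c("ax1", "ay1", "az1", "gx", "gy", "gz")
  }
  new_raw_trial(samples, meta, sample_rate_hz)
}

#' Attach per-sample class annotations to a trial
#'
#' The annotation file assigns each timestep one of the labels 0 (Non-Fall),
#' 1 (Pre-Fall), 2 (Fall). Both a single-column layout (one label per line)
#' and a two-column `timestep,label` layout are accepted.
#'
#' @param path Path to the annotation file.
#' @param trial A `raw_trial` the annotations belong to.
#' @return An `annotated_trial`: `list(trial = <raw_trial>, labels = <int[T]>)`.
#' @export
read_annotations <- function(path, trial) {
  stopifnot(inherits(trial, "raw_trial"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(gsub(";", ",", lines), ",", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(1L, 2L)) || length(unique(nf)) != 1L) {
    stop("annotation file must have one or two columns throughout", call. = FALSE)
  }
  raw <- if (nf[1L] == 2L) vapply(fields, `[`, "", 2L) else unlist(fields)
  labels <- suppressWarnings(as.numeric(raw))
  if (anyNA(labels)) stop("non-numeric annotation value", call. = FALSE)
  annotate_trial(trial, labels)
}

#' Pair a trial with an in-memory label vector
#'
#' @param trial A `raw_trial`.
#' @param labels Integer labels, one per sample row.
#' @return An `annotated_trial`.
#' @export
annotate_trial <- function(trial, labels) {
  stopifnot(inherits(trial, "raw_trial"))
  T_ <- nrow(trial$samples)
  if (length(labels) != T_) {
    stop("annotation length ", length(labels),
         " does not match trial length ", T_, call. = FALSE)
  }
  labels <- validate_labels(labels, "annotations")
  structure(list(trial = trial, labels = labels), class = "annotated_trial")
}

#' Keep a subset of sensor channels
#'
#' The default keeps the first accelerometer and the gyroscope (six input
#' dimensions), dropping the redundant second accelerometer.
#'
#' @param x A `raw_trial` or `annotated_trial`.
#' @param channels Integer column indices to keep.
#' @return Object of the same class with reduced channels.
#' @export
select_channels <- function(x, channels = 1:6) {
  if (inherits(x, "annotated_trial")) {
    x$trial <- select_channels(x$trial, channels)
    return(x)
  }
  stopifnot(inherits(x, "raw_trial"))
  if (any(channels < 1L) || any(channels > ncol(x$samples))) {
    stop("channel index out of range", call. = FALSE)
  }
  x$samples <- x$samples[, channels, drop = FALSE]
  x
}

#' Write a trial (and optionally its annotations) in the SisFall dialect
#'
#' Physical units are converted back to integer ADC counts with the same
#' linear factors used by [read_raw_trial()], so that generated data exercise
#' the real reader path. Nine-channel trials are required (both
#' accelerometers plus gyroscope), matching the on-disk format.
#'
#' @param at An `annotated_trial` (or `raw_trial`; then no annotations are
#'   written) with 9 channels in physical units.
#' @param raw_dir Directory for the `.txt` trial file.
#' @param annot_dir Directory for the annotation file (same base name);
#'   `NULL` to skip.
#' @param scale A [sisfall_scales()] object.
#' @return Invisibly, the trial file path.
#' @export
write_sisfall_trial <- function(at, raw_dir, annot_dir = NULL,
                                scale = sisfall_scales()) {
  trial <- if (inherits(at, "annotated_trial")) at$trial else at
  stopifnot(inherits(trial, "raw_trial"))
  if (ncol(trial$samples) != 9L) {
    stop("SisFall writer requires 9 channels", call. = FALSE)
  }
  fac <- rep(c(scale$accel1, scale$gyro, scale$accel2), each = 3L)
  counts <- round(sweep(trial$samples, 2L, fac, `/`))
  fname <- sprintf("%s_%s_R%02d.txt", trial$activity_code, trial$subject_id,
                   trial$trial_index)
  dir.create(raw_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(raw_dir, fname)
  writeLines(paste0(apply(counts, 1L, paste, collapse = ","), ";"), path)
  if (!is.null(annot_dir) && inherits(at, "annotated_trial")) {
    dir.create(annot_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(as.character(at$labels), file.path(annot_dir, fname))
  }
  invisible(path)
}
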