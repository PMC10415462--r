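# Containers for raw multichannel EEG and vertex-space BOLD recordings.

#' Multichannel EEG recording
#'
#' @param data channels x samples matrix (microvolts).
#' @param rate sampling rate in Hz (> 0).
#' @param channel_labels unique channel names (default E001...).
#' @param events list of typed event times in seconds: `tr_triggers_s`,
#'   `cardiac_s`, `gswd_s` (each possibly empty).
#' @param condition `"inside"` or `"outside"` the MR scanner.
#' @param meta free-form metadata list.
#' @return A `sensor_recording` object.
#' @export
sensor_recording <- function(data, rate, channel_labels = NULL,
                             events = list(), condition = c("outside", "inside"),
                             meta = list()) {
  condition <- match.arg(condition)
  rc_assert(is.matrix(data) && is.numeric(data), "data must be a numeric matrix")
  rc_assert(rate > 0, "sampling rate must be positive")
  if (is.null(channel_labels))
    channel_labels <- sprintf("E%03d", seq_len(nrow(data)))
  rc_assert(!anyDuplicated(channel_labels), "channel labels must be unique")
  rc_assert(length(channel_labels) == nrow(data),
            "one label per channel required")
  events <- utils::modifyList(
    list(tr_triggers_s = numeric(0), cardiac_s = numeric(0),
         gswd_s = numeric(0)), events)
  span <- ncol(data) / rate
  for (nm in names(events)) {
    ev <- events[[nm]]
    rc_assert(all(ev >= 0 & ev <= span),
              paste0("event times in '", nm, "' outside recording span"))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate = as.numeric(rate),
                 channel_labels = channel_labels, events = events,
                 condition = condition, meta = meta),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> %d ch x %d samples @ %g Hz (%s), %d TR / %d cardiac / %d GSWD events\n",
    nrow(x$data), ncol(x$data), x$rate, x$condition,
    length(x$events$tr_triggers_s), length(x$events$cardiac_s),
    length(x$events$gswd_s)))
  invisible(x)
}

#' Vertex- or voxel-space BOLD recording
#'
#' @param series locations x volumes matrix (arbitrary units).
#' @param tr repetition time in seconds.
#' @param confounds per-volume data frame with columns `trans_x`, `trans_y`,
#'   `trans_z` (mm), `rot_x`, `rot_y`, `rot_z` (rad).
#' @param location_kind per-location tag: `"brain"`, `"wm"` or `"csf"`
#'   (white-matter-like and CSF-like nuisance locations drive the
#'   component-based confound regressors).
#' @param outlier_flags per-volume logical (default all FALSE).
#' @param flag_reason per-volume character reason.
#' @param space_tag `"vertex"` or `"voxel"`.
#' @param meta free-form metadata list.
#' @return A `bold_recording` object.
#' @export
bold_recording <- function(series, tr, confounds, location_kind = NULL,
                           outlier_flags = NULL, flag_reason = NULL,
                           space_tag = c("vertex", "voxel"), meta = list()) {
  space_tag <- match.arg(space_tag)
  rc_assert(is.matrix(series) && is.numeric(series),
            "series must be a numeric matrix")
  n_vol <- ncol(series)
  rc_assert(tr > 0, "tr must be positive")
  rc_assert(is.data.frame(confounds) && nrow(confounds) == n_vol,
            "confound rows must equal the volume count")
  if (is.null(location_kind)) location_kind <- rep("brain", nrow(series))
  rc_assert(length(location_kind) == nrow(series),
            "one location_kind per row required")
  if (is.null(outlier_flags)) outlier_flags <- rep(FALSE, n_vol)
  if (is.null(flag_reason)) flag_reason <- rep("", n_vol)
  rc_assert(length(outlier_flags) == n_vol, "one outlier flag per volume")
  structure(list(series = series, tr = as.numeric(tr), confounds = confounds,
                 location_kind = location_kind, outlier_flags = outlier_flags,
                 flag_reason = flag_reason, space_tag = space_tag, meta = meta),
            class = "bold_recording")
}

#' @export
print.bold_recording <- function(x, ...) {
  cat(sprintf(
    "<bold_recording> %d locations (%d brain) x %d volumes @ TR %g s, %d flagged\n",
    nrow(x$series), sum(x$location_kind == "brain"), ncol(x$series), x$tr,
    sum(x$outlier_flags)))
  invisible(x)
}
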