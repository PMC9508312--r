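#' Multichannel recording container
#'
#' A `pdc_recording` holds one subject/condition block of multichannel signal:
#' a channels x samples numeric matrix, ordered channel labels, and the
#' sampling rate.  Optional metadata (subject id, group, condition) travels
#' with the object through the pipeline.
#'
#' @param data numeric matrix, channels x samples.
#' @param labels character vector of channel names, one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param subject_id optional subject identifier.
#' @param condition optional condition tag ("EC" or "EO").
#' @param group optional group label ("patient" or "control").
#' @return An object of class `pdc_recording`.
#' @export
recording <- function(data, labels, fs, subject_id = NA_character_,
                      condition = NA_character_, group = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) {
    stop("number of labels (", length(labels), ") must match rows of data (",
         nrow(data), ")")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  rownames(data) <- labels
  structure(
    list(data = data, labels = labels, fs = fs,
         subject_id = subject_id, condition = condition, group = group),
    class = "pdc_recording"
  )
}

#' @export
print.pdc_recording <- function(x, ...) {
  cat(sprintf("<pdc_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$condition)) cat("  condition:", x$condition, "\n")
  if (!is.na(x$group)) cat("  group:", x$group, "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `pdc_recording`.
#' @return seconds of signal.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write a recording as a delimited matrix
#'
#' Writes channels x samples with a header row of channel labels (channels as
#' columns would be enormous for EEG, so the layout is one row per channel
#' with the label in the first column).
#'
#' @param rec a `pdc_recording`.
#' @param path output file path.
#' @param sep field separator, default tab.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  df <- data.frame(label = rec$labels, rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = c("label", seq_len(ncol(rec$data))),
                     quote = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path.
#' @param fs sampling rate in Hz (not stored in the delimited layout).
#' @param sep field separator.
#' @inheritParams recording
#' @return a `pdc_recording`.
#' @export
read_recording <- function(path, fs, sep = "\t", subject_id = NA_character_,
                           condition = NA_character_, group = NA_character_) {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  labels <- as.character(df[[1L]])
  data <- as.matrix(df[, -1L, drop = FALSE])
  recording(data, labels, fs, subject_id = subject_id,
            condition = condition, group = group)
}
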