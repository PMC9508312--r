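#' Frequency band definition
#'
#' @param name band name (conventionally "alpha", "beta", "gamma").
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return a `pdc_band` list.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "pdc_band")
}

#' Canonical analysis bands
#'
#' Alpha 8-13 Hz, beta 13-30 Hz, gamma 30-50 Hz.
#'
#' @return named list of `pdc_band` objects.
#' @export
default_bands <- function() {
  list(alpha = band_spec("alpha", 8, 13),
       beta = band_spec("beta", 13, 30),
       gamma = band_spec("gamma", 30, 50))
}

#' Re-reference a recording
#'
#' Subtracts the sample-wise mean of the reference channels from every other
#' channel (e.g. the binaural mean for mastoid references) and drops the
#' reference channels from the output.  An empty reference list is a no-op,
#' for data that is already referenced (synthetic recordings).
#'
#' @param rec a `pdc_recording`.
#' @param reference_labels character vector of reference channel names.
#' @return the re-referenced `pdc_recording`.
#' @export
rereference <- function(rec, reference_labels) {
  if (length(reference_labels) == 0L) return(rec)
  missing <- setdiff(reference_labels, rec$labels)
  if (length(missing) > 0) {
    stop("reference channel(s) not in recording: ",
         paste(missing, collapse = ", "))
  }
  ref_idx <- match(reference_labels, rec$labels)
  ref_mean <- colMeans(rec$data[ref_idx, , drop = FALSE])
  keep <- setdiff(seq_along(rec$labels), ref_idx)
  out <- sweep(rec$data[keep, , drop = FALSE], 2L, ref_mean, "-")
  recording(out, rec$labels[keep], rec$fs, subject_id = rec$subject_id,
            condition = rec$condition, group = rec$group)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the pass band is amplitude-preserving and phase distortion -- which
#' would corrupt directed (lag-based) estimates -- is eliminated.
#'
#' @param rec a `pdc_recording`.
#' @param f_lo,f_hi band edges in Hz; `f_hi` must be below Nyquist.
#' @param order filter order per pass (default 4).
#' @return the filtered `pdc_recording`.
#' @export
bandpass <- function(rec, f_lo, f_hi, order = 4L) {
  nyq <- rec$fs / 2
  if (f_hi >= nyq) stop("f_hi must be below the Nyquist frequency ", nyq)
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi")
  bf <- signal::butter(order, c(f_lo, f_hi) / nyq, type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  recording(out, rec$labels, rec$fs, subject_id = rec$subject_id,
            condition = rec$condition, group = rec$group)
}

#' Resample (decimate) a recording
#'
#' Downsamples to `fs_new`.  For decimation an 8th-order zero-phase
#' Butterworth low-pass at 80% of the new Nyquist frequency is applied first
#' as an anti-alias guard, then samples are taken at the new rate.
#' `fs_new == fs` is the identity.
#'
#' @param rec a `pdc_recording`.
#' @param fs_new target sampling rate in Hz, `0 < fs_new <= fs`.
#' @return the resampled `pdc_recording`.
#' @export
resample_recording <- function(rec, fs_new) {
  if (fs_new <= 0) stop("fs_new must be positive")
  if (fs_new > rec$fs) stop("upsampling is not supported")
  if (fs_new == rec$fs) return(rec)
  bf <- signal::butter(4L, 0.8 * fs_new / rec$fs, type = "low")
  low <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  n_new <- floor(ncol(rec$data) * fs_new / rec$fs)
  # sample the filtered signal at the new grid (nearest original sample)
  idx <- pmin(ncol(rec$data), round(seq_len(n_new) * rec$fs / fs_new))
  recording(low[, idx, drop = FALSE], rec$labels, fs_new,
            subject_id = rec$subject_id, condition = rec$condition,
            group = rec$group)
}

#' Session schedule of eyes-closed / eyes-open segments
#'
#' @param segments list of `c(condition, start_s, end_s)` triples or a
#'   data.frame with columns `condition`, `start_s`, `end_s`; segments must
#'   be non-overlapping and increasing.
#' @return a validated data.frame of class `pdc_schedule`.
#' @export
session_schedule <- function(segments) {
  if (is.data.frame(segments)) {
    df <- segments
  } else {
    df <- do.call(rbind, lapply(segments, function(s) {
      data.frame(condition = as.character(s[[1L]]),
                 start_s = as.numeric(s[[2L]]),
                 end_s = as.numeric(s[[3L]]))
    }))
  }
  if (!all(df$condition %in% c("EC", "EO"))) {
    stop("conditions must be 'EC' or 'EO'")
  }
  if (any(df$end_s <= df$start_s)) stop("segments must have end_s > start_s")
  o <- order(df$start_s)
  df <- df[o, , drop = FALSE]
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)])) {
    stop("segments must not overlap")
  }
  rownames(df) <- NULL
  class(df) <- c("pdc_schedule", "data.frame")
  df
}

#' Split a recording into eyes-closed and eyes-open parts
#'
#' Concatenates all segments of each condition in temporal order.  Segment
#' boundaries (in samples of the concatenated output) are attached as the
#' `segments` attribute so downstream model fitting can optionally respect
#' them.
#'
#' @param rec a `pdc_recording`.
#' @param schedule a `pdc_schedule` (or input accepted by
#'   [session_schedule()]).
#' @return named list with elements `EC` and `EO`; a condition with no
#'   scheduled time is `NULL`.
#' @export
split_conditions <- function(rec, schedule) {
  if (!inherits(schedule, "pdc_schedule")) {
    schedule <- session_schedule(schedule)
  }
  dur <- rec_duration(rec)
  if (any(schedule$end_s > dur + 1e-9)) {
    stop("schedule extends past the end of the recording (",
         sprintf("%.1f s", dur), ")")
  }
  out <- list(EC = NULL, EO = NULL)
  for (cond in c("EC", "EO")) {
    seg <- schedule[schedule$condition == cond, , drop = FALSE]
    if (nrow(seg) == 0L) next
    pieces <- lapply(seq_len(nrow(seg)), function(k) {
      i0 <- floor(seg$start_s[k] * rec$fs) + 1L
      i1 <- floor(seg$end_s[k] * rec$fs)
      rec$data[, i0:i1, drop = FALSE]
    })
    data <- do.call(cbind, pieces)
    r <- recording(data, rec$labels, rec$fs, subject_id = rec$subject_id,
                   condition = cond, group = rec$group)
    ends <- cumsum(vapply(pieces, ncol, integer(1)))
    attr(r, "segments") <- data.frame(start = c(1L, utils::head(ends, -1L) + 1L),
                                      end = ends)
    out[[cond]] <- r
  }
  out
}
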