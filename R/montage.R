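#' Standard 30-channel 10-20 montage
#'
#' Channel sets used throughout the pipeline: left and right lateral
#' hemispheres (12 channels each, odd/even 10-20 suffixes), the midline
#' z-chain (6 channels), and the five lobe regions (frontal, temporal,
#' central, parietal, occipital).  The hemispheric and regional sets each
#' partition the full 30-channel montage.
#'
#' @return a list of class `pdc_montage` with elements `labels`, `left`,
#'   `right`, `midline`, and `regions` (a named list F/T/C/P/O).
#' @export
montage_1020_30 <- function() {
  m <- list(
    labels = c("FP1", "FP2", "FZ", "F4", "F8", "F3", "F7", "FCZ", "FC4",
               "FT8", "FC3", "FT7", "CZ", "C4", "T8", "T7", "C3", "TP7",
               "TP8", "P7", "CPZ", "CP4", "CP3", "PZ", "P4", "P8", "P3",
               "OZ", "O2", "O1"),
    left = c("FP1", "F7", "F3", "FT7", "FC3", "T7", "C3", "TP7", "CP3",
             "P7", "P3", "O1"),
    right = c("FP2", "F8", "F4", "FT8", "FC4", "T8", "C4", "TP8", "CP4",
              "P8", "P4", "O2"),
    midline = c("FZ", "FCZ", "CZ", "CPZ", "PZ", "OZ"),
    regions = list(
      F = c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8"),
      T = c("FT7", "T7", "TP7", "FT8", "T8", "TP8"),
      C = c("FC3", "FCZ", "FC4", "C3", "CZ", "C4", "CP3", "CPZ", "CP4"),
      P = c("P7", "P3", "PZ", "P4", "P8"),
      O = c("O1", "OZ", "O2")
    )
  )
  class(m) <- "pdc_montage"
  validate_montage(m)
  m
}

#' Validate a montage
#'
#' Checks that left/right/midline and the regions each partition the label
#' set, with no duplicates.
#'
#' @param m a montage list with `labels`, `left`, `right`, `midline`,
#'   `regions`.
#' @return `m` invisibly; errors on inconsistency.
#' @export
validate_montage <- function(m) {
  hemi <- c(m$left, m$right, m$midline)
  if (anyDuplicated(hemi)) stop("hemisphere/midline sets overlap")
  if (!setequal(hemi, m$labels)) {
    stop("left/right/midline must partition the montage labels")
  }
  reg <- unlist(m$regions, use.names = FALSE)
  if (anyDuplicated(reg)) stop("region sets overlap")
  if (!setequal(reg, m$labels)) {
    stop("regions must partition the montage labels")
  }
  invisible(m)
}

#' @export
print.pdc_montage <- function(x, ...) {
  cat(sprintf("<pdc_montage> %d channels: left %d / right %d / midline %d\n",
              length(x$labels), length(x$left), length(x$right),
              length(x$midline)))
  cat("  regions:",
      paste(sprintf("%s(%d)", names(x$regions), lengths(x$regions)),
            collapse = " "), "\n")
  invisible(x)
}
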