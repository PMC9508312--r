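#' Partial directed coherence of a fitted MVAR model
#'
#' Evaluates, on a frequency grid, the normalized frequency-domain measure of
#' directed influence from channel j to channel i:
#' \deqn{PDC_{j \to i}(f) = |\bar A_{ij}(f)| / \sqrt{\sum_k |\bar A_{kj}(f)|^2}}
#' where \eqn{\bar A(f) = I - \sum_r A_r e^{-i 2 \pi (f/f_s) r}} is the
#' identity minus the Fourier transform of the coefficient series.  By
#' construction the squared PDC values in every column (source) sum to 1 at
#' every frequency: PDC measures the fraction of a channel's outflow directed
#' at each target.
#'
#' @param model a `pdc_mvar` (or a list of K x K coefficient matrices with
#'   a `labels` attribute convention as produced by [spec_coef_matrices()]).
#' @param freqs frequency grid in Hz, all below `fs / 2`.
#' @param fs sampling rate in Hz the model was fitted at.
#' @return an object of class `pdc_spectrum`: `values` (K x K x F array,
#'   `values[i, j, f]` = PDC from j to i), `freqs`, `labels`.
#' @export
pdc <- function(model, freqs = seq(1, 50, by = 0.5), fs) {
  if (inherits(model, "pdc_mvar")) {
    A <- model$coefficients
    labels <- model$labels
  } else {
    A <- model
    labels <- rownames(A[[1L]])
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(A[[1L]])))
  }
  K <- nrow(A[[1L]])
  p <- length(A)
  if (any(freqs >= fs / 2)) stop("all frequencies must be below fs/2")
  vals <- array(NA_real_, dim = c(K, K, length(freqs)),
                dimnames = list(labels, labels, NULL))
  I_K <- diag(K)
  for (fi in seq_along(freqs)) {
    z <- exp(-1i * 2 * pi * (freqs[fi] / fs) * seq_len(p))
    Abar <- I_K + 0i
    for (r in seq_len(p)) Abar <- Abar - A[[r]] * z[r]
    mag <- Mod(Abar)
    colnorm <- sqrt(colSums(mag^2))
    if (any(colnorm < 1e-12)) {
      stop("numerically zero outflow column at f = ", freqs[fi], " Hz")
    }
    vals[, , fi] <- sweep(mag, 2L, colnorm, "/")
  }
  structure(list(values = vals, freqs = freqs, labels = labels),
            class = "pdc_spectrum")
}

#' @export
print.pdc_spectrum <- function(x, ...) {
  cat(sprintf("<pdc_spectrum> %d x %d channels, %d frequencies (%g-%g Hz)\n",
              dim(x$values)[1L], dim(x$values)[2L], length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Band-averaged weighted directed connectivity matrix
#'
#' Arithmetic mean of the PDC magnitudes over the grid frequencies inside
#' the band (edges inclusive); the diagonal is then set to 0, following the
#' convention that self-influence is not part of the network.
#'
#' @param spec a `pdc_spectrum`.
#' @param band a `pdc_band`.
#' @param condition optional condition tag carried on the result.
#' @return an object of class `pdc_connectivity`: `weights` (K x K, entry
#'   (i, j) = band-mean PDC from j to i, zero diagonal), `band`, `labels`,
#'   `condition`.
#' @export
band_average <- function(spec, band, condition = NA_character_) {
  sel <- spec$freqs >= band$f_lo & spec$freqs <= band$f_hi
  if (!any(sel)) {
    stop("band ", band$name, " (", band$f_lo, "-", band$f_hi,
         " Hz) does not intersect the frequency grid")
  }
  W <- apply(spec$values[, , sel, drop = FALSE], c(1L, 2L), mean)
  diag(W) <- 0
  connectivity_matrix(W, spec$labels, band = band, condition = condition)
}

#' Construct a connectivity matrix object
#'
#' @param weights K x K numeric matrix in [0, 1] with zero diagonal; entry
#'   (i, j) is the directed weight from channel j to channel i.
#' @param labels channel names.
#' @param band optional `pdc_band`.
#' @param condition optional condition tag.
#' @return a `pdc_connectivity` object.
#' @export
connectivity_matrix <- function(weights, labels, band = NULL,
                                condition = NA_character_) {
  weights <- as.matrix(weights)
  K <- nrow(weights)
  if (ncol(weights) != K) stop("weights must be square")
  if (length(labels) != K) stop("labels must match matrix dimension")
  if (any(weights < 0)) stop("connectivity weights must be non-negative")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = as.character(labels),
                 band = band, condition = condition),
            class = "pdc_connectivity")
}

#' @export
print.pdc_connectivity <- function(x, ...) {
  bn <- if (is.null(x$band)) "?" else x$band$name
  cat(sprintf("<pdc_connectivity> %d nodes, band %s, mean off-diag %.4f\n",
              nrow(x$weights), bn, mean_pdc(x)))
  invisible(x)
}

#' Mean off-diagonal connectivity
#'
#' The grand mean of the K(K-1) off-diagonal weights: the "mean PDC" summary
#' compared between groups per band and condition.
#'
#' @param mat a `pdc_connectivity` (or square matrix with zero diagonal).
#' @return scalar mean.
#' @export
mean_pdc <- function(mat) {
  W <- if (inherits(mat, "pdc_connectivity")) mat$weights else as.matrix(mat)
  K <- nrow(W)
  if (K < 2L) stop("need at least 2 channels")
  sum(W[row(W) != col(W)]) / (K * (K - 1))
}

#' Magnitude-squared coherence (undirected baseline)
#'
#' Welch-averaged magnitude-squared coherence between every channel pair,
#' band-averaged:
#' \deqn{MSC_{xy}(f) = |S_{xy}(f)|^2 / (S_{xx}(f) S_{yy}(f))}
#' with the auto-/cross-spectra estimated from Hann-windowed overlapping
#' segments.  MSC is symmetric and carries no direction; it serves as the
#' conventional undirected reference against the directed PDC network.
#'
#' @param rec a `pdc_recording`.
#' @param band a `pdc_band` to average over.
#' @param window_s segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return a `pdc_connectivity` whose weight matrix is symmetric with zero
#'   diagonal.
#' @export
msc <- function(rec, band, window_s = 2, overlap = 0.5) {
  K <- nrow(rec$data)
  N <- ncol(rec$data)
  nwin <- round(window_s * rec$fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, N - nwin + 1L, by = step)
  if (length(starts) < 8L) {
    stop("record too short: need >= 8 averaging windows, have ",
         length(starts))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  freqs <- (seq_len(nwin) - 1L) * rec$fs / nwin
  sel <- freqs >= band$f_lo & freqs <= band$f_hi
  if (!any(sel)) stop("band does not intersect the spectral grid")
  nf <- sum(sel)
  Sxy <- array(0 + 0i, dim = c(K, K, nf))
  for (s in starts) {
    seg <- rec$data[, s:(s + nwin - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Fm <- t(stats::mvfft(t(seg * rep(w, each = K))))[, sel, drop = FALSE]
    for (fi in seq_len(nf)) {
      Sxy[, , fi] <- Sxy[, , fi] + tcrossprod(Fm[, fi], Conj(Fm[, fi]))
    }
  }
  C <- matrix(0, K, K)
  for (fi in seq_len(nf)) {
    S <- Sxy[, , fi]
    d <- Re(diag(S))
    C <- C + Mod(S)^2 / outer(d, d)
  }
  C <- C / nf
  diag(C) <- 0
  connectivity_matrix(C, rec$labels,
                      band = band, condition = rec$condition)
}
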