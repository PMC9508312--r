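#' Fit a multichannel autoregressive (MVAR) model
#'
#' Multivariate ordinary least squares on the (mean-removed) record: each
#' channel at time t is regressed on all channels at lags 1..p, minimizing
#' the one-step prediction error.  With `order = "auto"` the order is chosen
#' by Schwarz's Bayesian criterion (SBC) over 1..`max_order`, each candidate
#' fitted on the common sample range so criteria are comparable; the
#' criterion trace is stored on the returned model.
#'
#' @param rec a `pdc_recording` (or bare channels x samples matrix).
#' @param order integer model order, or `"auto"` for SBC selection.
#' @param max_order largest order considered when `order = "auto"`.
#' @return an object of class `pdc_mvar` with elements `order`,
#'   `coefficients` (list of K x K matrices A_1..A_p, entry (i, j) = effect
#'   of channel j at lag r on channel i), `noise_cov`, `labels`,
#'   `n_samples_used`, `residuals`, `sbc_trace`, and the companion
#'   `spectral_radius`.
#' @export
fit_mvar <- function(rec, order = "auto", max_order = 20L) {
  if (inherits(rec, "pdc_recording")) {
    Y <- rec$data
    labels <- rec$labels
  } else {
    Y <- as.matrix(rec)
    labels <- rownames(Y)
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(Y)))
  }
  K <- nrow(Y)
  N <- ncol(Y)
  sds <- apply(Y, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant channel(s): ", paste(labels[sds == 0], collapse = ", "))
  }
  p_max <- if (identical(order, "auto")) as.integer(max_order)
           else as.integer(order)
  if (N <= (p_max * K + 1) * 10) {
    stop("record too short for order ", p_max, ": need > ",
         (p_max * K + 1) * 10, " samples, have ", N)
  }
  Y <- Y - rowMeans(Y)

  fit_order <- function(p, t_start) {
    tt <- t_start:N                       # response times
    n_eff <- length(tt)
    X <- matrix(0, K * p, n_eff)          # stacked lagged predictors
    for (r in seq_len(p)) {
      X[((r - 1) * K + 1):(r * K), ] <- Y[, tt - r, drop = FALSE]
    }
    G <- tcrossprod(X)                    # (Kp) x (Kp)
    h <- tcrossprod(Y[, tt, drop = FALSE], X)   # K x (Kp)
    B <- t(solve(G, t(h)))                # K x (Kp)
    resid <- Y[, tt, drop = FALSE] - B %*% X
    list(B = B, resid = resid, n_eff = n_eff)
  }

  if (identical(order, "auto")) {
    t_start <- p_max + 1L
    n_eff <- N - p_max
    trace <- data.frame(order = 1:p_max, sbc = NA_real_)
    fits <- vector("list", p_max)
    for (p in 1:p_max) {
      f <- tryCatch(fit_order(p, t_start), error = function(e) NULL)
      if (is.null(f)) next
      S <- tcrossprod(f$resid) / f$n_eff
      ld <- determinant(S, logarithm = TRUE)
      if (ld$sign <= 0) next
      trace$sbc[p] <- as.numeric(ld$modulus) + (log(n_eff) / n_eff) * p * K^2
      fits[[p]] <- f
    }
    if (all(is.na(trace$sbc))) stop("SBC selection failed at every order")
    p_sel <- trace$order[which.min(trace$sbc)]
    # refit the winner on its own maximal sample range
    f <- fit_order(p_sel, p_sel + 1L)
    p <- p_sel
  } else {
    p <- as.integer(order)
    if (p < 1L) stop("order must be >= 1")
    f <- fit_order(p, p + 1L)
    trace <- data.frame(order = p, sbc = NA_real_)
  }
  A <- lapply(seq_len(p), function(r) {
    f$B[, ((r - 1) * K + 1):(r * K), drop = FALSE]
  })
  A <- lapply(A, function(a) { dimnames(a) <- list(labels, labels); a })
  dof <- f$n_eff - K * p
  noise_cov <- tcrossprod(f$resid) / max(1L, dof)
  dimnames(noise_cov) <- list(labels, labels)
  structure(
    list(order = p, coefficients = A, noise_cov = noise_cov,
         labels = labels, n_samples_used = f$n_eff, residuals = f$resid,
         sbc_trace = trace,
         spectral_radius = companion_spectral_radius(A)),
    class = "pdc_mvar"
  )
}

#' @export
print.pdc_mvar <- function(x, ...) {
  cat(sprintf(
    "<pdc_mvar> K = %d, order = %d, fitted on %d samples\n",
    length(x$labels), x$order, x$n_samples_used))
  cat(sprintf("  companion spectral radius %.4f\n", x$spectral_radius))
  invisible(x)
}
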