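#' Ground-truth directed coupling specification
#'
#' Describes a stationary multichannel vector autoregressive (VAR) generative
#' process: per-channel autoregressive "self" terms that shape each channel's
#' spectrum, directed cross-channel edges with a lag and coefficient, and
#' per-channel innovation standard deviations.  The companion-matrix spectral
#' radius must be below 1 (stationarity), which is asserted at construction.
#'
#' @param labels character vector of unique channel names (10-20 system for
#'   the default montage, but any unique names are accepted).
#' @param edges data.frame with columns `source`, `target`, `lag`, `coef`:
#'   directed coupling source -> target at the given lag (samples, >= 1).
#' @param self data.frame with columns `channel`, `lag`, `coef`: per-channel
#'   autoregressive terms.
#' @param noise_sd innovation standard deviation, scalar or one per channel.
#' @return an object of class `pdc_coupling_spec`.
#' @export
coupling_spec <- function(labels, edges = NULL, self = NULL, noise_sd = 1) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  K <- length(labels)
  empty <- data.frame(source = character(), target = character(),
                      lag = integer(), coef = numeric())
  if (is.null(edges)) edges <- empty
  if (is.null(self)) {
    self <- data.frame(channel = character(), lag = integer(),
                       coef = numeric())
  }
  edges <- as.data.frame(edges)
  self <- as.data.frame(self)
  if (nrow(edges) > 0) {
    bad <- setdiff(unique(c(edges$source, edges$target)), labels)
    if (length(bad) > 0) stop("unknown channels in edges: ",
                              paste(bad, collapse = ", "))
    if (any(edges$lag < 1)) stop("edge lags must be >= 1")
    if (any(edges$source == edges$target)) {
      stop("self terms belong in `self`, not `edges`")
    }
  }
  if (nrow(self) > 0) {
    bad <- setdiff(unique(self$channel), labels)
    if (length(bad) > 0) stop("unknown channels in self terms: ",
                              paste(bad, collapse = ", "))
    if (any(self$lag < 1)) stop("self-term lags must be >= 1")
  }
  noise_sd <- rep_len(as.numeric(noise_sd), K)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  spec <- structure(
    list(labels = labels, edges = edges, self = self, noise_sd = noise_sd),
    class = "pdc_coupling_spec"
  )
  rho <- companion_spectral_radius(spec)
  if (rho >= 1) {
    stop(sprintf(
      "coupling spec is non-stationary: companion spectral radius %.4f >= 1",
      rho))
  }
  spec
}

#' @export
print.pdc_coupling_spec <- function(x, ...) {
  cat(sprintf(
    "<pdc_coupling_spec> %d channels, %d cross edges, %d self terms\n",
    length(x$labels), nrow(x$edges), nrow(x$self)))
  cat(sprintf("  max lag %d, companion spectral radius %.4f\n",
              spec_order(x), companion_spectral_radius(x)))
  invisible(x)
}

#' Maximum lag of a coupling spec
#' @param spec a `pdc_coupling_spec`.
#' @return the VAR order implied by the largest lag (0 for pure noise).
#' @export
spec_order <- function(spec) {
  max(0L, spec$edges$lag, spec$self$lag)
}

#' Coefficient matrices of a coupling spec
#'
#' @param spec a `pdc_coupling_spec`.
#' @return list of K x K matrices A_1 ... A_p; entry (i, j) of A_r is the
#'   effect of channel j at lag r on channel i.
#' @export
spec_coef_matrices <- function(spec) {
  K <- length(spec$labels)
  p <- spec_order(spec)
  idx <- stats::setNames(seq_len(K), spec$labels)
  A <- lapply(seq_len(p), function(r) matrix(0, K, K))
  if (nrow(spec$self) > 0) {
    for (k in seq_len(nrow(spec$self))) {
      i <- idx[[spec$self$channel[k]]]
      r <- spec$self$lag[k]
      A[[r]][i, i] <- A[[r]][i, i] + spec$self$coef[k]
    }
  }
  if (nrow(spec$edges) > 0) {
    for (k in seq_len(nrow(spec$edges))) {
      i <- idx[[spec$edges$target[k]]]
      j <- idx[[spec$edges$source[k]]]
      r <- spec$edges$lag[k]
      A[[r]][i, j] <- A[[r]][i, j] + spec$edges$coef[k]
    }
  }
  A
}

#' Companion-matrix spectral radius
#'
#' Largest eigenvalue modulus of the VAR companion matrix; the process is
#' (covariance-)stationary iff this is strictly below 1.
#'
#' @param spec a `pdc_coupling_spec`, or a list of K x K coefficient
#'   matrices.
#' @return the spectral radius (0 for an empty model).
#' @export
companion_spectral_radius <- function(spec) {
  A <- if (inherits(spec, "pdc_coupling_spec")) spec_coef_matrices(spec)
       else spec
  p <- length(A)
  if (p == 0L) return(0)
  K <- nrow(A[[1L]])
  comp <- matrix(0, K * p, K * p)
  comp[seq_len(K), ] <- do.call(cbind, A)
  if (p > 1L) {
    comp[(K + 1):(K * p), seq_len(K * (p - 1))] <- diag(K * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Default 30-channel resting-EEG coupling spec
#'
#' Every channel carries a damped-oscillator AR(2) self term
#' `a1 = 2 * rho * cos(2 * pi * f0 / fs)`, `a2 = -rho^2` tuned to a ~10 Hz
#' spectral peak (the alpha band), plus nearest-neighbour directed
#' cross-edges: anterior-to-posterior chains within each lateral hemisphere
#' and along the midline, homologous right-to-left edges, a smaller set of
#' left-to-right edges, and midline-to-hemisphere links.  The right-to-left
#' and left-to-left cross-edges are the ones attenuated in the patient group
#' by [simulate_cohort()].
#'
#' The cross-edge coefficient defaults to half the oscillator's DC stability
#' margin, `0.5 * (1 - a1 - a2)`: the margin shrinks as `fs` grows (the pole
#' pair approaches z = 1), so a fixed coefficient would destabilize the
#' network at high sampling rates, while a margin-proportional one keeps the
#' relative coupling strength -- and the companion spectral radius --
#' comparable across rates.
#'
#' @param fs sampling rate in Hz the process is tuned for.
#' @param f0 oscillator peak frequency in Hz (default 10, mid-alpha).
#' @param rho oscillator pole modulus in (0, 1); closer to 1 gives a sharper
#'   spectral peak.
#' @param cross_coef coefficient of each lag-1 cross edge; `NULL` (default)
#'   uses half the AR(2) stability margin at this `fs`.
#' @param noise_sd innovation standard deviation.
#' @return a `pdc_coupling_spec` over the [montage_1020_30()] labels.
#' @export
default_base_spec <- function(fs = 500, f0 = 10, rho = 0.9,
                              cross_coef = NULL, noise_sd = 1) {
  m <- montage_1020_30()
  a1 <- 2 * rho * cos(2 * pi * f0 / fs)
  a2 <- -rho^2
  if (is.null(cross_coef)) cross_coef <- 0.5 * (1 - a1 - a2)
  self <- rbind(
    data.frame(channel = m$labels, lag = 1L, coef = a1),
    data.frame(channel = m$labels, lag = 2L, coef = a2)
  )
  chain <- function(chs) data.frame(source = chs[-length(chs)],
                                    target = chs[-1L])
  e <- rbind(
    # anterior -> posterior chains, left then right lateral strips
    chain(c("FP1", "F3", "C3", "P3", "O1")),
    chain(c("F7", "FT7", "T7", "TP7", "P7")),
    chain(c("FP2", "F4", "C4", "P4", "O2")),
    chain(c("F8", "FT8", "T8", "TP8", "P8")),
    # midline chain
    chain(c("FZ", "FCZ", "CZ", "CPZ", "PZ", "OZ")),
    # homologous right -> left
    data.frame(source = c("F4", "C4", "P4", "O2"),
               target = c("F3", "C3", "P3", "O1")),
    # left -> right
    data.frame(source = c("F3", "C3"), target = c("F4", "C4")),
    # midline -> hemispheres
    data.frame(source = c("CZ", "CZ"), target = c("C3", "C4"))
  )
  e$lag <- 1L
  e$coef <- cross_coef
  coupling_spec(m$labels, edges = e, self = self, noise_sd = noise_sd)
}

#' Simulate a multichannel recording from a coupling spec
#'
#' Draws Gaussian innovations, runs the VAR recursion from zero initial
#' conditions, and discards a burn-in of `10 * max_lag * n_channels` samples
#' so the retained block is (approximately) a draw from the stationary
#' distribution.  Deterministic given `seed`.
#'
#' @param spec a `pdc_coupling_spec` (stationary; asserted).
#' @param duration_s retained duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed.
#' @inheritParams recording
#' @return a `pdc_recording` of `duration_s * fs` samples.
#' @export
simulate_recording <- function(spec, duration_s, fs, seed,
                               subject_id = NA_character_,
                               condition = "EC", group = NA_character_) {
  stopifnot(inherits(spec, "pdc_coupling_spec"))
  rho <- companion_spectral_radius(spec)
  if (rho >= 1) {
    stop(sprintf(
      "non-stationary spec: companion spectral radius %.4f >= 1", rho))
  }
  K <- length(spec$labels)
  p <- spec_order(spec)
  n <- round(duration_s * fs)
  if (n < 10 * K * max(1L, p)) {
    stop("record too short: need at least 10 * n_channels * max_lag samples")
  }
  burn <- 10L * p * K
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  innov <- matrix(stats::rnorm((n + burn) * K), nrow = K) * spec$noise_sd
  if (p == 0L) {
    y <- innov
  } else {
    coef <- do.call(cbind, spec_coef_matrices(spec))
    y <- var_recurse(coef, innov, p)
  }
  y <- y[, (burn + 1L):(burn + n), drop = FALSE]
  recording(y, spec$labels, fs, subject_id = subject_id,
            condition = condition, group = group)
}

# save/restore the global RNG state so simulation seeds do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cohort design for the synthetic benchmark
#'
#' Describes a two-group cohort: patients carry attenuated directed coupling
#' on configured source -> target blocks (default: right-to-left and
#' left-to-left hemispheric edges), and Hamilton Depression Rating Scale
#' (HDRS) scores are generated as
#' `baseline - slope * (ground-truth coupling sum in the configured blocks) +
#' Gaussian noise`, clipped at >= 17 for patients (the usual inclusion
#' threshold for moderate depression) and at >= 0 for controls.  Because
#' patients have a smaller coupling sum than controls, HDRS is negatively
#' correlated with the attenuated-block connectivity across the cohort.
#'
#' @param n_patients,n_controls group sizes (>= 2 each).
#' @param attenuation multiplicative factor in [0, 1] applied to the
#'   patient-group coefficients of edges falling in `atten_blocks`.
#' @param hdrs_model numeric vector `c(baseline, slope, noise_sd)`, or
#'   `NULL` (default) to self-calibrate at simulation time: baseline 30,
#'   noise sd 2.5, and the slope chosen so an unattenuated (control)
#'   coupling sum maps to a healthy score of about 4.
#' @param duration_s per-subject recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed cohort-level integer seed; per-subject seeds are derived from
#'   it deterministically.
#' @param atten_blocks list of `list(sources = <labels>, targets = <labels>)`
#'   defining which directed edges are attenuated; default right->left and
#'   left->left over [montage_1020_30()].
#' @return an object of class `pdc_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 19, n_controls = 20, attenuation = 0.3,
                        hdrs_model = NULL,
                        duration_s = 240, fs = 500, seed = 1,
                        atten_blocks = NULL) {
  if (n_patients < 2 || n_controls < 2) stop("group sizes must be >= 2")
  if (attenuation < 0 || attenuation > 1) {
    stop("attenuation must lie in [0, 1]")
  }
  if (!is.null(hdrs_model) && length(hdrs_model) != 3L) {
    stop("hdrs_model must be c(baseline, slope, noise_sd) or NULL")
  }
  if (is.null(atten_blocks)) {
    m <- montage_1020_30()
    atten_blocks <- list(
      list(sources = m$right, targets = m$left),   # right -> left
      list(sources = m$left, targets = m$left)     # left -> left
    )
  }
  if (!is.null(hdrs_model)) {
    hdrs_model <- stats::setNames(as.numeric(hdrs_model),
                                  c("baseline", "slope", "noise_sd"))
  }
  structure(
    list(n_patients = n_patients, n_controls = n_controls,
         attenuation = attenuation,
         hdrs_model = hdrs_model,
         duration_s = duration_s, fs = fs, seed = as.integer(seed),
         atten_blocks = atten_blocks),
    class = "pdc_cohort_spec"
  )
}

# which rows of spec$edges fall in any configured source -> target block
.block_edge_rows <- function(spec, atten_blocks) {
  if (nrow(spec$edges) == 0L) return(integer())
  hit <- rep(FALSE, nrow(spec$edges))
  for (b in atten_blocks) {
    hit <- hit | (spec$edges$source %in% b$sources &
                  spec$edges$target %in% b$targets)
  }
  which(hit)
}

#' Ground-truth coupling sum over the attenuated blocks
#'
#' Sum of the generating cross-edge coefficients that fall in the cohort's
#' configured blocks; the quantity the HDRS model is driven by.
#'
#' @param spec a `pdc_coupling_spec`.
#' @param atten_blocks block list as in [cohort_spec()].
#' @return scalar coefficient sum.
#' @export
block_coupling_sum <- function(spec, atten_blocks) {
  rows <- .block_edge_rows(spec, atten_blocks)
  sum(spec$edges$coef[rows])
}

#' Simulate a two-group cohort of recordings
#'
#' Builds the patient-group coupling spec by multiplying the base spec's
#' coefficients in the configured blocks by `attenuation`, then simulates one
#' recording per subject with a deterministic per-subject seed and draws the
#' HDRS score from the cohort's HDRS model.
#'
#' @param cohort a `pdc_cohort_spec`.
#' @param base a `pdc_coupling_spec`; default [default_base_spec()] at the
#'   cohort's sampling rate.
#' @return a list with `recordings` (list of `pdc_recording`), `meta`
#'   (data.frame: id, group, hdrs, seed), and `ground_truth` (the two specs
#'   and their configured-block coupling sums).
#' @export
simulate_cohort <- function(cohort, base = default_base_spec(cohort$fs)) {
  stopifnot(inherits(cohort, "pdc_cohort_spec"),
            inherits(base, "pdc_coupling_spec"))
  rows <- .block_edge_rows(base, cohort$atten_blocks)
  if (length(rows) == 0L) {
    warning("no base edges fall in the configured attenuation blocks; ",
            "attenuation is a no-op")
  }
  patient_spec <- base
  patient_spec$edges$coef[rows] <- base$edges$coef[rows] * cohort$attenuation
  # revalidate stationarity of the modified spec
  patient_spec <- coupling_spec(patient_spec$labels, patient_spec$edges,
                                patient_spec$self, patient_spec$noise_sd)

  n <- cohort$n_patients + cohort$n_controls
  group <- c(rep("patient", cohort$n_patients),
             rep("control", cohort$n_controls))
  ids <- sprintf("S%02d", seq_len(n))
  seeds <- (as.numeric(cohort$seed) * 10007 + 7919 * seq_len(n)) %% 2147483647
  seeds <- as.integer(seeds)

  s_pat <- block_coupling_sum(patient_spec, cohort$atten_blocks)
  s_con <- block_coupling_sum(base, cohort$atten_blocks)
  hm <- cohort$hdrs_model
  if (is.null(hm)) {
    slope <- if (s_con > 0) (30 - 4) / s_con else 0
    hm <- c(baseline = 30, slope = slope, noise_sd = 2.5)
  }

  recs <- vector("list", n)
  hdrs <- numeric(n)
  for (i in seq_len(n)) {
    spec_i <- if (group[i] == "patient") patient_spec else base
    recs[[i]] <- simulate_recording(spec_i, cohort$duration_s, cohort$fs,
                                    seed = seeds[i], subject_id = ids[i],
                                    condition = "EC", group = group[i])
    s_i <- if (group[i] == "patient") s_pat else s_con
    old <- .Random.seed_save()
    set.seed(seeds[i] %% 1000003L + 1L)
    raw <- hm[["baseline"]] - hm[["slope"]] * s_i +
      stats::rnorm(1, 0, hm[["noise_sd"]])
    .Random.seed_restore(old)
    hdrs[i] <- if (group[i] == "patient") max(17, raw) else max(0, raw)
  }
  list(
    recordings = recs,
    meta = data.frame(id = ids, group = group, hdrs = hdrs, seed = seeds,
                      stringsAsFactors = FALSE),
    ground_truth = list(control_spec = base, patient_spec = patient_spec,
                        control_block_sum = s_con, patient_block_sum = s_pat,
                        hdrs_model = hm)
  )
}

#' Write cohort metadata as a delimited table
#' @param meta the `meta` data.frame from [simulate_cohort()].
#' @param path output path.
#' @export
write_cohort_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a coupling spec to JSON
#' @param spec a `pdc_coupling_spec`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the path, or the JSON string when `path` is `NULL`.
#' @export
spec_to_json <- function(spec, path = NULL) {
  obj <- list(labels = spec$labels, edges = spec$edges, self = spec$self,
              noise_sd = spec$noise_sd)
  js <- jsonlite::toJSON(obj, dataframe = "columns", digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a coupling spec from JSON written by [spec_to_json()]
#' @param path file path or JSON string.
#' @return a `pdc_coupling_spec`.
#' @export
spec_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  edges <- as.data.frame(obj$edges)
  self <- as.data.frame(obj$self)
  if (nrow(edges) > 0) edges$lag <- as.integer(edges$lag)
  if (nrow(self) > 0) self$lag <- as.integer(self$lag)
  coupling_spec(obj$labels,
                edges = if (nrow(edges)) edges else NULL,
                self = if (nrow(self)) self else NULL,
                noise_sd = obj$noise_sd)
}
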