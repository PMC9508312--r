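# minimal hand-built model objects: a list of coefficient matrices is
# accepted by pdc() directly
mk_model <- function(...) {
  A <- list(...)
  lapply(A, function(a) {
    dimnames(a) <- list(c("c1", "c2", "c3")[seq_len(nrow(a))],
                        c("c1", "c2", "c3")[seq_len(nrow(a))])
    a
  })
}

test_that("diagonal models have zero cross-channel PDC", {
  A <- mk_model(diag(c(0.5, -0.3, 0.2)))
  sp <- pdc(A, freqs = seq(1, 40, by = 1), fs = 100)
  off <- sp$values
  for (f in seq_along(sp$freqs)) diag(off[, , f]) <- 0
  expect_equal(max(abs(off)), 0)
})

test_that("the unidirectional 2-channel model matches the hand-computed value", {
  A1 <- matrix(c(0.5, 0, 0.7, 0), 2, 2, byrow = TRUE)
  sp <- pdc(mk_model(A1[1:2, 1:2]), freqs = c(0.0001, 5, 10), fs = 100)
  # at f -> 0: Abar = I - A1, column 1 = (0.5, -0.7)
  expect_equal(sp$values[2, 1, 1], 0.7 / sqrt(0.5^2 + 0.7^2),
               tolerance = 1e-6)
  expect_equal(sp$values[1, 2, ], rep(0, 3))
})

test_that("squared PDC sums to 1 over targets for every source and frequency", {
  # hand model
  sp <- pdc(mk_model(matrix(c(0.5, 0.1, -0.2, 0.4), 2, 2)),
            freqs = seq(1, 45, by = 0.5), fs = 100)
  sums <- apply(sp$values^2, c(2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)

  # fitted model on simulated data
  rec <- simulate_recording(known_mvar3_spec(), 60, 100, seed = 41)
  m <- fit_mvar(rec, order = 2)
  sp <- pdc(m, freqs = seq(1, 45, by = 0.5), fs = 100)
  sums <- apply(sp$values^2, c(2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-9)
})

test_that("pdc matches a symbolic evaluation of the formula on a 3-channel model", {
  A <- known_mvar3()
  freqs <- c(2, 8, 13, 25)
  fs <- 100
  sp <- pdc(mk_model(A[[1]], A[[2]]), freqs = freqs, fs = fs)
  for (fi in seq_along(freqs)) {
    Abar <- diag(3) - A[[1]] * exp(-2i * pi * freqs[fi] / fs) -
      A[[2]] * exp(-2i * pi * freqs[fi] * 2 / fs)
    for (j in 1:3) {
      for (i in 1:3) {
        expect_equal(sp$values[i, j, fi],
                     Mod(Abar[i, j]) / sqrt(sum(Mod(Abar[, j])^2)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("band averaging is the in-band arithmetic mean with a zeroed diagonal", {
  set.seed(42)
  K <- 4
  freqs <- seq(1, 30, by = 1)
  vals <- array(runif(K * K * length(freqs)), c(K, K, length(freqs)))
  spec <- structure(list(values = vals, freqs = freqs,
                         labels = paste0("c", 1:K)),
                    class = "pdc_spectrum")

  alpha <- band_spec("alpha", 8, 13)
  cm <- band_average(spec, alpha)
  sel <- which(freqs >= 8 & freqs <= 13)
  manual <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) manual[i, j] <- mean(vals[i, j, sel])
  diag(manual) <- 0
  expect_equal(cm$weights, manual, ignore_attr = TRUE, tolerance = 1e-14)

  # constant spectrum: every off-diagonal equals the constant
  vals2 <- array(0.37, c(K, K, length(freqs)))
  spec2 <- structure(list(values = vals2, freqs = freqs,
                          labels = paste0("c", 1:K)),
                     class = "pdc_spectrum")
  cm2 <- band_average(spec2, alpha)
  expect_true(all(cm2$weights[row(cm2$weights) != col(cm2$weights)] == 0.37))
  expect_true(all(diag(cm2$weights) == 0))

  # a band covering exactly two grid points averages them
  vals3 <- vals2
  vals3[2, 1, freqs == 9] <- 0.2
  vals3[2, 1, freqs == 10] <- 0.4
  spec3 <- structure(list(values = vals3, freqs = freqs,
                          labels = paste0("c", 1:K)),
                     class = "pdc_spectrum")
  cm3 <- band_average(spec3, band_spec("narrow", 9, 10))
  expect_equal(cm3$weights[2, 1], 0.3, ignore_attr = TRUE)

  expect_error(band_average(spec, band_spec("x", 31.2, 31.8)),
               "does not intersect")
})

test_that("mean_pdc averages the off-diagonal entries", {
  W <- matrix(0.1, 5, 5); diag(W) <- 0
  expect_equal(mean_pdc(connectivity_matrix(W, paste0("c", 1:5))), 0.1)
  W2 <- matrix(c(0, 0.4, 0.2, 0), 2, 2)
  expect_equal(mean_pdc(W2), 0.3)
  set.seed(43)
  W3 <- matrix(runif(900), 30, 30); diag(W3) <- 0
  manual <- 0; n <- 0
  for (i in 1:30) for (j in 1:30) if (i != j) {
    manual <- manual + W3[i, j]; n <- n + 1
  }
  expect_equal(mean_pdc(W3), manual / n, tolerance = 1e-14)
})

test_that("directionality: unidirectional coupling is recovered asymmetrically", {
  spec <- coupling_spec(
    c("c1", "c2"),
    edges = data.frame(source = "c1", target = "c2", lag = 1L, coef = 0.7),
    self = data.frame(channel = c("c1", "c2"), lag = 1L, coef = 0.3))
  rec <- simulate_recording(spec, 120, 100, seed = 44)
  m <- fit_mvar(rec, order = 1)
  sp <- pdc(m, freqs = seq(8, 13, by = 0.5), fs = 100)
  cm <- band_average(sp, band_spec("alpha", 8, 13))
  expect_gt(cm$weights["c2", "c1"], 0.5)   # 1 -> 2 strong
  expect_lt(cm$weights["c1", "c2"], 0.1)   # 2 -> 1 absent
})

test_that("estimated band PDC converges to the ground truth", {
  spec <- known_mvar3_spec()
  rec <- simulate_recording(spec, 300, 100, seed = 45)
  m <- fit_mvar(rec, order = 2)
  freqs <- seq(1, 45, by = 0.5)
  est <- pdc(m, freqs, fs = 100)
  truth <- pdc(spec_coef_matrices(spec), freqs, fs = 100)
  expect_lt(max(abs(est$values - truth$values)), 0.05)
})

test_that("msc is 1 for duplicated channels, small for independent noise, scale-free", {
  set.seed(46)
  x <- rnorm(12000)
  rec <- recording(rbind(x, x), c("a", "b"), 100)
  cm <- msc(rec, band_spec("alpha", 8, 13))
  expect_equal(cm$weights[2, 1], 1, tolerance = 1e-6, ignore_attr = TRUE)

  y <- rnorm(12000)
  rec2 <- recording(rbind(x, y), c("a", "b"), 100)
  cm2 <- msc(rec2, band_spec("alpha", 8, 13))
  expect_lt(cm2$weights[2, 1], 0.15)

  rec3 <- recording(rbind(3.7 * x, 0.2 * y), c("a", "b"), 100)
  cm3 <- msc(rec3, band_spec("alpha", 8, 13))
  expect_equal(cm3$weights, cm2$weights, tolerance = 1e-10)

  expect_true(isSymmetric(cm2$weights))
  short <- recording(rbind(x[1:500], y[1:500]), c("a", "b"), 100)
  expect_error(msc(short, band_spec("alpha", 8, 13)), "windows")
})
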