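test_that("a spec with no dynamics yields white noise", {
  spec <- coupling_spec(c("a", "b", "c"))
  rec <- simulate_recording(spec, 60, 100, seed = 11)
  for (i in 1:3) {
    x <- rec$data[i, ]
    r1 <- stats::cor(x[-1], x[-length(x)])
    expect_lt(abs(r1), 0.05)
  }
  expect_equal(companion_spectral_radius(spec), 0)
})

test_that("AR(1) sample variance matches the closed form sigma^2/(1 - a^2)", {
  spec <- coupling_spec("ch", self = data.frame(channel = "ch", lag = 1L,
                                                coef = 0.5), noise_sd = 1)
  rec <- simulate_recording(spec, 120, 100, seed = 3)
  expect_equal(stats::var(as.numeric(rec$data)), 1 / (1 - 0.25),
               tolerance = 0.1 / (1 / (1 - 0.25)))
})

test_that("a 1 -> 2 edge puts the cross-correlation peak at lag +1", {
  spec <- coupling_spec(
    c("c1", "c2"),
    edges = data.frame(source = "c1", target = "c2", lag = 1L, coef = 0.7))
  rec <- simulate_recording(spec, 120, 100, seed = 5)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  # brute-force cross-correlogram over lags -5..5
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    if (l >= 0) stats::cor(y[(1 + l):length(y)], x[1:(length(x) - l)])
    else stats::cor(y[1:(length(y) + l)], x[(1 - l):length(x)])
  }, numeric(1))
  expect_equal(lags[which.max(abs(cc))], 1)
})

test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  spec <- default_base_spec(fs = 100)
  r1 <- simulate_recording(spec, 20, 100, seed = 42)
  set.seed(999)
  before <- .Random.seed
  r2 <- simulate_recording(spec, 20, 100, seed = 42)
  expect_identical(r1$data, r2$data)
  expect_identical(before, .Random.seed)
})

test_that("non-stationary specs are rejected with a spectral-radius diagnostic", {
  expect_error(
    coupling_spec("ch", self = data.frame(channel = "ch", lag = 1L,
                                          coef = 1.05)),
    "spectral radius")
  err <- tryCatch(
    coupling_spec("ch", self = data.frame(channel = "ch", lag = 1L,
                                          coef = 1.05)),
    error = conditionMessage)
  expect_match(err, "1\\.05|1\\.0500")
})

test_that("default base spec is stationary with alpha-band self terms", {
  for (fs in c(100, 120, 250, 500)) {
    spec <- default_base_spec(fs = fs)
    expect_lt(companion_spectral_radius(spec), 1)
    expect_equal(length(spec$labels), 30)
  }
  # AR(2) poles at rho * exp(+/- i 2 pi 10 / fs)
  spec <- default_base_spec(fs = 500)
  a1 <- spec$self$coef[spec$self$channel == "FP1" & spec$self$lag == 1]
  expect_equal(a1, 2 * 0.9 * cos(2 * pi * 10 / 500))
})

test_that("attenuation semantics: identity at 1, zeroing at 0, exact scaling between", {
  base <- default_base_spec(fs = 100)
  m <- montage_1020_30()
  blocks <- list(list(sources = m$right, targets = m$left),
                 list(sources = m$left, targets = m$left))

  ch1 <- cohort_spec(n_patients = 2, n_controls = 2, attenuation = 1,
                     duration_s = 8, fs = 100, seed = 1)
  sim1 <- simulate_cohort(ch1, base)
  expect_identical(sim1$ground_truth$patient_spec$edges,
                   sim1$ground_truth$control_spec$edges)

  ch0 <- cohort_spec(n_patients = 2, n_controls = 2, attenuation = 0,
                     duration_s = 8, fs = 100, seed = 1)
  sim0 <- simulate_cohort(ch0, base)
  pe <- sim0$ground_truth$patient_spec$edges
  in_block <- (pe$source %in% m$right & pe$target %in% m$left) |
              (pe$source %in% m$left & pe$target %in% m$left)
  expect_true(all(pe$coef[in_block] == 0))
  expect_identical(pe$coef[!in_block], base$edges$coef[!in_block])

  ch4 <- cohort_spec(n_patients = 2, n_controls = 2, attenuation = 0.4,
                     duration_s = 8, fs = 100, seed = 1)
  sim4 <- simulate_cohort(ch4, base)
  expect_equal(block_coupling_sum(sim4$ground_truth$patient_spec, blocks),
               0.4 * block_coupling_sum(base, blocks))
})

test_that("cohorts are bit-identical across repeated runs of the same seed", {
  ch <- cohort_spec(n_patients = 3, n_controls = 3, attenuation = 0.4,
                    duration_s = 8, fs = 100, seed = 7)
  base <- default_base_spec(fs = 100)
  s1 <- simulate_cohort(ch, base)
  s2 <- simulate_cohort(ch, base)
  expect_identical(lapply(s1$recordings, `[[`, "data"),
                   lapply(s2$recordings, `[[`, "data"))
  expect_identical(s1$meta, s2$meta)
})

test_that("patient HDRS scores are clipped at >= 17 and negatively tied to coupling", {
  ch <- cohort_spec(n_patients = 6, n_controls = 6, attenuation = 0.2,
                    duration_s = 8, fs = 100, seed = 21)
  sim <- simulate_cohort(ch, default_base_spec(fs = 100))
  pat <- sim$meta$group == "patient"
  expect_true(all(sim$meta$hdrs[pat] >= 17))
  expect_true(all(sim$meta$hdrs >= 0))
  # attenuated patients have the smaller ground-truth coupling sum
  expect_lt(sim$ground_truth$patient_block_sum,
            sim$ground_truth$control_block_sum)
  expect_gt(mean(sim$meta$hdrs[pat]), mean(sim$meta$hdrs[!pat]))
})

test_that("attenuation outside configured edges warns and is a no-op", {
  spec <- coupling_spec(
    c("a", "b"),
    edges = data.frame(source = "a", target = "b", lag = 1L, coef = 0.3),
    self = data.frame(channel = c("a", "b"), lag = 1L, coef = 0.4))
  ch <- cohort_spec(n_patients = 2, n_controls = 2, attenuation = 0.5,
                    duration_s = 8, fs = 100, seed = 2,
                    atten_blocks = list(list(sources = "b", targets = "a")))
  expect_warning(sim <- simulate_cohort(ch, spec), "no-op")
  expect_identical(sim$ground_truth$patient_spec$edges, spec$edges)
})

test_that("coupling specs round-trip through JSON", {
  spec <- default_base_spec(fs = 250)
  path <- withr::local_tempfile(fileext = ".json")
  spec_to_json(spec, path)
  back <- spec_from_json(path)
  expect_equal(back$labels, spec$labels)
  expect_equal(back$edges, spec$edges)
  expect_equal(back$self, spec$self)
  expect_equal(back$noise_sd, spec$noise_sd)
})

test_that("recordings round-trip through the delimited format", {
  spec <- coupling_spec(c("a", "b", "c"))
  rec <- simulate_recording(spec, 5, 100, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path, fs = 100)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$data, rec$data, ignore_attr = TRUE, tolerance = 1e-12)
})
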