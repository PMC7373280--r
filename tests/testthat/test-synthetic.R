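test_that("waveform matches its closed form at the endpoints", {
  # noise-free: s(length-1) - s(0) ~ direction * A * (1 + dysmetria)
  for (case in list(list(tau = 2.5, dys = 0, dir = 1, angle = 30),
                    list(tau = 5, dys = 0.15, dir = 1, angle = 60),
                    list(tau = 4, dys = 0.2, dir = -1, angle = 10))) {
    sh <- shape_params(case$tau, dysmetria_fraction = case$dys,
                       noise_sd = 0, baseline_sd = 0)
    w <- generate_saccade_waveform(sh, case$angle, case$dir, t0 = 96,
                                   length = 192, seed = 1)
    expected <- case$dir * case$angle * (1 + case$dys)
    # logistic tails decay within ~tau * log scale; generous tolerance
    expect_equal(w[192] - w[1], expected, tolerance = 1e-3)
  }
})

test_that("tau -> 0 limit is a step at t0", {
  sh <- shape_params(1e-6, noise_sd = 0, baseline_sd = 0)
  w <- generate_saccade_waveform(sh, 30, 1, t0 = 96, length = 192,
                                 seed = 1)
  expect_equal(w[1:96], rep(0, 96), tolerance = 1e-9)  # samples t < 96
  expect_equal(w[98:192], rep(30, 95), tolerance = 1e-9)
})

test_that("opposite directions under one seed are exact mirrors", {
  sh <- shape_params(3, noise_sd = 0.5, baseline_sd = 0)
  wp <- generate_saccade_waveform(sh, 20, 1, seed = 77)
  wm <- generate_saccade_waveform(sh, 20, -1, seed = 77)
  expect_equal(wm, -wp, tolerance = 1e-12)
})

test_that("waveform parameter validation", {
  expect_error(shape_params(0), "tau")
  expect_error(shape_params(2, dysmetria_fraction = 1), "dysmetria")
  sh <- shape_params(2)
  expect_error(generate_saccade_waveform(sh, 30, 1, t0 = 200), "t0")
  expect_error(generate_saccade_waveform(sh, 30, 2), "direction")
})

test_that("generated datasets have the promised label-noise structure", {
  cfg <- small_gen_config(seed = 5, contamination = 0.6)
  ds <- generate_dataset(cfg)
  # given labels always match the register diagnosis (validated on build),
  # and true shape labels differ only inside P registers
  m <- ds$meta
  expect_true(all(m$true_shape_label[m$given_label != "P"] ==
                    m$given_label[m$given_label != "P"]))
  per_reg <- split(m$true_shape_label[m$given_label == "P"],
                   m$register_id[m$given_label == "P"])
  for (lab in per_reg) {
    n_c <- round(0.6 * length(lab))
    expect_equal(sum(lab == "C"), n_c)
    expect_gte(sum(lab == "P"), 1L)
  }
})

test_that("contamination boundaries behave (rho = 0 and rho = 1)", {
  ds0 <- generate_dataset(small_gen_config(seed = 8, contamination = 0))
  m0 <- ds0$meta
  expect_true(all(m0$true_shape_label[m0$given_label == "P"] == "P"))

  ds1 <- generate_dataset(small_gen_config(seed = 8, contamination = 1))
  m1 <- ds1$meta
  perreg <- tapply(m1$true_shape_label[m1$given_label == "P"] == "P",
                   m1$register_id[m1$given_label == "P"], sum)
  expect_true(all(perreg == 1L))  # the at-least-one-P-shaped guard
})

test_that("generation is a pure function of config + seed", {
  a <- generate_dataset(small_gen_config(seed = 31))
  b <- generate_dataset(small_gen_config(seed = 31))
  c <- generate_dataset(small_gen_config(seed = 32))
  expect_identical(a$samples, b$samples)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$samples, c$samples))
})

test_that("normalized windows have ~30 degree displacement, rightward", {
  ds <- generate_dataset(small_gen_config(seed = 12))
  disp <- ds$samples[, 192] - ds$samples[, 1]
  expect_true(all(disp > 0))
  # C and P shapes settle fully; S dysmetria adds its secondary step
  expect_equal(mean(disp[ds$meta$true_shape_label == "C"]), 30,
               tolerance = 0.05)
})

test_that("class shapes are separable by a nearest-centroid oracle", {
  # noise-free C vs P waveforms with a 2x tau ratio must be perfectly
  # separable by nearest centroid (the premise the SOM stage relies on)
  mk <- function(tau, n) {
    t(vapply(seq_len(n), function(i) {
      sh <- shape_params(tau, noise_sd = 0, baseline_sd = 0)
      generate_saccade_waveform(sh, 30, 1, seed = i)
    }, numeric(192)))
  }
  A <- mk(2.5, 10)
  B <- mk(5, 10)
  cA <- colMeans(A); cB <- colMeans(B)
  near <- function(x) {
    c(sum((x - cA)^2), sum((x - cB)^2))
  }
  labs <- apply(rbind(A, B), 1, function(x) which.min(near(x)))
  expect_equal(labs, rep(c(1L, 2L), each = 10))
})

test_that("raw trace generator returns correct ground truth", {
  plan <- list(list(fixation = 150),
               list(angle = 30, tau = 4, direction = 1, duration = 60),
               list(fixation = 150),
               list(angle = 20, tau = 4, direction = -1, duration = 60),
               list(fixation = 150))
  tr <- generate_raw_trace(plan, noise_sd = 0, seed = 1)
  expect_equal(length(tr$trace), 150 + 60 + 150 + 60 + 150)
  expect_equal(nrow(tr$intervals), 2L)
  # interval interior contains all samples with |diff| above half the peak
  v <- abs(diff(tr$trace))
  for (i in 1:2) {
    seg <- tr$intervals[i, ]
    big <- which(v >= 0.5 * max(v[(seg[1] + 1):(seg[2] - 1)]))
    # restrict to this saccade's neighborhood
    big <- big[big > seg[1] - 30 & big < seg[2] + 30]
    expect_true(all(big >= seg[1] + 1 & big <= seg[2] - 1 + 1))
  }
  # trace levels: ends at 30 - 20 = 10 degrees
  expect_equal(tr$trace[length(tr$trace)], 10, tolerance = 1e-9)
  # determinism with noise
  t1 <- generate_raw_trace(plan, noise_sd = 0.3, seed = 4)
  t2 <- generate_raw_trace(plan, noise_sd = 0.3, seed = 4)
  expect_identical(t1$trace, t2$trace)
  # degenerate plans error
  expect_error(generate_raw_trace(list()), "non-empty")
  expect_error(generate_raw_trace(list(list(angle = 10))), "tau")
})
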