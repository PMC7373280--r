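test_that("relabel decision branches match the worked examples", {
  # strict S plurality wins regardless of theta
  expect_equal(relabel_saccade(c(1, 2, 5), 2), "S")
  expect_equal(relabel_saccade(c(1, 2, 5), 4.5), "S")
  # |P| = 0 branch
  expect_equal(relabel_saccade(c(4, 0, 1), 2), "C")
  # ratio branch at theta = 2: C must be at least double P to stay C
  expect_equal(relabel_saccade(c(2, 1, 0), 2), "C")
  expect_equal(relabel_saccade(c(1, 1, 0), 2), "P")
  # theta = 4
  expect_equal(relabel_saccade(c(3, 1, 0), 4), "P")
  expect_equal(relabel_saccade(c(4, 1, 0), 4), "C")
  # nC = 0, nP > 0: ratio 0 < theta -> P (no special case)
  expect_equal(relabel_saccade(c(0, 1, 0), 2), "P")
  # S tie is not a strict plurality; falls through to the ratio rule
  expect_equal(relabel_saccade(c(2, 1, 2), 2), "C")
  expect_error(relabel_saccade(c(0, 0, 0), 2), "at least one")
})

test_that("relabel_saccade agrees with the brute-force decision tree", {
  # exhaustive: all 11^3 = 1331 triples, minus the all-zero one
  grid <- expand.grid(nC = 0:10, nP = 0:10, nS = 0:10)
  grid <- grid[rowSums(grid) > 0, ]
  for (theta in c(2, 3, 4, 4.5)) {
    got <- mapply(function(a, b, c) relabel_saccade(c(a, b, c), theta),
                  grid$nC, grid$nP, grid$nS)
    want <- mapply(oracle_relabel, grid$nC, grid$nP, grid$nS, theta)
    expect_identical(unname(got), unname(want))
  }
})

test_that("the P cell set grows monotonically with theta", {
  # for fixed counts, cells labeled P at a smaller theta stay P at a larger
  grid <- expand.grid(nC = 0:8, nP = 0:8, nS = 0:8)
  grid <- grid[rowSums(grid) > 0, ]
  thetas <- c(2, 3, 4, 4.5)
  lab <- sapply(thetas, function(th) {
    mapply(function(a, b, c) relabel_saccade(c(a, b, c), th),
           grid$nC, grid$nP, grid$nS)
  })
  for (i in seq_len(length(thetas) - 1)) {
    expect_true(all(lab[lab[, i] == "P", i + 1] == "P"))
    # and S decisions never vary with theta
    expect_identical(lab[, i] == "S", lab[, i + 1] == "S")
  }
})

test_that("relabeling a training set only moves working labels", {
  ds <- generate_dataset(small_gen_config(seed = 23))
  g <- train_som(ds, width = 4, height = 4, epochs = 5, seed = 3)
  rl <- relabel_training_set(g, ds, 4)
  out <- rl$dataset
  expect_identical(out$meta$given_label, ds$meta$given_label)
  expect_identical(out$samples, ds$samples)
  expect_identical(out$registers, ds$registers)
  # summary transition counts are consistent
  tr <- rl$summary$transitions
  expect_equal(sum(tr), n_saccades(ds))
  expect_equal(rl$summary$n_changed, sum(tr) - sum(diag(tr)))
  expect_equal(unname(rowSums(tr)),
               as.vector(table(factor(ds$meta$given_label, levels = diagnosis_levels))))
})

test_that("pure cells are stable at any threshold", {
  # construct a collection whose cells are all single-class by using
  # widely separated class shapes and no noise
  mk <- function(tau, lab, n, offset) {
    sh <- shape_params(tau, noise_sd = 0, baseline_sd = 0)
    s <- t(vapply(seq_len(n), function(i)
      generate_saccade_waveform(sh, 30, 1, seed = i) + offset,
      numeric(192)))
    meta <- data.frame(saccade_id = sprintf("%s%02d", lab, 1:n),
                       register_id = paste0("R", lab), angle = 30,
                       given_label = lab, working_label = lab)
    list(s = s, meta = meta)
  }
  a <- mk(2.5, "C", 8, 0)
  b <- mk(2.5, "P", 8, 200)   # far-offset cloud: its own cells
  c <- mk(2.5, "S", 8, -200)
  ds <- saccade_dataset(rbind(a$s, b$s, c$s),
                        rbind(a$meta, b$meta, c$meta))
  g <- train_som(ds, width = 3, height = 1, epochs = 20, seed = 2)
  for (th in c(2, 4.5)) {
    rl <- relabel_training_set(g, ds, th)
    expect_identical(rl$dataset$meta$working_label,
                     ds$meta$given_label)
    expect_equal(rl$summary$n_changed, 0)
  }
})

test_that("a fully mixed cell follows the cell decision", {
  # 1x1 grid: everything lands in one cell, so every saccade takes the
  # label the global counts dictate
  ds <- generate_dataset(small_gen_config(seed = 2))
  g <- train_som(ds, width = 1, height = 1, epochs = 2, seed = 1)
  cnt <- table(factor(ds$meta$given_label, levels = diagnosis_levels))
  rl <- relabel_training_set(g, ds, 2)
  want <- relabel_saccade(as.numeric(cnt), 2)
  expect_true(all(rl$dataset$meta$working_label == want))
})

test_that("relabeled-P totals are monotone in theta on a fixed dataset", {
  ds <- generate_dataset(small_gen_config(seed = 29))
  g <- train_som(ds, width = 4, height = 4, epochs = 8, seed = 5)
  cc <- compute_cell_counts(g, ds)
  p_counts <- vapply(c(2, 3, 4, 4.5), function(th) {
    rl <- relabel_training_set(g, ds, th, counts = cc)
    sum(rl$dataset$meta$working_label == "P")
  }, numeric(1))
  expect_true(all(diff(p_counts) >= 0))
  s_counts <- vapply(c(2, 3, 4, 4.5), function(th) {
    rl <- relabel_training_set(g, ds, th, counts = cc)
    sum(rl$dataset$meta$working_label == "S" &
          ds$meta$given_label != "S")
  }, numeric(1))
  expect_equal(length(unique(s_counts)), 1L)
})
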