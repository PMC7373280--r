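test_that("sequence-length bookkeeping matches the conv/pool arithmetic", {
  cfg <- model_config()  # reference architecture
  expect_equal(unname(cfg$seq_lengths),
               c(192L, 190L, 95L, 93L, 46L))
  small <- small_model_config()
  expect_equal(small$seq_lengths[["pool2"]], 46L)
  expect_error(model_config(input_length = 6), "too short")
})

test_that("forward passes are softmax-normalized for any input", {
  m <- build_model(small_model_config(), seed = 3)
  set.seed(1)
  X <- rbind(matrix(rnorm(5 * 192), 5, 192),
             matrix(0, 2, 192),
             matrix(1e3, 1, 192))
  p <- predict_saccade_probs(m, X)
  expect_equal(dim(p), c(8L, 3L))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 8), tolerance = 1e-6)
  expect_error(predict_saccade_probs(m, matrix(0, 2, 100)), "expects")
})

test_that("model building is deterministic in the seed", {
  m1 <- build_model(small_model_config(), seed = 11)
  m2 <- build_model(small_model_config(), seed = 11)
  m3 <- build_model(small_model_config(), seed = 12)
  probe <- matrix(sin(1:192 / 7), 1, 192)
  expect_identical(m1$params, m2$params)
  expect_equal(predict_saccade_probs(m1, probe),
               predict_saccade_probs(m2, probe))
  expect_false(identical(m1$params, m3$params))
})

test_that("analytic gradients match numerical gradients", {
  # spot-check the full backward pass on a tiny network
  cfg <- model_config(input_length = 24L, conv_filters = c(3L, 4L),
                      lstm_units = 5L, dropout = 0)
  m <- build_model(cfg, seed = 2)
  set.seed(8)
  X <- matrix(rnorm(4 * 24), 4, 24)
  y <- c(1L, 2L, 3L, 2L)
  fwd <- eogtandem:::nn_forward(m$params, X, cfg, train = FALSE)
  gr <- eogtandem:::nn_backward(m$params, fwd, y)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(m$params)) {
    for (r in 1:4) {
      idx <- sample(length(m$params[[nm]]), 1)
      p2 <- m$params
      p2[[nm]][idx] <- p2[[nm]][idx] + eps
      lp <- eogtandem:::nn_loss(
        eogtandem:::nn_forward(p2, X, cfg)$probs, y)
      p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
      lm <- eogtandem:::nn_loss(
        eogtandem:::nn_forward(p2, X, cfg)$probs, y)
      num <- (lp - lm) / (2 * eps)
      expect_equal(gr[[nm]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("compromise score is the C/P recall minimum", {
  expect_equal(compromise_score(c(C = 1, P = 0, S = 1)), 0)
  expect_equal(compromise_score(c(C = 0.8, P = 0.5, S = 0.9)), 0.5)
  expect_equal(compromise_score(c(P = 0.5, C = 0.9)), 0.5)
  expect_error(compromise_score(c(C = 0.5, S = 1)), "C and P")
  expect_error(compromise_score(c(C = 2, P = 0)), "0, 1")
})

test_that("training learns a separable task and selection behaves", {
  # three shape classes, no noise beyond mild jitter: separable
  ds <- generate_dataset(
    generator_config(registers_per_class = c(5, 5, 5),
                     saccades_per_register = c(10, 12),
                     contamination = 0,  # P registers purely P-shaped
                     seed = 61))
  sp <- split_registers(ds, seed = 2)
  parts <- apply_split(ds, sp)
  m <- build_model(small_model_config(), seed = 4)
  tr <- train_with_selection(m, parts$train, parts$val,
                             training_config(max_epochs = 10,
                                             batch_size = 32, seed = 5))
  expect_equal(nrow(tr$history), 10L)
  # the selected epoch attains the best score seen
  expect_equal(tr$selected_score, max(tr$history$score))
  expect_equal(tr$history$score[tr$selected_epoch], tr$selected_score)
  # loss decreases over training (sanity)
  expect_lt(tail(tr$history$train_loss, 1), tr$history$train_loss[1])
  # separable classes end up well classified at the register level
  pred <- predict_saccade_labels(tr, parts$test$samples)
  reg <- vote_registers(parts$test, pred)
  expect_gte(mean(reg$predicted == reg$diagnosis), 2 / 3)
})

test_that("max_epochs = 1 trivially selects epoch 1 and reruns reproduce", {
  ds <- generate_dataset(small_gen_config(seed = 71))
  sp <- split_registers(ds, seed = 1)
  parts <- apply_split(ds, sp)
  tc <- training_config(max_epochs = 1, batch_size = 16, seed = 13)
  m <- build_model(small_model_config(), seed = 6)
  t1 <- train_with_selection(m, parts$train, parts$val, tc)
  t2 <- train_with_selection(m, parts$train, parts$val, tc)
  expect_equal(t1$selected_epoch, 1L)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
})

test_that("validation without all three classes errors", {
  ds <- generate_dataset(small_gen_config(seed = 81))
  sp <- split_registers(ds, seed = 1)
  parts <- apply_split(ds, sp)
  crippled <- subset_registers(
    parts$val,
    parts$val$registers$register_id[parts$val$registers$diagnosis != "P"])
  m <- build_model(small_model_config(), seed = 1)
  expect_error(train_with_selection(m, parts$train, crippled,
                                    training_config(max_epochs = 1)),
               "cover all classes")
})

test_that("prediction ties break toward the severer class", {
  m <- build_model(small_model_config(), seed = 5)
  # force an exact three-way tie by zeroing the output layer
  m$params$Wd[] <- 0
  m$params$bd[] <- 0
  lab <- predict_saccade_labels(m, matrix(rnorm(3 * 192), 3, 192))
  expect_equal(lab, c("S", "S", "S"))
  expect_equal(predict_saccade_labels(m, matrix(0, 0, 192)),
               character(0))
})

test_that("models survive the plain-text round-trip", {
  ds <- generate_dataset(small_gen_config(seed = 91))
  sp <- split_registers(ds, seed = 3)
  parts <- apply_split(ds, sp)
  m <- build_model(small_model_config(), seed = 2)
  tr <- train_with_selection(m, parts$train, parts$val,
                             training_config(max_epochs = 2,
                                             batch_size = 32, seed = 3))
  dir <- withr::local_tempdir()
  save_model(tr, dir)
  back <- load_model(dir)
  X <- parts$test$samples[1:5, , drop = FALSE]
  expect_equal(predict_saccade_probs(back, X),
               predict_saccade_probs(tr, X), tolerance = 1e-12)
  expect_equal(back$selected_epoch, tr$selected_epoch)
})
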