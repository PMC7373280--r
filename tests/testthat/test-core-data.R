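test_that("dataset construction validates its invariants", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "saccade_dataset")
  expect_equal(n_saccades(ds), 3L)
  expect_equal(n_registers(ds), 2L)

  # wrong window length
  expect_error(saccade_dataset(matrix(0, 1, 191), ds$meta[1, ]),
               "192 samples")
  # given_label must match the register diagnosis
  bad <- ds$meta
  bad$given_label[1] <- "S"
  expect_error(saccade_dataset(ds$samples, bad, ds$registers),
               "disagrees with register diagnosis")
  # unknown label token
  bad <- ds$meta
  bad$working_label[2] <- "X"
  expect_error(saccade_dataset(ds$samples, bad), "unknown diagnosis")
  # orphan register reference
  bad <- ds$meta
  bad$register_id[3] <- "R9"
  expect_error(saccade_dataset(ds$samples, bad, ds$registers),
               "unknown register")
  # register with no saccades
  regs <- rbind(ds$registers,
                data.frame(register_id = "R3", diagnosis = "S"))
  expect_error(saccade_dataset(ds$samples, ds$meta, regs), "no saccades")
  # bad angle
  bad <- ds$meta
  bad$angle[1] <- 45
  expect_error(saccade_dataset(ds$samples, bad), "angle")
})

test_that("CSV round-trip preserves the dataset", {
  ds <- generate_dataset(small_gen_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_saccade_table(ds, path)
  back <- read_saccade_table(path)
  expect_equal(back$meta$saccade_id, ds$meta$saccade_id)
  expect_equal(back$meta$given_label, ds$meta$given_label)
  expect_equal(back$meta$working_label, ds$meta$working_label)
  expect_equal(back$meta$true_shape_label, ds$meta$true_shape_label)
  expect_equal(back$meta$angle, ds$meta$angle)
  expect_equal(unname(back$samples), unname(ds$samples),
               tolerance = 1e-9)
})

test_that("a relabeled working_label column survives the round-trip", {
  ds <- tiny_dataset()
  ds$meta$working_label <- c("P", "C", "P")
  path <- withr::local_tempfile(fileext = ".csv")
  write_saccade_table(ds, path)
  back <- read_saccade_table(path)
  expect_equal(back$meta$working_label, c("P", "C", "P"))
  expect_equal(back$meta$given_label, c("C", "C", "P"))
})

test_that("matrix + metadata layout loads and bad layouts error", {
  ds <- tiny_dataset()
  mpath <- withr::local_tempfile(fileext = ".csv")
  dpath <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(as.data.frame(ds$samples), mpath, col.names = FALSE)
  data.table::fwrite(data.frame(register_id = ds$meta$register_id,
                                angle = ds$meta$angle,
                                label = ds$meta$given_label), dpath)
  back <- read_saccade_table(mpath, format = "matrix", metadata = dpath)
  expect_equal(n_saccades(back), 3L)
  expect_equal(back$meta$given_label, ds$meta$given_label)
  expect_equal(unname(back$samples), unname(ds$samples), tolerance = 1e-9)

  # 191 sample columns -> format error
  data.table::fwrite(as.data.frame(ds$samples[, 1:191]), mpath,
                     col.names = FALSE)
  expect_error(read_saccade_table(mpath, format = "matrix",
                                  metadata = dpath), "192 columns")
  # row-count mismatch
  data.table::fwrite(as.data.frame(ds$samples[1:2, ]), mpath,
                     col.names = FALSE)
  expect_error(read_saccade_table(mpath, format = "matrix",
                                  metadata = dpath), "do not match")
})

test_that("split counts follow the half-up rounding rule per class", {
  # the printed cohort split is asserted in test-acceptance; here the rule
  ds <- generate_dataset(small_gen_config(seed = 1,
                                          registers = c(5, 5, 5)))
  sp <- split_registers(ds, c(0.4, 0.4, 0.2), seed = 9)
  for (ids in list(sp$train_register_ids, sp$val_register_ids)) {
    expect_equal(as.vector(table(substr(ids, 1, 1))[c("C", "P", "S")]),
                 c(2L, 2L, 2L))
  }
  expect_equal(length(sp$test_register_ids), 3L)
})

test_that("splits are deterministic in the seed and counts seed-invariant", {
  ds <- generate_dataset(small_gen_config(seed = 3))
  s1 <- split_registers(ds, seed = 5)
  s2 <- split_registers(ds, seed = 5)
  s3 <- split_registers(ds, seed = 6)
  expect_identical(s1$train_register_ids, s2$train_register_ids)
  expect_identical(s1$test_register_ids, s2$test_register_ids)
  expect_equal(length(s3$train_register_ids),
               length(s1$train_register_ids))
  expect_equal(length(s3$test_register_ids),
               length(s1$test_register_ids))
  # disjoint and jointly covering
  all_ids <- c(s1$train_register_ids, s1$val_register_ids,
               s1$test_register_ids)
  expect_equal(sort(all_ids), sort(ds$registers$register_id))
})

test_that("degenerate splits error with advice", {
  ds <- generate_dataset(small_gen_config(seed = 2,
                                          registers = c(5, 4, 5)))
  # class P: round(1.6) + round(1.6) = 4 -> 0 test registers
  expect_error(split_registers(ds, c(0.4, 0.4, 0.2), seed = 1),
               "adjust the fractions")
  expect_error(split_registers(tiny_dataset(), c(0.4, 0.4, 0.2), 1),
               "class S has no registers")
  expect_error(split_registers(ds, c(0.5, 0.4, 0.2), 1), "sum to 1")
})
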