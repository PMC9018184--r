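test_that("a zero-epoch schedule returns the initial networks and an empty log", {
  s <- tiny_train_setup()
  tr <- train_staged(s$data, s$gen, s$disc,
                     train_config(stage_epochs = c(0, 0, 0), seed = 1))
  expect_identical(tr$generator$layers, s$gen$layers)
  expect_identical(tr$discriminator$layers, s$disc$layers)
  expect_equal(nrow(tr$log), 0)
  expect_equal(tr$status, "ok")
})

test_that("training is bit-reproducible under a fixed seed", {
  s <- tiny_train_setup()
  cfg <- train_config(stage_epochs = c(1, 1, 1), batch_size = 4, seed = 7)
  tr1 <- train_staged(s$data, s$gen, s$disc, cfg)
  tr2 <- train_staged(s$data, s$gen, s$disc, cfg)
  expect_identical(tr1$log, tr2$log)
  expect_identical(tr1$generator$layers, tr2$generator$layers)
  expect_identical(tr1$discriminator$layers, tr2$discriminator$layers)
})

test_that("the generator is frozen bit-identically through Stage II", {
  s <- tiny_train_setup()
  tr <- train_staged(s$data, s$gen, s$disc,
                     train_config(stage_epochs = c(1, 2, 0), seed = 3))
  expect_identical(tr$snapshots$stage1$layers, tr$snapshots$stage2$layers)
  # but the discriminators did train
  expect_false(identical(tr$discriminator$layers, s$disc$layers))
})

test_that("Stage-I optimization lowers the median validation L1 per epoch", {
  data <- generate_dataset(16, 19, image_size = 32, local_size = 16,
                           split = c(train = 0.625, val = 0.25, test = 0.125),
                           keep_cases = TRUE)
  gen <- build_generator(generator_spec(base_filters = 4), seed = 1)
  disc <- build_dual_discriminator(
    discriminator_spec(base_filters = 4, image_size = 32, local_size = 16),
    seed = 2)
  tr <- train_staged(data, gen, disc,
                     train_config(stage_epochs = c(6, 0, 0), batch_size = 4,
                                  seed = 5))
  v <- tr$val_l1$l1
  expect_gte(length(v), 6)
  expect_lt(median(tail(v, 2)), median(head(v, 2)))
})

test_that("the training log records each loss over its participating stages", {
  s <- tiny_train_setup()
  tr <- train_staged(s$data, s$gen, s$disc,
                     train_config(stage_epochs = c(1, 1, 1), seed = 9))
  lg <- tr$log
  expect_true(all(!is.na(lg$l_l1)))
  expect_true(all(!is.na(lg$l_mse)))
  expect_true(all(is.na(lg$l_per[lg$stage == 1])))
  expect_true(all(!is.na(lg$l_per[lg$stage >= 2])))
  expect_true(all(is.na(lg$l_adv[lg$stage < 3])))
  expect_true(all(!is.na(lg$l_adv[lg$stage == 3])))
  expect_true(all(!is.na(lg$l_disc[lg$stage >= 2])))
})

test_that("training writes a CSV log when asked", {
  s <- tiny_train_setup()
  dir <- withr::local_tempdir()
  tr <- train_staged(s$data, s$gen, s$disc,
                     train_config(stage_epochs = c(1, 0, 0), seed = 2),
                     log_dir = dir)
  lg <- read.csv(file.path(dir, "training_log.csv"))
  expect_equal(nrow(lg), nrow(tr$log))
  expect_named(lg, c("iteration", "stage", "l_l1", "l_mse", "l_per",
                     "l_adv", "l_disc"))
})

test_that("the frozen-validation Stage-II mode leaves the discriminators untouched", {
  s <- tiny_train_setup()
  tr <- train_staged(s$data, s$gen, s$disc,
                     train_config(stage_epochs = c(0, 2, 0), seed = 4,
                                  stage2_mode = "frozen-validation"))
  expect_identical(tr$discriminator$layers, s$disc$layers)
  expect_true(all(!is.na(tr$log$l_mse)))
})

test_that("fused adversarial mode also trains end to end", {
  s <- tiny_train_setup()
  tr <- train_staged(s$data, s$gen, s$disc,
                     train_config(stage_epochs = c(1, 1, 1), seed = 6,
                                  adv_mode = "fused"))
  expect_equal(tr$status, "ok")
  expect_true(all(is.finite(tr$log$l_adv[tr$log$stage == 3])))
})
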