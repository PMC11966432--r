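# Training recipe: learning-rate schedule, dataset splitting, step
# bookkeeping, determinism, deep-supervision gradient flow and the ablation
# harness.  Training runs use the tiny configuration on 32x32x16 phantoms.

test_that("the learning-rate schedule decays exponentially from 2e-4", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 2e-4)
  expect_equal(lr_at_epoch(cfg, 1), 2e-4 * 0.999)
  expect_equal(lr_at_epoch(cfg, 100), 2e-4 * 0.999^100)
  expect_equal(lr_at_epoch(cfg, 600), 2e-4 * 0.999^600)
  expect_equal(lr_at_epoch(train_config(lr_decay = 1), 500), 2e-4)
  expect_error(lr_at_epoch(cfg, -1), ">= 0")
})

test_that("dataset splitting allocates 6:2:2 with remainders to training", {
  sp <- split_dataset(sprintf("case%03d", 1:245), c(6, 2, 2), seed = 1)
  expect_length(sp$train, 147)
  expect_length(sp$validation, 49)
  expect_length(sp$test, 49)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), sprintf("case%03d", 1:245))

  sp10 <- split_dataset(1:10, c(6, 2, 2), seed = 3)
  expect_equal(lengths(sp10), c(train = 6L, validation = 2L, test = 2L))
  # remainders: 11 cases -> floor(2.2) = 2 each, train gets 7
  sp11 <- split_dataset(1:11, c(6, 2, 2), seed = 3)
  expect_equal(lengths(sp11), c(train = 7L, validation = 2L, test = 2L))

  expect_identical(split_dataset(1:20, seed = 9), split_dataset(1:20, seed = 9))
  expect_false(identical(split_dataset(1:20, seed = 9), split_dataset(1:20, seed = 10)))
  expect_error(split_dataset(1:2), "fewer cases")
  expect_error(split_dataset(character()), "empty")
})

test_that("one epoch takes exactly one optimizer step per case at batch 1", {
  cases <- tiny_cases(3, seed = 60)
  fit <- train(cases, tiny_network_config(),
               train_config(epochs = 1L, seed = 5), deep_supervision_spec())
  expect_equal(fit$steps, 3L)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("training is deterministic under a fixed seed", {
  cases <- tiny_cases(1, seed = 61)
  f1 <- train(cases, tiny_network_config(), train_config(epochs = 1L, seed = 7),
              deep_supervision_spec())
  f2 <- train(cases, tiny_network_config(), train_config(epochs = 1L, seed = 7),
              deep_supervision_spec())
  expect_identical(f1$history$loss[1], f2$history$loss[1])
  expect_identical(f1$net$params, f2$net$params)
})

test_that("eta = 0 leaves the main loss unchanged and only alters gradients", {
  cases <- tiny_cases(1, seed = 62)
  spec_on <- deep_supervision_spec()
  spec_off <- deep_supervision_spec(eta0 = c(0, 0, 0))
  f_on <- train(cases, tiny_network_config(), train_config(epochs = 1L, seed = 8), spec_on)
  f_off <- train(cases, tiny_network_config(), train_config(epochs = 1L, seed = 8), spec_off)
  expect_identical(f_on$history$main_loss[1], f_off$history$main_loss[1])
})

test_that("every deep-supervision head receives gradient at step 1", {
  cases <- tiny_cases(1, seed = 63)
  ca <- vnetseg:::case_arrays(cases[[1]])
  cfg <- tiny_network_config()
  net <- build_network(cfg, seed = 9)
  tape <- vnetseg:::new_tape()
  P <- vnetseg:::leaf_params(tape, net$params)
  ls <- vnetseg:::graph_case_loss(tape, P, ca$image, ca$label, cfg,
                                  deep_supervision_spec(),
                                  eta_at_epoch(deep_supervision_spec(), 0))
  vnetseg:::tape_backward(tape, ls$total)
  head_w <- grep("^head[0-9]+\\.(up[0-9]+|proj)\\.w$", names(P), value = TRUE)
  expect_gt(length(head_w), 0)
  for (nm in head_w) expect_gt(max(abs(P[[nm]]$g)), 0)
  # and the first encoder convolution still learns
  expect_gt(max(abs(P[["enc1.conv1.w"]]$g)), 0)
})

test_that("non-finite losses abort with a diagnostic and empty datasets are rejected", {
  expect_error(train(list(), tiny_network_config()), "empty dataset")
  cases <- tiny_cases(1, seed = 64)
  bad <- cases
  bad[[1]]$image$data[1] <- Inf           # poisons the forward pass
  expect_error(suppressWarnings(
    train(bad, tiny_network_config(), train_config(epochs = 1L, seed = 1),
          deep_supervision_spec())),
    "non-finite")
})

test_that("validation tracking retains the best checkpoint", {
  cases <- tiny_cases(2, seed = 65)
  dir_ <- tempfile()
  fit <- train(cases[1], tiny_network_config(),
               train_config(lr0 = 1e-3, epochs = 6L, seed = 10),
               deep_supervision_spec(),
               val_dataset = cases[2], out_dir = dir_)
  expect_true(file.exists(file.path(dir_, "checkpoints", "best")))
  expect_true(file.exists(file.path(dir_, "checkpoints", "last")))
  expect_true(file.exists(file.path(dir_, "metrics.csv")))
  expect_equal(nrow(fit$val_history), 6)
  expect_false(is.na(fit$best_epoch))
  best <- load_checkpoint(file.path(dir_, "checkpoints", "best"))
  expect_s3_class(best, "vnet")
})

test_that("the ablation harness accepts the structure tuples and is reproducible", {
  cases <- tiny_cases(2, seed = 66)
  grid <- list(list(structure = c(1, 2, 3, 3, 2, 2, 2, 2, 2), kernel_size = 3))
  tc <- train_config(epochs = 1L, seed = 11)
  tab <- ablation_harness(grid, cases[1], cases[2],
                          tconfig = tc)
  expect_equal(nrow(tab), 1)
  expect_true(all(c("dsc_mean", "iou_mean", "sensitivity_mean", "precision_mean",
                    "hd_mm_mean") %in% names(tab)))
  # the published structure tuples are all accepted
  tuples <- list(c(1, 2, 3, 3, 3, 3, 3, 2, 1), c(1, 2, 2, 2, 2, 2, 2, 2, 1),
                 c(1, 2, 3, 3, 2, 2, 2, 2, 2))
  for (tp in tuples) expect_s3_class(network_config(convs_per_stage = tp), "network_config")
  tab2 <- ablation_harness(grid, cases[1], cases[2], tconfig = tc)
  expect_equal(tab, tab2)
  expect_error(ablation_harness(list(), cases[1], cases[2]), "empty")
})
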