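test_that("train_config mirrors the study defaults and validates", {
  j <- train_config("jigsaw")
  expect_identical(j$batch_size, 128L)
  expect_identical(j$epochs, 100L)
  expect_equal(j$learning_rate, 0.001)
  expect_equal(j$weight_decay, 0)
  f <- train_config("finetune")
  expect_identical(f$batch_size, 64L)
  expect_error(train_config("jigsaw", learning_rate = 0), "positive")
  expect_error(train_config("jigsaw", epochs = -1L), "positive")
})

test_that("zero-epoch training returns the parameters unchanged", {
  ps <- small_permset()
  imgs <- small_dataset()$images[1:4]
  cfn <- build_cfn(test_encoder(), seed = 20L)
  out <- train_jigsaw(cfn, imgs, ps,
                      train_config("jigsaw", epochs = 0L, batch_size = 4L),
                      test_grid())
  expect_identical(out$model$params, cfn$params)
  expect_identical(nrow(out$history), 0L)
  clf <- build_classifier(test_encoder(), seed = 21L)
  out2 <- train_classifier(clf, imgs, c(0, 1, 0, 1),
                           train_config("finetune", epochs = 0L))
  expect_identical(out2$model$params, clf$params)
})

test_that("training is deterministic under a fixed seed", {
  ps <- small_permset()
  imgs <- small_dataset()$images[1:6]
  cfg <- train_config("jigsaw", epochs = 2L, batch_size = 3L, seed = 22L)
  a <- train_jigsaw(build_cfn(test_encoder(), seed = 23L), imgs, ps, cfg,
                    test_grid())
  b <- train_jigsaw(build_cfn(test_encoder(), seed = 23L), imgs, ps, cfg,
                    test_grid())
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$history, b$history)
})

test_that("training validates inputs", {
  ps <- small_permset()
  imgs <- small_dataset()$images[1:4]
  cfn <- build_cfn(test_encoder(), seed = 24L)
  expect_error(train_jigsaw(cfn, list(), ps,
                            train_config("jigsaw", epochs = 1L), test_grid()),
               "no training images")
  expect_error(train_jigsaw(cfn, imgs, ps, train_config("finetune"),
                            test_grid()),
               "jigsaw")
  ps2 <- generate_permutation_set(n_extra = 1L, pool_size = 20L, seed = 1L)
  expect_error(train_jigsaw(cfn, imgs, ps2,
                            train_config("jigsaw", epochs = 1L), test_grid()),
               "does not match")
  clf <- build_classifier(test_encoder(), seed = 25L)
  expect_error(train_classifier(clf, imgs, c(1, 1, 1, 1),
                                train_config("finetune", epochs = 1L)),
               "both classes")
  expect_error(train_classifier(clf, imgs, c(0, 1),
                                train_config("finetune", epochs = 1L)),
               "differ in length")
})

test_that("a linearly separable fixture reaches training AUC 1 quickly", {
  withr::local_seed(26)
  bright <- replicate(6, matrix(stats::runif(96 * 96, 0.6, 1.0), 96, 96),
                      simplify = FALSE)
  dark <- replicate(6, matrix(stats::runif(96 * 96, 0.0, 0.4), 96, 96),
                    simplify = FALSE)
  clf <- build_classifier(test_encoder(), seed = 27L)
  out <- train_classifier(clf, c(bright, dark), rep(c(1, 0), each = 6),
                          train_config("finetune", epochs = 10L,
                                       batch_size = 4L, seed = 28L))
  expect_equal(out$history$auc[10L], 1)
  expect_identical(nrow(out$history), 10L)
})

test_that("loss is finite and decreases on a 10-sample overfit fixture", {
  ds <- small_dataset()
  lesion <- which(ds$manifest$finding != "normal")
  idx <- c(lesion[ds$manifest$cancer[lesion] == 1][1:5],
           lesion[ds$manifest$cancer[lesion] == 0][1:5])
  imgs <- ds$images[idx]
  labels <- ds$manifest$cancer[idx]
  clf <- build_classifier(test_encoder(), seed = 29L)
  out <- train_classifier(clf, imgs, labels,
                          train_config("finetune", epochs = 15L,
                                       batch_size = 5L, seed = 30L))
  expect_true(all(is.finite(out$history$loss)))
  expect_lt(out$history$loss[15L], out$history$loss[1L])
})

test_that("evaluate_jigsaw_accuracy is seeded and near chance for a fixed-output model", {
  ps <- small_permset()
  imgs <- small_dataset()$images[1:5]
  cfn <- build_cfn(test_encoder(), seed = 31L)
  # force a constant argmax: the label is right only when it is drawn
  cfn$params$head.W[] <- 0
  cfn$params$head.b <- c(10, rep(0, 30))
  acc <- evaluate_jigsaw_accuracy(cfn, imgs, ps, n_samples = 310L,
                                  seed = 32L, grid = test_grid())
  expect_identical(acc,
                   evaluate_jigsaw_accuracy(cfn, imgs, ps, n_samples = 310L,
                                            seed = 32L, grid = test_grid()))
  expect_lt(abs(acc - 1 / 31), 0.035)
  expect_error(evaluate_jigsaw_accuracy(cfn, imgs, ps, n_samples = 0L),
               "n_samples")
})

test_that("pipeline arms encode the four-arm contract", {
  expect_error(pipeline_arm("IN"), "weights_file")
  expect_error(pipeline_arm("IN-Jig"), "weights_file")
  a <- pipeline_arm("Scratch")
  expect_identical(a$encoder_init, "random")
  expect_false(a$jigsaw_pretraining)
  b <- pipeline_arm("Scratch-Jig")
  expect_true(b$jigsaw_pretraining)
  ck <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), ck)
  d <- pipeline_arm("IN", weights_file = ck)
  expect_identical(d$encoder_init, paste0("file:", ck))
})

test_that("run_arm scores every image exactly once per trial", {
  ds <- small_dataset()
  ps <- small_permset()
  splits <- grouped_kfold(ds$manifest$patient_id, k = 5L, trials = 1L,
                          seed = 40L)
  cfgJ <- train_config("jigsaw", epochs = 0L, batch_size = 16L, seed = 41L)
  cfgF <- train_config("finetune", epochs = 1L, batch_size = 16L, seed = 42L)
  tab <- run_arm(pipeline_arm("Scratch"), ds, ps, cfgJ, cfgF, splits,
                 test_grid(), test_encoder())
  expect_identical(sort(tab$image_id), sort(ds$manifest$image_id))
  expect_identical(anyDuplicated(tab$image_id), 0L)
  expect_true(all(tab$trial == 1L))
  m <- merge(tab, ds$manifest, by = "image_id")
  expect_identical(m$label, m$cancer)
})

test_that("Scratch-Jig with zero pretext epochs degenerates to Scratch", {
  ds <- small_dataset()
  ps <- small_permset()
  splits <- grouped_kfold(ds$manifest$patient_id, k = 5L, trials = 1L,
                          seed = 46L)
  cfgJ <- train_config("jigsaw", epochs = 0L, batch_size = 16L, seed = 47L)
  cfgF <- train_config("finetune", epochs = 2L, batch_size = 16L, seed = 48L)
  sj <- run_arm(pipeline_arm("Scratch-Jig"), ds, ps, cfgJ, cfgF, splits,
                test_grid(), test_encoder(), trials = 1L, folds = 1L)
  sc <- run_arm(pipeline_arm("Scratch"), ds, ps, cfgJ, cfgF, splits,
                test_grid(), test_encoder(), trials = 1L, folds = 1L)
  expect_identical(sj, sc)
})

test_that("a patient split across folds aborts the run", {
  ds <- small_dataset()
  ps <- small_permset()
  splits <- grouped_kfold(ds$manifest$patient_id, k = 5L, trials = 1L,
                          seed = 43L)
  bad <- splits
  extra <- bad$assignment[1L, ]
  extra$fold <- (extra$fold %% 5L) + 1L
  bad$assignment <- rbind(bad$assignment, extra)
  cfgJ <- train_config("jigsaw", epochs = 0L, seed = 1L)
  cfgF <- train_config("finetune", epochs = 1L, seed = 2L)
  expect_error(run_arm(pipeline_arm("Scratch"), ds, ps, cfgJ, cfgF, bad,
                       test_grid(), test_encoder(),
                       folds = extra$fold),
               "protocol error")
})

test_that("pretrain_rotation writes a checkpoint usable by the IN arms", {
  imgs <- small_dataset()$images[1:8]
  path <- withr::local_tempfile(fileext = ".rds")
  pretrain_rotation(imgs, test_encoder(), path, epochs = 1L,
                    batch_size = 4L, seed = 44L)
  ck <- load_checkpoint(path)
  expect_true(all(c("enc1.W", "enc4.b") %in% names(ck$params)))
  clf <- build_classifier(encoder_spec(init = paste0("file:", path)),
                          seed = 45L)
  expect_identical(clf$params$enc1.W, ck$params$enc1.W)
})
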