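test_that("reference population tables carry the study totals", {
  ref <- cmmd_reference_counts()
  expect_identical(sum(ref$findings$cancer), 1515L)
  expect_identical(sum(ref$findings$not_cancer), 1309L)
  expect_identical(sum(ref$density$cancer), 1515L)
  expect_identical(sum(ref$density$not_cancer), 1309L)
  expect_identical(sum(ref$findings$cancer) + sum(ref$findings$not_cancer),
                   2824L)
  expect_identical(ref$findings$cancer[ref$findings$finding == "normal"], 0L)
})

test_that("synthetic_config validates proportions and ranges", {
  expect_error(synthetic_config(finding_mix = c(mass = 0.5,
                                                calcification = 0.2,
                                                distortion = 0.2,
                                                normal = 0.2)),
               "sum to 1")
  expect_error(synthetic_config(density_mix = 1.5), "proportion")
  expect_error(synthetic_config(
    cancer_rate_per_finding = c(mass = 0.5, calcification = 0.5,
                                distortion = 0.5, normal = 0.1)),
    "normal")
  expect_error(synthetic_config(lesion_area_range = list(
    mass = c(0.3, 0.2), calcification = c(0.16, 0.34),
    distortion = c(0.45, 0.7))), "increasing pair")
  expect_error(synthetic_config(exclusion_rates = c(phyllodes = 0.5,
                                                    neurofibromatosis = 0.5,
                                                    lymphedema = 0,
                                                    venous_port = 0,
                                                    foreign_body = 0,
                                                    artifact = 0,
                                                    lesion_unidentifiable = 0)),
               "sum to < 1")
})

test_that("generate_record is deterministic and honors record semantics", {
  cfg <- synthetic_config(n_patients = 10L, image_size = 96L, seed = 51L)
  skel <- synthetic_manifest_skeleton(cfg)
  i_norm <- which(skel$finding == "normal")[1L]
  i_les <- which(skel$finding != "normal")[1L]
  a <- generate_record(cfg, i_les)
  b <- generate_record(cfg, i_les)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  g <- generate_record(cfg, i_norm)
  expect_null(g$mask)
  expect_identical(g$record$cancer, 0L)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_error(generate_record(cfg, nrow(skel) + 1L), "exceeds")
})

test_that("mask area fractions stay inside the configured ranges", {
  ds <- small_dataset()
  cfg <- synthetic_config(n_patients = 60L, image_size = 96L, seed = 11L)
  S2 <- 96^2
  for (i in seq_len(nrow(ds$manifest))) {
    f <- ds$manifest$finding[i]
    if (f == "normal") {
      expect_null(ds$masks[[i]])
      next
    }
    rng <- cfg$lesion_area_range[[f]]
    frac <- sum(ds$masks[[i]]) / S2
    # small slack for pixel discretization of the continuous area draw
    expect_gte(frac, rng[1] * 0.93)
    expect_lte(frac, rng[2] * 1.07)
  }
})

test_that("dense breasts show brighter, higher-variance texture", {
  a <- synthetic_fullfield(256L, 192L, seed = 52L, dense = FALSE)
  b <- synthetic_fullfield(256L, 192L, seed = 52L, dense = TRUE)
  inb <- a$breast_mask & !a$pectoral_mask
  expect_gt(mean(b$image[inb]), mean(a$image[inb]))
  expect_gt(stats::sd(b$image[inb]), stats::sd(a$image[inb]))
  expect_true(any(a$pectoral_mask))
  expect_true(all(which(a$pectoral_mask) %in% which(a$breast_mask)))
})

test_that("manifest skeleton groups images under patients with both views of the mixture", {
  cfg <- synthetic_config(n_patients = 120L, image_size = 96L, seed = 53L)
  skel <- synthetic_manifest_skeleton(cfg)
  expect_identical(anyDuplicated(skel$image_id), 0L)
  per_pat <- table(skel$patient_id)
  expect_true(all(per_pat %in% 1:2))
  expect_setequal(unique(skel$finding),
                  c("mass", "calcification", "distortion", "normal"))
  expect_true(all(skel$cancer[skel$finding == "normal"] == 0L))
  # density is a patient-level attribute
  per_pat_dens <- tapply(skel$density, skel$patient_id,
                         function(d) length(unique(d)))
  expect_true(all(per_pat_dens == 1))
  expect_true(all(skel$exclusion_flag == "none"))  # default rates are 0
})

test_that("build_dataset writes a readable, bit-reproducible dataset", {
  cfg <- synthetic_config(n_patients = 8L, image_size = 96L, seed = 54L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- build_dataset(cfg, d1)
  m2 <- build_dataset(cfg, d2)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  back <- read_manifest(file.path(d1, "manifest.csv"))
  expect_identical(back$image_id, m1$image_id)
  # image round-trip within 16-bit quantization
  g <- generate_record(cfg, 1L)
  img <- read_gray(file.path(d1, m1$image_path[1L]))
  expect_lt(max(abs(img - g$image)), 1 / 65535 + 1e-9)
  has_mask <- which(m1$mask_path != "")[1L]
  msk <- read_gray(file.path(d1, m1$mask_path[has_mask]))
  expect_true(all(msk %in% c(0, 1)))
})

test_that("exclusion flags are drawn at the configured rates", {
  cfg <- synthetic_config(n_patients = 400L, image_size = 96L, seed = 55L,
                          exclusion_rates = c(phyllodes = 0.3,
                                              neurofibromatosis = 0,
                                              lymphedema = 0,
                                              venous_port = 0,
                                              foreign_body = 0,
                                              artifact = 0.1,
                                              lesion_unidentifiable = 0))
  skel <- synthetic_manifest_skeleton(cfg)
  tab <- table(skel$exclusion_flag) / nrow(skel)
  expect_equal(unname(tab[["phyllodes"]]), 0.3, tolerance = 0.08)
  expect_equal(unname(tab[["artifact"]]), 0.1, tolerance = 0.06)
  expect_false("lymphedema" %in% names(tab))
})

test_that("a small classifier learns the cancer label from 500 crops", {
  cfg <- synthetic_config(n_patients = 450L, image_size = 96L, seed = 56L)
  ds <- generate_dataset(cfg)
  n <- nrow(ds$manifest)
  expect_gte(n, 600L)
  withr::local_seed(57)
  train_idx <- sample(n, 500L)
  held <- setdiff(seq_len(n), train_idx)
  clf <- build_classifier(test_encoder(), seed = 58L)
  out <- train_classifier(clf, ds$images[train_idx],
                          ds$manifest$cancer[train_idx],
                          train_config("finetune", epochs = 25L,
                                       batch_size = 16L, seed = 59L))
  scores <- predict_classifier(out$model, ds$images[held])
  auc <- roc_auc(scores, ds$manifest$cancer[held])$auc
  expect_gt(auc, 0.8)
})
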