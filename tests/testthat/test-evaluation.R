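test_that("roc_auc matches hand-computed and boundary cases", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0)
  # 4 pos-neg pairs: (.35 vs .1) win, (.35 vs .4) loss, (.8 vs .1) win,
  # (.8 vs .4) win -> 3/4
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  # ties count half: pos .5, neg .5 and .1 -> (1 + .5)/2
  expect_equal(roc_auc(c(0.5, 0.5, 0.1), c(1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc agrees with the pROC reference implementation", {
  withr::local_seed(101)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(stats::runif(n), 2)  # rounding induces ties
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    ours <- roc_auc(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("every ROC point (1-spec, sens) is consistent with its threshold", {
  withr::local_seed(5)
  scores <- round(stats::runif(40), 1)
  labels <- c(0, 1, stats::rbinom(38, 1, 0.4))
  pts <- roc_auc(scores, labels)$points
  for (i in seq_len(nrow(pts))) {
    t <- pts$threshold[i]
    expect_equal(pts$tpr[i], mean(scores[labels == 1] >= t))
    expect_equal(pts$fpr[i], mean(scores[labels == 0] >= t))
  }
})

test_that("youden_cutoff matches hand-scanned examples", {
  y <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(y$J, 1)
  expect_equal(y$cutoff, 0.8)
  # all scores identical: no informative threshold
  expect_equal(youden_cutoff(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))$J, 0)
  y <- youden_cutoff(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(y$cutoff, 0.35)
  expect_equal(y$J, 0.5)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 0.5)
  expect_error(youden_cutoff(1:3, c(0, 0, 0)), "both classes")
})

test_that("subgroup_report matches per-subgroup brute-force Mann-Whitney", {
  tab <- data.frame(
    score = c(0.9, 0.2, 0.8, 0.3, 0.7, 0.6, 0.1, 0.4),
    label = c(1, 0, 1, 0, 1, 0, 0, 0),
    finding = c("mass", "mass", "calcification", "calcification",
                "distortion", "distortion", "normal", "normal"),
    density = rep(c("DB", "Not-DB"), 4))
  brute <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  sg <- subgroup_report(tab, cutoff = 0.5)
  for (f in c("mass", "calcification", "distortion")) {
    sub <- tab[tab$finding == f, ]
    expect_equal(unname(sg$per_finding_auc[f]), brute(sub$score, sub$label))
  }
  expect_equal(sg$normal_tnr, 1)  # 0.1 and 0.4 both below 0.5
  for (d in c("DB", "Not-DB")) {
    sub <- tab[tab$density == d, ]
    expect_equal(unname(sg$per_density_auc[d]), brute(sub$score, sub$label))
  }
})

test_that("one-class subgroups are reported NA, not an abort", {
  tab <- data.frame(score = c(0.2, 0.3, 0.9, 0.8),
                    label = c(0, 0, 1, 1),
                    finding = c("mass", "mass", "calcification",
                                "calcification"),
                    density = "DB")
  sg <- subgroup_report(tab, 0.5)
  expect_true(is.na(sg$per_finding_auc[["mass"]]))          # no positives
  expect_true(is.na(sg$per_finding_auc[["calcification"]])) # no negatives
  expect_true(is.na(sg$normal_tnr))                         # no normals
  expect_equal(unname(sg$per_density_auc[["DB"]]), 1)
})

test_that("mean_roc_curve averages vertically as interpolation by hand", {
  r1 <- data.frame(threshold = c(Inf, 0.9, 0.1),
                   fpr = c(0, 0, 1), tpr = c(0, 0.5, 1))
  r2 <- data.frame(threshold = c(Inf, 0.5, 0.2),
                   fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  one <- mean_roc_curve(list(r1))
  # single trial: mean equals that curve at the grid points (ties -> max)
  expect_equal(one$mean_tpr[one$fpr == 0], 0.5)
  expect_equal(one$mean_tpr[one$fpr == 0.5], 0.75)
  expect_equal(one$mean_tpr[one$fpr == 1], 1)
  two <- mean_roc_curve(list(r1, r1))
  expect_equal(two$lo, two$hi)  # identical trials: zero-width envelope
  m <- mean_roc_curve(list(r1, r2))
  # hand interpolation at fpr = 0.5: r1 gives 0.75, r2 gives 1
  expect_equal(m$mean_tpr[m$fpr == 0.5], (0.75 + 1) / 2)
  expect_true(all(diff(m$mean_tpr) >= -1e-12))
  expect_error(mean_roc_curve(list()), "no ROC")
})

test_that("grouped_kfold deals patients evenly and reproducibly", {
  pats <- sprintf("P%02d", 1:10)
  sp <- grouped_kfold(pats, k = 5L, trials = 3L, seed = 2L)
  for (tr in 1:3) {
    asg <- sp$assignment[sp$assignment$trial == tr, ]
    expect_setequal(asg$patient_id, pats)       # conservation
    expect_identical(anyDuplicated(asg$patient_id), 0L)  # disjoint folds
    expect_true(all(table(asg$fold) == 2))      # 10 patients over 5 folds
  }
  sp2 <- grouped_kfold(pats, k = 5L, trials = 3L, seed = 2L)
  expect_identical(sp$assignment, sp2$assignment)
  expect_error(grouped_kfold(sprintf("P%d", 1:3), k = 5L), "fewer distinct")
})

test_that("repeated patient ids never span folds", {
  ids <- rep(sprintf("P%02d", 1:12), times = sample(1:3, 12, replace = TRUE))
  sp <- grouped_kfold(ids, k = 4L, trials = 2L, seed = 9L)
  manifest_fold <- merge(data.frame(patient_id = ids),
                         sp$assignment[sp$assignment$trial == 1, ])
  per_pat <- tapply(manifest_fold$fold, manifest_fold$patient_id,
                    function(f) length(unique(f)))
  expect_true(all(per_pat == 1))
})

test_that("compare_auc_ttest matches the closed-form paired t", {
  a <- c(0.91, 0.93, 0.90, 0.95, 0.92, 0.94, 0.91, 0.93, 0.92, 0.90)
  b <- c(0.89, 0.92, 0.91, 0.93, 0.90, 0.92, 0.90, 0.91, 0.93, 0.88)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  got <- compare_auc_ttest(a, b)
  expect_equal(got$t, t_hand)
  expect_equal(got$p, p_hand)
})

test_that("compare_auc_ttest handles degenerate and error cases", {
  x <- c(0.9, 0.91, 0.92)
  expect_equal(compare_auc_ttest(x, x), list(t = 0, p = 1))
  got <- compare_auc_ttest(x + 0.01, x)  # zero-variance nonzero mean
  expect_identical(got$t, Inf)
  expect_equal(got$p, 0)
  withr::local_seed(4)
  jit <- stats::rnorm(10, 0, 1e-4)
  got <- compare_auc_ttest(seq(0.9, 0.91, length.out = 10) + 0.01 + jit,
                           seq(0.9, 0.91, length.out = 10))
  expect_lt(got$p, 0.05)
  expect_error(compare_auc_ttest(1:3 / 10, 1:4 / 10), "equal length")
  expect_error(compare_auc_ttest(0.5, 0.6), "n >= 2")
})

test_that("eval_report aggregates trials with ordered CIs and valid rates", {
  withr::local_seed(33)
  n <- 60
  tabs <- lapply(1:4, function(tr) {
    lab <- stats::rbinom(n, 1, 0.5)
    lab[1:2] <- c(0, 1)
    data.frame(trial = tr,
               score = stats::plogis(2 * lab + stats::rnorm(n)),
               label = lab,
               finding = sample(c("mass", "calcification", "distortion",
                                  "normal"), n, TRUE,
                                prob = c(0.4, 0.2, 0.1, 0.3)),
               density = sample(c("DB", "Not-DB"), n, TRUE))
  })
  tabs <- do.call(rbind, tabs)
  tabs$label[tabs$finding == "normal"] <- 0
  rep <- eval_report(tabs)
  expect_identical(rep$n_trials, 4L)
  expect_true(rep$auc > 0 && rep$auc <= 1)
  expect_true(all(c(rep$sensitivity, rep$specificity, rep$normal_tnr) >= 0))
  expect_true(all(c(rep$sensitivity, rep$specificity, rep$normal_tnr) <= 1))
  expect_lte(rep$ci95$auc[["lo"]], rep$ci95$auc[["hi"]])
  expect_length(rep$trial_aucs, 4L)
  expect_output(print(rep), "evaluation over 4 trials")
  json <- withr::local_tempfile(fileext = ".json")
  roc_csv <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, json, roc_csv)
  back <- jsonlite::read_json(json)
  expect_equal(back$auc, rep$auc, tolerance = 1e-9)
  roc <- utils::read.csv(roc_csv)
  expect_identical(nrow(roc), 101L)
})
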