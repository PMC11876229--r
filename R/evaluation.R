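# Metric and statistics suite of the study protocol: ROC/AUC
# (Mann-Whitney form), the Youden operating point, subgroup metrics with
# the normal-true-negative rate, vertically averaged mean ROC curves,
# patient-grouped repeated k-fold splits, and the paired AUC t-test.

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic P(score+ > score-) + 1/2 P(tie),
#' computed from ranks so ties are handled exactly; ROC points are given
#' at every distinct threshold (predict positive at score >= threshold).
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1), both classes present.
#' @return List with `points` (data frame threshold / fpr / tpr, ordered
#'   by increasing fpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Youden-index operating point
#'
#' Scans all candidate cutoffs (the distinct observed scores plus +Inf;
#' predict positive at score >= cutoff) and returns the cutoff maximizing
#' J = sensitivity + specificity - 1, ties broken toward the smallest
#' cutoff.
#'
#' @inheritParams roc_auc
#' @return List with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  cand <- c(sort(unique(scores)), Inf)
  sens <- vapply(cand, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  spec <- vapply(cand, function(t) sum(scores < t & labels == 0L) / n0, 0)
  J <- sens + spec - 1
  best <- which(J == max(J))[1L]  # cand sorted ascending: first = smallest
  list(cutoff = cand[best], J = J[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Subgroup metrics at a fixed cutoff
#'
#' Per radiological finding f in {mass, calcification, distortion}, AUC on
#' the cancer images with finding f together with all non-cancer images of
#' finding f; for normal images (where AUC is undefined) the normal-true-
#' negative rate, the fraction scored below the cutoff. Per breast density
#' class, AUC over all images of that class. Subgroups with one class are
#' reported as NA rather than aborting.
#'
#' @param score_table Data frame with columns score, label, finding,
#'   density (e.g. a [run_arm()] result).
#' @param cutoff Operating cutoff (e.g. from [youden_cutoff()]).
#' @return List with `per_finding_auc`, `normal_tnr`, `per_density_auc`.
#' @export
subgroup_report <- function(score_table, cutoff) {
  need <- c("score", "label", "finding", "density")
  if (!all(need %in% names(score_table)))
    stop("score table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  safe_auc <- function(s, l) {
    if (length(unique(as.integer(l))) < 2L) return(NA_real_)
    roc_auc(s, l)$auc
  }
  lesions <- c("mass", "calcification", "distortion")
  pf <- vapply(lesions, function(f) {
    sub <- score_table[score_table$finding == f, ]
    safe_auc(sub$score, sub$label)
  }, 0)
  nrm <- score_table[score_table$finding == "normal", ]
  ntnr <- if (nrow(nrm)) mean(nrm$score < cutoff) else NA_real_
  pd <- vapply(unique(score_table$density), function(d) {
    sub <- score_table[score_table$density == d, ]
    safe_auc(sub$score, sub$label)
  }, 0)
  list(per_finding_auc = pf, normal_tnr = ntnr, per_density_auc = pd)
}

#' Vertically averaged mean ROC curve
#'
#' Interpolates each trial's ROC curve onto the fixed 101-point FPR grid
#' 0, 0.01, ..., 1 (linear interpolation in FPR, taking the maximal TPR at
#' duplicated FPR values) and averages vertically, with a min/max
#' envelope.
#'
#' @param per_trial_rocs List of ROC point data frames (from
#'   [roc_auc()]`$points`).
#' @return List with `fpr` (grid), `mean_tpr`, `lo`, `hi`.
#' @export
mean_roc_curve <- function(per_trial_rocs) {
  if (!length(per_trial_rocs)) stop("no ROC curves supplied", call. = FALSE)
  grid <- seq(0, 1, by = 0.01)
  interp <- vapply(per_trial_rocs, function(pts) {
    stats::approx(pts$fpr, pts$tpr, xout = grid, ties = max, rule = 2)$y
  }, grid)
  interp <- matrix(interp, nrow = length(grid))
  list(fpr = grid,
       mean_tpr = rowMeans(interp),
       lo = apply(interp, 1, min),
       hi = apply(interp, 1, max))
}

#' Patient-grouped repeated k-fold split plan
#'
#' For each trial, patients are shuffled under a trial-specific seed and
#' dealt round-robin into k folds, so fold sizes differ by at most one
#' patient and no patient ever spans folds within a trial.
#'
#' @param patient_ids Character vector of (possibly repeated) patient ids;
#'   the distinct set is split.
#' @param k Folds (default 5).
#' @param trials Repetitions (default 10).
#' @param seed Integer base seed.
#' @return An object of class `split_plan`: list with `k`, `trials`,
#'   `seed` and `assignment` (data frame trial / patient_id / fold).
#' @export
grouped_kfold <- function(patient_ids, k = 5L, trials = 10L, seed = 1L) {
  patients <- unique(as.character(patient_ids))
  if (length(patients) < k)
    stop("fewer distinct patients than folds", call. = FALSE)
  out <- vector("list", trials)
  for (tr in seq_len(trials)) {
    shuffled <- withr::with_seed(seed + 7919L * tr,
                                 sample(patients))
    out[[tr]] <- data.frame(trial = tr, patient_id = shuffled,
                            fold = rep_len(seq_len(k), length(shuffled)),
                            stringsAsFactors = FALSE)
  }
  structure(list(k = as.integer(k), trials = as.integer(trials),
                 seed = as.integer(seed),
                 assignment = do.call(rbind, out)),
            class = "split_plan")
}

#' Paired t-test between per-trial AUC vectors
#'
#' Two-sided paired t-test on the trial-wise AUC differences between two
#' arms (pairing is justified because arms share trial and fold seeds).
#' Degenerate cases: all differences zero gives t = 0, p = 1; zero
#' variance with nonzero mean gives p = 0 in the limit.
#'
#' @param trial_aucs_a,trial_aucs_b Equal-length numeric vectors (one AUC
#'   per trial), n >= 2.
#' @param paired Use the paired test (default); unpaired Welch otherwise.
#' @return List with `t` and `p`.
#' @export
compare_auc_ttest <- function(trial_aucs_a, trial_aucs_b, paired = TRUE) {
  if (length(trial_aucs_a) != length(trial_aucs_b))
    stop("trial vectors must have equal length", call. = FALSE)
  if (length(trial_aucs_a) < 2L) stop("need n >= 2 trials", call. = FALSE)
  d <- trial_aucs_a - trial_aucs_b
  if (paired && stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- if (paired) stats::t.test(trial_aucs_a, trial_aucs_b, paired = TRUE)
        else stats::t.test(trial_aucs_a, trial_aucs_b)
  list(t = unname(ht$statistic), p = ht$p.value)
}

ci95 <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  c(lo = m - 1.96 * se, hi = m + 1.96 * se)
}

#' Full evaluation report over repeated cross-validation trials
#'
#' Per trial (pooling that trial's folds): AUC, Youden cutoff with its
#' sensitivity and specificity, normal-TNR and subgroup AUCs. Reported
#' values are means over trials with 95% confidence intervals
#' (mean +/- 1.96 SE over trials), plus the vertically averaged mean ROC
#' curve.
#'
#' @param score_table A [run_arm()]-style data frame (must carry a `trial`
#'   column).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(score_table) {
  trials <- sort(unique(score_table$trial))
  per <- lapply(trials, function(tr) {
    sub <- score_table[score_table$trial == tr, ]
    roc <- roc_auc(sub$score, sub$label)
    yj <- youden_cutoff(sub$score, sub$label)
    sg <- subgroup_report(sub, yj$cutoff)
    list(auc = roc$auc, cutoff = yj$cutoff, sensitivity = yj$sensitivity,
         specificity = yj$specificity, normal_tnr = sg$normal_tnr,
         per_finding = sg$per_finding_auc, per_density = sg$per_density_auc,
         roc = roc$points)
  })
  get <- function(f) vapply(per, f, 0)
  pf <- do.call(rbind, lapply(per, function(x) x$per_finding))
  pd <- do.call(rbind, lapply(per, function(x) x$per_density))
  structure(list(
    n_trials = length(trials),
    auc = mean(get(function(x) x$auc)),
    sensitivity = mean(get(function(x) x$sensitivity)),
    specificity = mean(get(function(x) x$specificity)),
    cutoff = mean(get(function(x) x$cutoff)),
    normal_tnr = mean(get(function(x) x$normal_tnr)),
    per_finding_auc = colMeans(pf, na.rm = TRUE),
    per_density_auc = colMeans(pd, na.rm = TRUE),
    ci95 = list(auc = ci95(get(function(x) x$auc)),
                sensitivity = ci95(get(function(x) x$sensitivity)),
                specificity = ci95(get(function(x) x$specificity)),
                normal_tnr = ci95(get(function(x) x$normal_tnr))),
    trial_aucs = get(function(x) x$auc),
    mean_roc = mean_roc_curve(lapply(per, function(x) x$roc))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation over %d trials\n", x$n_trials))
  cat(sprintf("  AUC          %.3f (%.3f-%.3f)\n", x$auc,
              x$ci95$auc[1], x$ci95$auc[2]))
  cat(sprintf("  sensitivity  %.3f\n  specificity  %.3f\n  cutoff       %.3f\n",
              x$sensitivity, x$specificity, x$cutoff))
  if (is.finite(x$normal_tnr))
    cat(sprintf("  normal-TNR   %.3f\n", x$normal_tnr))
  pf <- x$per_finding_auc
  cat("  per-finding AUC:",
      paste(sprintf("%s %.3f", names(pf), pf), collapse = ", "), "\n")
  pd <- x$per_density_auc
  cat("  per-density AUC:",
      paste(sprintf("%s %.3f", names(pd), pd), collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional ROC CSV)
#'
#' @param report An `eval_report`.
#' @param json_path Output JSON path.
#' @param roc_csv_path Optional CSV path for the mean ROC grid.
#' @export
write_eval_report <- function(report, json_path, roc_csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  out <- unclass(report)
  out$mean_roc <- NULL
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(roc_csv_path)) {
    utils::write.csv(data.frame(fpr = report$mean_roc$fpr,
                                mean_tpr = report$mean_roc$mean_tpr,
                                lo = report$mean_roc$lo,
                                hi = report$mean_roc$hi),
                     roc_csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
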