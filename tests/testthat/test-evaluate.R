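test_that("segment-level fold plans stratify classes exactly", {
  tens <- random_tensor(n = 100, len = 8, ch = 2, seed = 1)
  tens$labels <- factor(rep(c("a", "b"), 50), levels = c("a", "b"))
  plan <- make_fold_plan(tens, 10, "segment_level", seed = 2)
  for (f in 1:10) {
    test_idx <- which(plan$fold == f)
    expect_length(test_idx, 10)
    expect_equal(as.numeric(table(tens$labels[test_idx])), c(5, 5))
  }
  # the rotation gives the global 70/20/10 split
  part <- fold_partition(plan, 1)
  expect_length(part$train, 70)
  expect_length(part$validation, 20)
  expect_length(part$test, 10)
  expect_setequal(c(part$train, part$validation, part$test), 1:100)

  plan2 <- make_fold_plan(tens, 10, "segment_level", seed = 2)
  expect_identical(plan$fold, plan2$fold)
  expect_error(make_fold_plan(subset_segments(tens, 1:15), 10), "need >=")
})

test_that("subject-level plans keep each subject inside one fold", {
  tens <- random_tensor(n = 120, len = 8, ch = 2, seed = 3, subjects = 12)
  tens$labels <- factor(rep(c("a", "b"), each = 60), levels = c("a", "b"))
  tens$info$subject_id <- rep(sprintf("S%02d", 1:12), each = 10)
  plan <- make_fold_plan(tens, 6, "subject_level", seed = 4)
  tab <- table(tens$info$subject_id, plan$fold)
  expect_true(all(rowSums(tab > 0) == 1))
  for (f in 1:6) {
    part <- fold_partition(plan, f)
    expect_length(intersect(unique(tens$info$subject_id[part$train]),
                            unique(tens$info$subject_id[part$test])), 0)
  }
  # fold plan file round-trip supports exact reruns
  path <- tempfile(fileext = ".csv")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_identical(back$fold, plan$fold)
  expect_identical(back$policy, plan$policy)
})

test_that("confusion-matrix metrics match hand arithmetic", {
  cm <- structure(list(tp = 90, fp = 20, tn = 80, fn = 10, positive = "pos"),
                  class = "confusion_matrix")
  met <- classification_metrics(cm)
  expect_equal(met$sensitivity, 0.9)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$overall_accuracy, 0.85)
  expect_equal(met$precision, 90 / 110)
  expect_equal(met$f_measure, 2 * (90 / 110) * 0.9 / (90 / 110 + 0.9))

  perfect <- structure(list(tp = 5, fp = 0, tn = 5, fn = 0, positive = "p"),
                       class = "confusion_matrix")
  mp <- classification_metrics(perfect)
  expect_true(all(unlist(mp) == 1))
  expect_equal(cohen_kappa(perfect), 1)

  worst <- structure(list(tp = 0, fp = 5, tn = 0, fn = 5, positive = "p"),
                     class = "confusion_matrix")
  mw <- classification_metrics(worst)
  expect_equal(mw$sensitivity, 0)
  expect_equal(mw$specificity, 0)

  degen <- structure(list(tp = 0, fp = 0, tn = 5, fn = 0, positive = "p"),
                     class = "confusion_matrix")
  # both the sensitivity and precision denominators are zero here
  md <- suppressWarnings(classification_metrics(degen))
  expect_warning(expect_warning(classification_metrics(degen), "undefined"))
  expect_true(is.na(md$sensitivity) && is.na(md$precision))
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  # direct-formula oracle
  kappa_oracle <- function(tp, fp, tn, fn) {
    n <- tp + fp + tn + fn
    po <- (tp + tn) / n
    pe <- ((tp + fn) * (tp + fp) + (fn + tn) * (fp + tn)) / n^2
    (po - pe) / (1 - pe)
  }
  cm <- structure(list(tp = 90, fp = 20, tn = 80, fn = 10, positive = "p"),
                  class = "confusion_matrix")
  expect_equal(cohen_kappa(cm), kappa_oracle(90, 20, 80, 10))
  expect_equal(cohen_kappa(cm), 0.7)

  # chance-level predictions (counts equal products of marginals) give 0
  chance <- structure(list(tp = 24, fp = 36, tn = 24, fn = 16, positive = "p"),
                      class = "confusion_matrix")
  expect_equal(cohen_kappa(chance), 0)

  set.seed(6)
  for (i in 1:25) {
    v <- sample(0:40, 4, replace = TRUE) + 1
    cm <- structure(list(tp = v[1], fp = v[2], tn = v[3], fn = v[4],
                         positive = "p"), class = "confusion_matrix")
    expect_equal(cohen_kappa(cm), kappa_oracle(v[1], v[2], v[3], v[4]))
    met <- classification_metrics(cm)
    expect_equal(met$overall_accuracy,
                 1 - (v[2] + v[4]) / sum(v))  # accuracy identity
  }

  degen <- structure(list(tp = 7, fp = 0, tn = 0, fn = 0, positive = "p"),
                     class = "confusion_matrix")
  expect_warning(k <- cohen_kappa(degen), "degenerate")
  expect_equal(k, 0)
})

test_that("AUC equals the normalised Mann-Whitney statistic", {
  auc_oracle <- function(scores, pos) {
    s_pos <- scores[pos]; s_neg <- scores[!pos]
    tot <- 0
    for (a in s_pos) for (b in s_neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
    tot / (length(s_pos) * length(s_neg))
  }
  lab <- factor(rep(c("n", "p"), each = 10), levels = c("n", "p"))
  expect_equal(roc_auc(c(rnorm(10), rnorm(10) + 100), lab), 1)
  expect_equal(roc_auc(rep(0.5, 20), lab), 0.5)

  set.seed(7)
  for (i in 1:20) {
    scores <- round(runif(20), 1)  # rounding forces ties
    pos <- lab == "p"
    expect_equal(roc_auc(scores, lab), auc_oracle(scores, pos))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(3 * scores), lab), roc_auc(scores, lab))
  }
  expect_error(roc_auc(runif(5), factor(rep("p", 5), levels = c("n", "p"))),
               "both classes")
})

test_that("AUC agrees with an independent implementation when available", {
  skip_if_not_installed("pROC")
  set.seed(8)
  lab <- factor(sample(c("n", "p"), 50, replace = TRUE), levels = c("n", "p"))
  scores <- runif(50) + 0.5 * (lab == "p")
  ref <- as.numeric(pROC::auc(pROC::roc(lab, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, lab), ref)
})

test_that("cross-validation aggregates folds without touching test partitions", {
  set.seed(30)
  tens <- random_tensor(n = 80, len = 32, ch = 4, seed = 30)
  # make classes separable so training converges quickly
  shift <- array(rep(as.integer(tens$labels) - 1, 32 * 4) * 2, c(80, 32, 4))
  tens$segments <- tens$segments + shift
  plan <- make_fold_plan(tens, 5, "segment_level", seed = 31)
  rep1 <- suppressWarnings(run_cross_validation(
    tens, plan, arch = tiny_arch(),
    train_cfg = train_config(batch_size = 16, epochs = 3, seed = 32),
    augment_cfg = augment_config(seed = 33), folds = 1:2))

  expect_equal(nrow(rep1$per_fold), 2)
  expect_equal(sum(rep1$per_fold$n_test), cm_total <- with(rep1$confusion,
                                                           tp + fp + tn + fn))
  expect_equal(nrow(rep1$summary), 2)
  expect_identical(rep1$summary$stat, c("mean", "sd"))
  expect_true(all(rep1$per_fold$overall_accuracy >= 0 &
                    rep1$per_fold$overall_accuracy <= 1))

  # determinism: identical rerun gives identical metrics
  rep2 <- suppressWarnings(run_cross_validation(
    tens, plan, arch = tiny_arch(),
    train_cfg = train_config(batch_size = 16, epochs = 3, seed = 32),
    augment_cfg = augment_config(seed = 33), folds = 1:2))
  expect_equal(rep1$per_fold, rep2$per_fold)

  # artificial segments are refused as CV input
  aug <- augment_training_partition(tens, augment_config())
  expect_error(run_cross_validation(aug, plan), "real segments")

  # report files are written
  base <- file.path(tempdir(), "cvrep")
  write_metrics_report(rep1, base)
  expect_true(file.exists(paste0(base, "_metrics.csv")))
  expect_true(file.exists(paste0(base, "_metrics.json")))
  expect_true(file.exists(paste0(base, "_confusion.csv")))
})
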