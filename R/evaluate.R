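#' Stratified cross-validation fold plan
#'
#' Assigns segments to `n_folds` folds with class label distributions
#' preserved to within one segment per class. Under the `subject_level`
#' policy all segments of one subject share one fold, so no subject can
#' span the train/test boundary (the `segment_level` policy mirrors the
#' published protocol but leaks subject identity across partitions).
#'
#' For fold `f`, the test partition is fold `f`, the validation partition
#' is the next two folds cyclically, and the remaining seven folds train --
#' a fixed 70/20/10 global split.
#'
#' @param tensor A [segment_tensor()].
#' @param n_folds Number of folds (default 10).
#' @param policy `"segment_level"` or `"subject_level"`.
#' @param seed Seed for the shuffling.
#' @return An object of class `fold_plan`.
#' @export
make_fold_plan <- function(tensor, n_folds = 10,
                           policy = c("segment_level", "subject_level"),
                           seed = 1) {
  policy <- match.arg(policy)
  n <- dim(tensor$segments)[1]
  labels <- tensor$labels
  fold <- integer(n)

  with_seed(seed, {
    if (policy == "segment_level") {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < n_folds) {
          stop("class '", cl, "' has ", length(idx),
               " segments; need >= ", n_folds, call. = FALSE)
        }
        idx <- sample(idx)
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      subj <- tensor$info$subject_id
      # group subjects by their label signature so stratification holds
      sig <- vapply(split(as.character(labels), subj),
                    function(l) paste(sort(unique(l)), collapse = "+"),
                    character(1))
      for (g in unique(sig)) {
        subs <- names(sig)[sig == g]
        if (length(subs) < n_folds && length(unique(sig)) == 1) {
          stop("only ", length(subs), " subjects; need >= ", n_folds,
               " for subject-level folds", call. = FALSE)
        }
        subs <- sample(subs)
        sub_fold <- rep_len(seq_len(n_folds), length(subs))
        for (i in seq_along(subs)) fold[subj == subs[i]] <- sub_fold[i]
      }
      if (any(fold == 0)) stop("unassigned segments in fold plan",
                               call. = FALSE)
    }
  })
  structure(list(n_folds = as.integer(n_folds), policy = policy,
                 seed = seed, fold = fold),
            class = "fold_plan")
}

#' Train/validation/test indices for one fold
#'
#' @param plan A [make_fold_plan()] result.
#' @param f Fold number in `1..n_folds`.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
fold_partition <- function(plan, f) {
  stopifnot(inherits(plan, "fold_plan"), f >= 1, f <= plan$n_folds)
  k <- plan$n_folds
  val_folds <- (c(f, f + 1) %% k) + 1L
  list(train = which(!plan$fold %in% c(f, val_folds)),
       validation = which(plan$fold %in% val_folds),
       test = which(plan$fold == f))
}

#' Write / read a fold plan for exact reruns
#' @param plan A `fold_plan`.
#' @param path CSV path.
#' @return `path` / the reloaded `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  utils::write.csv(data.frame(segment = seq_along(plan$fold),
                              fold = plan$fold,
                              n_folds = plan$n_folds, policy = plan$policy,
                              seed = plan$seed),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(n_folds = df$n_folds[1], policy = df$policy[1],
                 seed = df$seed[1], fold = df$fold),
            class = "fold_plan")
}

#' Binary confusion matrix
#'
#' @param truth,pred Factors with the same levels; the positive class is
#'   the second level unless `positive` is given.
#' @param positive Positive class label.
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_matrix <- function(truth, pred, positive = NULL) {
  truth <- as.factor(truth)
  pred <- factor(as.character(pred), levels = levels(truth))
  if (is.null(positive)) positive <- levels(truth)[2]
  tpos <- truth == positive
  ppos <- pred == positive
  structure(list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
                 tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(t(m))
  invisible(x)
}

cm_total <- function(cm) cm$tp + cm$fp + cm$tn + cm$fn

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, overall accuracy,
#' precision `tp/(tp+fp)`, recall (= sensitivity) and F-measure (harmonic
#' mean of precision and sensitivity). A zero denominator yields `NA` with
#' a warning, never a silent 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list of metric values.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- safe_div(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  fme <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec,
       overall_accuracy = (cm$tp + cm$tn) / cm_total(cm),
       precision = prec, recall = sens, f_measure = fme)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)` with `p_o` the
#' observed accuracy and `p_e` the product-of-marginals chance agreement.
#' Degenerate marginals (`p_e = 1`) yield 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    warning("degenerate marginals; kappa defined as 0", call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' ROC area under the curve
#'
#' The Mann-Whitney statistic: the probability that a random positive
#' scores above a random negative, with ties counting one half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Positive-class scores/probabilities.
#' @param labels Factor; the positive class is the second level.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  pos <- labels == levels(labels)[2]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run cross-validated training and evaluation
#'
#' For each requested fold: split by the fold plan, augment only the
#' training partition, train the network, and evaluate on the untouched
#' test partition. Per-fold metrics are averaged (with SDs) over folds and
#' confusion counts are summed. Artificial segments never reach the
#' validation or test partitions; this is asserted from provenance on every
#' run.
#'
#' @param tensor A [segment_tensor()] of real (non-artificial) segments.
#' @param plan A [make_fold_plan()] for `tensor`.
#' @param arch An [architecture_spec()].
#' @param train_cfg A [train_config()].
#' @param augment_cfg An [augment_config()], or `NULL` to skip augmentation.
#' @param folds Folds to run (default all; a subset gives a cheaper
#'   unbiased estimate since folds are exchangeable).
#' @return An object of class `metrics_report`: `per_fold` data frame,
#'   `summary` (mean/SD rows), aggregated `confusion`, and the fold plan
#'   policy.
#' @export
run_cross_validation <- function(tensor, plan, arch = default_architecture(),
                                 train_cfg = train_config(),
                                 augment_cfg = augment_config(),
                                 folds = seq_len(plan$n_folds)) {
  if (any(tensor$info$is_artificial)) {
    stop("tensor passed to CV must contain only real segments", call. = FALSE)
  }
  stopifnot(inherits(plan, "fold_plan"),
            length(plan$fold) == dim(tensor$segments)[1])
  per_fold <- list()
  agg <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  positive <- levels(tensor$labels)[2]

  for (f in folds) {
    part <- fold_partition(plan, f)
    if (nlevels(droplevels(tensor$labels[part$test])) < 2) {
      stop("fold ", f, " has a single-class test partition", call. = FALSE)
    }
    if (plan$policy == "subject_level") {
      overlap <- intersect(unique(tensor$info$subject_id[part$train]),
                           unique(tensor$info$subject_id[part$test]))
      if (length(overlap)) {
        stop("subject-level leakage in fold ", f, ": ",
             paste(overlap, collapse = ", "), call. = FALSE)
      }
    }
    train <- subset_segments(tensor, part$train)
    if (!is.null(augment_cfg)) {
      cfg_f <- augment_cfg
      cfg_f$seed <- augment_cfg$seed + f  # independent draws per fold
      train <- augment_training_partition(train, cfg_f)
    }
    val <- subset_segments(tensor, part$validation)
    test <- subset_segments(tensor, part$test)
    stopifnot(!any(val$info$is_artificial), !any(test$info$is_artificial))

    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    model <- build_and_train(arch, train, val, cfg_f)
    probs <- predict_proba(model, test)
    pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                   levels = levels(tensor$labels))
    cm <- confusion_matrix(test$labels, pred, positive)
    met <- classification_metrics(cm)
    met$cohen_kappa <- cohen_kappa(cm)
    met$auc <- roc_auc(probs[, positive], test$labels)
    per_fold[[length(per_fold) + 1]] <-
      data.frame(fold = f, n_test = cm_total(cm), as.data.frame(met))
    for (nm in c("tp", "fp", "tn", "fn")) agg[[nm]] <- agg[[nm]] + cm[[nm]]
  }

  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test"))
  summary <- data.frame(
    stat = c("mean", "sd"),
    rbind(colMeans(per_fold[metric_cols]),
          apply(per_fold[metric_cols], 2, stats::sd)))
  names(summary)[-1] <- metric_cols
  confusion <- structure(c(agg, list(positive = positive)),
                         class = "confusion_matrix")
  structure(list(per_fold = per_fold, summary = summary,
                 confusion = confusion, policy = plan$policy,
                 folds = folds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds (%s policy)\n",
              nrow(x$per_fold), x$policy))
  m <- x$summary[x$summary$stat == "mean", -1]
  s <- x$summary[x$summary$stat == "sd", -1]
  for (nm in names(m)) {
    cat(sprintf("  %-17s %.3f (+/- %.3f)\n", nm, m[[nm]], s[[nm]]))
  }
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report A `metrics_report`.
#' @param path Base path; `_metrics.csv`, `_metrics.json` and
#'   `_confusion.csv` are appended.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  per <- report$per_fold
  summ <- report$summary
  out <- rbind(cbind(stat = as.character(per$fold),
                     per[, setdiff(names(per), "fold")]),
               cbind(stat = summ$stat,
                     n_test = NA, summ[, -1]))
  utils::write.csv(out, paste0(path, "_metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_fold = report$per_fold, summary = report$summary,
         policy = report$policy),
    paste0(path, "_metrics.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  cm <- report$confusion
  utils::write.csv(data.frame(tp = cm$tp, fp = cm$fp, tn = cm$tn,
                              fn = cm$fn, positive = cm$positive),
                   paste0(path, "_confusion.csv"), row.names = FALSE)
  invisible(path)
}
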