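#' Augmentation configuration
#'
#' The training set grows by about `fraction_per_fold` for each of the
#' `n_folds` cross-validation folds, i.e. by `fraction_per_fold * n_folds`
#' in total (about 20% with the defaults). Artificial segments are built by
#' averaging `n_average` randomly drawn same-class training segments and
#' then re-injecting a small fraction of raw time instances from one parent.
#'
#' @param fraction_per_fold Per-fold growth fraction (default 0.02).
#' @param n_folds Number of CV folds entering the total (default 10).
#' @param n_average Segments averaged per artificial sample (>= 2).
#' @param perturb_fraction Fraction of time instances per channel replaced
#'   by a parent's raw values (default 0.02).
#' @param seed Seed for parent selection and perturbation.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(fraction_per_fold = 0.02, n_folds = 10,
                           n_average = 2, perturb_fraction = 0.02,
                           seed = 1) {
  if (fraction_per_fold < 0 || fraction_per_fold > 1) {
    stop("fraction_per_fold must lie in [0, 1]", call. = FALSE)
  }
  if (n_average < 2) stop("n_average must be >= 2", call. = FALSE)
  if (perturb_fraction < 0 || perturb_fraction > 1) {
    stop("perturb_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(fraction_per_fold = fraction_per_fold, n_folds = n_folds,
                 n_average = n_average, perturb_fraction = perturb_fraction,
                 seed = seed),
            class = "augment_config")
}

#' Total dataset size after augmentation
#'
#' `ceiling(n * (1 + fraction_per_fold * n_folds))`. The ceiling matches
#' the published sizing arithmetic for every self-consistent column of the
#' source sizing table (27,683 -> 33,220; 28,050 -> 33,660;
#' 14,358 -> 17,230; 27,616 -> 33,140).
#'
#' @param n_segments Segment count before augmentation.
#' @param cfg An [augment_config()].
#' @return Integer total after augmentation.
#' @export
#' @examples
#' augmented_total_size(27683, augment_config())  # 33220
augmented_total_size <- function(n_segments, cfg = augment_config()) {
  if (n_segments < 1) stop("n_segments must be >= 1", call. = FALSE)
  as.integer(ceiling(n_segments * (1 + cfg$fraction_per_fold * cfg$n_folds)))
}

#' Dataset sizing arithmetic for one task
#'
#' Reproduces the sizing chain: segments after reshaping, total after
#' augmentation, and the 90/10 split into train+validation vs test.
#'
#' @param n_segments Segment count after reshaping.
#' @param cfg An [augment_config()].
#' @return List with `reshaped`, `augmented`, `train_validation`, `test`.
#' @export
#' @examples
#' dataset_sizing(27683)  # 33220 total; 29898 train+val; 3322 test
dataset_sizing <- function(n_segments, cfg = augment_config()) {
  total <- augmented_total_size(n_segments, cfg)
  test <- as.integer(round(total / cfg$n_folds))
  list(reshaped = as.integer(n_segments), augmented = total,
       train_validation = total - test, test = test)
}

#' Generate artificial training segments by random averaging
#'
#' Each artificial segment is the element-wise mean of `cfg$n_average`
#' randomly drawn training segments of one class; then, independently per
#' channel, `cfg$perturb_fraction` of its time instances are replaced by the
#' corresponding raw values of one randomly chosen parent. Labels equal the
#' parents' shared class and provenance records the parent indices.
#' Deterministic given `cfg$seed`.
#'
#' @param train A [segment_tensor()] of training segments.
#' @param k Number of artificial segments to generate.
#' @param cfg An [augment_config()].
#' @param classes Optional character vector of length `k` fixing the class
#'   of each artificial segment; defaults to sampling classes proportionally
#'   to their training frequency.
#' @return A [segment_tensor()] of `k` artificial segments.
#' @export
make_artificial_segments <- function(train, k, cfg = augment_config(),
                                     classes = NULL) {
  stopifnot(inherits(train, "segment_tensor"))
  d <- dim(train$segments)
  if (k == 0) {
    return(segment_tensor(array(0, c(0, d[2], d[3])),
                          factor(character(0), levels = levels(train$labels))))
  }
  counts <- table(train$labels)
  small <- names(counts)[counts < cfg$n_average & counts > 0]
  used_classes <- if (is.null(classes)) names(counts)[counts > 0] else
    unique(classes)
  bad <- intersect(used_classes, small)
  if (length(bad)) {
    stop("class '", bad[1], "' has fewer than n_average = ", cfg$n_average,
         " training segments", call. = FALSE)
  }

  with_seed(cfg$seed, {
    if (is.null(classes)) {
      pool <- names(counts)[counts > 0]
      classes <- sample(pool, k, replace = TRUE,
                        prob = counts[pool] / sum(counts[pool]))
    }
    seg <- array(0, c(k, d[2], d[3]))
    parent_ids <- character(k)
    n_swap <- round(cfg$perturb_fraction * d[2])
    for (i in seq_len(k)) {
      cand <- which(train$labels == classes[i])
      par <- sample(cand, cfg$n_average)
      avg <- apply(train$segments[par, , , drop = FALSE], c(2, 3), mean)
      if (n_swap > 0) {
        donor <- train$segments[sample(par, 1), , ]
        for (ch in seq_len(d[3])) {
          idx <- sample.int(d[2], n_swap)
          avg[idx, ch] <- donor[idx, ch]
        }
      }
      seg[i, , ] <- avg
      parent_ids[i] <- paste(par, collapse = "|")
    }
    info <- data.frame(subject_id = NA_character_, session = NA_character_,
                       condition = NA_character_, source_offset = NA_integer_,
                       is_artificial = TRUE, parent_ids = parent_ids,
                       stringsAsFactors = FALSE)[rep(1, k), ]
    info$parent_ids <- parent_ids
    rownames(info) <- NULL
    segment_tensor(seg, factor(classes, levels = levels(train$labels)), info)
  })
}

#' Augment a training partition to its target size
#'
#' Appends `augmented_total_size(n, cfg) - n` artificial segments to the
#' training partition, allocating them across classes proportionally to the
#' class frequencies (largest-remainder rounding) so class proportions are
#' preserved to within one segment per class. Never applied to validation
#' or test partitions.
#'
#' @param train A [segment_tensor()] of training segments.
#' @param cfg An [augment_config()].
#' @return The augmented [segment_tensor()]; artificial segments are marked
#'   `is_artificial` in the provenance.
#' @export
augment_training_partition <- function(train, cfg = augment_config()) {
  n <- dim(train$segments)[1]
  if (n == 0) stop("empty training partition", call. = FALSE)
  k <- augmented_total_size(n, cfg) - n
  if (k == 0) return(train)

  counts <- table(train$labels)
  counts <- counts[counts > 0]
  exact <- k * as.numeric(counts) / sum(counts)
  alloc <- floor(exact)
  rem <- k - sum(alloc)
  if (rem > 0) {
    order_rem <- order(exact - alloc, decreasing = TRUE)
    alloc[order_rem[seq_len(rem)]] <- alloc[order_rem[seq_len(rem)]] + 1
  }
  classes <- rep(names(counts), alloc)
  art <- make_artificial_segments(train, k, cfg, classes = classes)
  combine_segments(train, art)
}
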