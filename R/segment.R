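#' Stacked fixed-length EEG segments
#'
#' The tensor fed to the classifier: `n_segments x segment_len x n_channels`
#' with one class label per segment and a provenance table recording, for
#' every segment, its source subject/session/condition, its sample offset in
#' the source recording, and (for augmented data) its parents.
#'
#' @param segments Numeric array `n x segment_len x channels` (time-major).
#' @param labels Factor (or coercible) of length `n`; the second factor
#'   level is the positive class.
#' @param info Data frame with `n` rows: columns `subject_id`, `session`,
#'   `condition`, `source_offset`, `is_artificial`, `parent_ids`.
#' @return An object of class `segment_tensor`.
#' @export
segment_tensor <- function(segments, labels, info = NULL) {
  stopifnot(is.array(segments), length(dim(segments)) == 3)
  n <- dim(segments)[1]
  labels <- as.factor(labels)
  if (length(labels) != n) stop("one label per segment required", call. = FALSE)
  if (is.null(info)) {
    info <- data.frame(subject_id = rep(NA_character_, n),
                       session = rep(NA_character_, n),
                       condition = rep(NA_character_, n),
                       source_offset = rep(NA_integer_, n),
                       is_artificial = rep(FALSE, n),
                       parent_ids = rep(NA_character_, n),
                       stringsAsFactors = FALSE)
  }
  if (nrow(info) != n) stop("info must have one row per segment", call. = FALSE)
  structure(list(segments = segments, labels = labels, info = info),
            class = "segment_tensor")
}

#' @export
print.segment_tensor <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_tensor> %d x %d x %d", d[1], d[2], d[3]))
  if (d[1] > 0) {
    tab <- table(x$labels)
    cat("  [", paste(names(tab), tab, sep = ": ", collapse = ", "), "]")
    na <- sum(x$info$is_artificial)
    if (na > 0) cat(sprintf("  (%d artificial)", na))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.segment_tensor <- function(x) dim(x$segments)

#' Number of whole segments obtainable from recordings
#'
#' The dataset-sizing arithmetic: each recording of `m` samples yields
#' `floor(m / segment_len)` non-overlapping segments; the trailing remainder
#' is discarded.
#'
#' @param sample_counts Integer vector of per-recording sample counts.
#' @param segment_len Segment length in samples.
#' @return Total segment count.
#' @export
#' @examples
#' count_segments(13841500, 500)  # 27683
count_segments <- function(sample_counts, segment_len) {
  sum(floor(sample_counts / segment_len))
}

#' Cut a recording into fixed-length segments
#'
#' Non-overlapping consecutive windows of `segment_len` samples; the
#' trailing remainder shorter than `segment_len` is discarded. Segments are
#' stored time-major (`segment_len x channels`).
#'
#' @param rec An [eeg_recording()].
#' @param segment_len Segment length in samples (default 500, i.e. 1 s at
#'   500 Hz).
#' @param label Class label attached to every segment of this recording.
#' @return A [segment_tensor()].
#' @export
segment_recording <- function(rec, segment_len = 500, label = rec$session) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (segment_len < 1) stop("segment_len must be >= 1", call. = FALSE)
  n <- ncol(rec$data)
  k <- floor(n / segment_len)
  nch <- nrow(rec$data)
  if (k == 0) {
    warning("recording shorter than segment_len; empty tensor", call. = FALSE)
    return(segment_tensor(array(0, c(0, segment_len, nch)),
                          factor(character(0))))
  }
  used <- k * segment_len
  # channels x samples -> k x segment_len x channels, time-major
  seg <- aperm(array(t(rec$data[, seq_len(used), drop = FALSE]),
                     c(segment_len, k, nch)), c(2, 1, 3))
  info <- data.frame(subject_id = rec$subject_id, session = rec$session,
                     condition = rec$condition,
                     source_offset = (seq_len(k) - 1L) * segment_len,
                     is_artificial = FALSE, parent_ids = NA_character_,
                     stringsAsFactors = FALSE)
  segment_tensor(seg, rep(label, k), info)
}

#' Concatenate segment tensors
#'
#' @param ... `segment_tensor` objects with identical segment shape.
#' @return A combined [segment_tensor()]; factor levels are unioned in order
#'   of appearance.
#' @export
combine_segments <- function(...) {
  parts <- Filter(function(p) dim(p)[1] > 0, list(...))
  if (length(parts) == 0) stop("nothing to combine", call. = FALSE)
  if (length(parts) == 1) return(parts[[1]])
  shp <- dim(parts[[1]])[-1]
  for (p in parts) stopifnot(identical(dim(p)[-1], shp))
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  seg <- array(0, c(n, shp))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    seg[(at + 1):(at + k), , ] <- p$segments
    at <- at + k
  }
  levs <- unique(unlist(lapply(parts, function(p) levels(p$labels))))
  labels <- factor(unlist(lapply(parts, function(p) as.character(p$labels))),
                   levels = levs)
  info <- do.call(rbind, lapply(parts, function(p) p$info))
  rownames(info) <- NULL
  segment_tensor(seg, labels, info)
}

#' Subset a segment tensor
#'
#' @param tensor A [segment_tensor()].
#' @param idx Integer or logical index over segments.
#' @return The subsetted [segment_tensor()] (factor levels preserved).
#' @export
subset_segments <- function(tensor, idx) {
  segment_tensor(tensor$segments[idx, , , drop = FALSE],
                 tensor$labels[idx],
                 tensor$info[idx, , drop = FALSE])
}

#' Treatment-response labelling rule
#'
#' A patient is a responder when the BDI-II score fell by at least 50%:
#' `(bdi_pre - bdi_post) / bdi_pre >= 0.5`. Vectorised; scale-invariant in
#' its arguments.
#'
#' @param bdi_pre,bdi_post Pre-/post-treatment BDI-II scores; `bdi_pre`
#'   must be positive.
#' @return Factor with levels `nonresponder`, `responder`.
#' @export
#' @examples
#' label_response(30, 15)  # responder (exactly 50%)
#' label_response(30, 16)  # nonresponder
label_response <- function(bdi_pre, bdi_post) {
  if (any(bdi_pre <= 0)) {
    stop("response is undefined for bdi_pre <= 0", call. = FALSE)
  }
  if (any(bdi_post < 0)) stop("bdi_post must be >= 0", call. = FALSE)
  factor(ifelse((bdi_pre - bdi_post) / bdi_pre >= 0.5,
                "responder", "nonresponder"),
         levels = c("nonresponder", "responder"))
}

#' Assemble the labelled data matrix for one classification task
#'
#' Selects and labels segments according to the five task definitions:
#' \describe{
#'   \item{1}{female, pre vs post session}
#'   \item{2}{male, pre vs post session}
#'   \item{3}{female pre-treatment, responder vs nonresponder}
#'   \item{4}{male pre-treatment, responder vs nonresponder}
#'   \item{5}{both sexes pre-treatment, responder vs nonresponder}
#' }
#' Both eye conditions are pooled under the same class label.
#'
#' @param recordings List of (already preprocessed) [eeg_recording()]s.
#' @param subjects Data frame with columns `subject_id`, `sex`, `bdi_pre`,
#'   `bdi_post` (one row per subject).
#' @param model_id Task id, 1-5.
#' @param segment_len Segment length in samples.
#' @return A [segment_tensor()] with two classes. For tasks 1-2 the labels
#'   are `pre`/`post` (positive class `post`); for 3-5 they are
#'   `nonresponder`/`responder` (positive class `responder`).
#' @export
assemble_dataset <- function(recordings, subjects, model_id,
                             segment_len = 500) {
  if (!model_id %in% 1:5) stop("model_id must be in 1..5", call. = FALSE)
  meta <- subjects
  meta$response <- as.character(label_response(meta$bdi_pre, meta$bdi_post))

  sex_filter <- switch(model_id, "female", "male", "female", "male", NULL)
  session_task <- model_id %in% 1:2

  parts <- list()
  for (rec in recordings) {
    subj <- meta[meta$subject_id == rec$subject_id, ]
    if (nrow(subj) != 1) {
      stop("recording subject ", rec$subject_id, " not in subjects table",
           call. = FALSE)
    }
    if (!is.null(sex_filter) && subj$sex != sex_filter) next
    if (!session_task && rec$session != "pre") next
    lab <- if (session_task) rec$session else subj$response
    parts[[length(parts) + 1]] <- segment_recording(rec, segment_len, lab)
  }
  if (length(parts) == 0) stop("no recordings match task ", model_id,
                               call. = FALSE)
  out <- do.call(combine_segments, parts)
  levs <- if (session_task) c("pre", "post") else
    c("nonresponder", "responder")
  out$labels <- factor(as.character(out$labels), levels = levs)
  if (any(table(out$labels) == 0)) {
    stop("task ", model_id, " has an empty class: ",
         paste(levs[table(out$labels) == 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write/read a segment tensor with its provenance sidecar
#'
#' The tensor is stored as an RDS array plus a CSV of per-segment
#' provenance so a run can be audited without loading the array.
#'
#' @param tensor A [segment_tensor()].
#' @param path Base path; `.rds` and `_provenance.csv` are appended.
#' @return `path` invisibly / the reloaded [segment_tensor()].
#' @export
write_segments <- function(tensor, path) {
  saveRDS(list(segments = tensor$segments,
               labels = as.character(tensor$labels),
               levels = levels(tensor$labels)),
          paste0(path, ".rds"))
  prov <- cbind(tensor$info, label = as.character(tensor$labels))
  utils::write.csv(prov, paste0(path, "_provenance.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  raw <- readRDS(paste0(path, ".rds"))
  prov <- utils::read.csv(paste0(path, "_provenance.csv"),
                          stringsAsFactors = FALSE)
  segment_tensor(raw$segments, factor(raw$labels, levels = raw$levels),
                 prov[, setdiff(names(prov), "label")])
}
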