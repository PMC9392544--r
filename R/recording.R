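#' Continuous multichannel EEG recording
#'
#' Container for one subject/session/condition's continuous EEG: a
#' channels x samples matrix in microvolts plus acquisition metadata.
#'
#' @param data Numeric matrix, channels x samples (rows in montage order), in uV.
#' @param sampling_rate Sampling rate in Hz.
#' @param montage A [montage_spec()].
#' @param subject_id Subject identifier.
#' @param session `"pre"` or `"post"` (relative to the rTMS course).
#' @param condition `"eyes_open"` or `"eyes_closed"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, montage = montage_1020(),
                          subject_id = "S00", session = c("pre", "post"),
                          condition = c("eyes_closed", "eyes_open")) {
  session <- match.arg(session)
  condition <- match.arg(condition)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(data) != length(montage$channel_names)) {
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$channel_names), " channels", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("data must be finite", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  rownames(data) <- montage$channel_names
  structure(
    list(data = data, sampling_rate = sampling_rate, montage = montage,
         subject_id = subject_id, session = session, condition = condition),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session, x$condition,
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `eeg_recording`.
#' @return Integer sample count per channel.
#' @export
n_samples <- function(rec) ncol(rec$data)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
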