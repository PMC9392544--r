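#' Independent component analysis of a recording
#'
#' Fits a negentropy-maximising ICA (symmetric fixed-point iteration with
#' the logcosh contrast) after centering and PCA whitening. With all
#' components retained, `mixing %*% sources + means` reconstructs the input
#' to numerical precision, and the unmixed sources are pairwise uncorrelated.
#'
#' @param rec An [eeg_recording()] (or a channels x samples matrix).
#' @param n_components Number of components; defaults to the channel count
#'   (full rank). Use `channels - 1` for average- or linked-ears-referenced
#'   data whose rank is reduced. Reduced automatically (with a warning) if
#'   the data are rank-deficient.
#' @param seed Seed for the random orthogonal initialisation.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `ica_result` with elements `mixing`
#'   (channels x components), `sources` (components x samples), `means`
#'   (per-channel means), `rejected` (integer indices, initially empty) and
#'   `rejection_scores`.
#' @export
run_ica <- function(rec, n_components = NULL, seed = 1,
                    max_iter = 200, tol = 1e-6) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  nch <- nrow(x)
  n <- ncol(x)
  if (n <= nch * 10) {
    stop("need many more samples than channels for ICA", call. = FALSE)
  }
  if (is.null(n_components)) n_components <- nch

  means <- rowMeans(x)
  xc <- x - means
  cv <- tcrossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  rank <- sum(pos)
  if (n_components > rank) {
    warning("data rank ", rank, " < requested components ", n_components,
            "; reducing", call. = FALSE)
    n_components <- rank
  }
  k <- n_components
  d <- eg$values[seq_len(k)]
  e <- eg$vectors[, seq_len(k), drop = FALSE]
  whiten <- diag(1 / sqrt(d), k) %*% t(e)        # k x ch
  dewhiten <- e %*% diag(sqrt(d), k)             # ch x k
  z <- whiten %*% xc                             # whitened, unit covariance

  w <- with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
    q
  })
  sym_orth <- function(w) {
    s <- eigen(w %*% t(w), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), k) %*% t(s$vectors) %*% w
  }
  w <- sym_orth(w)
  for (it in seq_len(max_iter)) {
    wz <- w %*% z                 # k x n
    g <- tanh(wz)
    gp <- 1 - g^2
    w_new <- (g %*% t(z)) / n - diag(rowMeans(gp), k) %*% w
    w_new <- sym_orth(w_new)
    delta <- max(abs(abs(rowSums(w_new * w)) - 1))
    w <- w_new
    if (delta < tol) break
  }

  sources <- w %*% z                             # k x n
  mixing <- dewhiten %*% t(w)                    # ch x k
  structure(list(mixing = mixing, sources = sources, means = means,
                 channel_names = rownames(x),
                 rejected = integer(0),
                 rejection_scores = data.frame(component = seq_len(k),
                                               blink_cor = NA_real_,
                                               kurtosis = NA_real_),
                 n_iter = it, converged = delta < tol),
            class = "ica_result")
}

#' Flag artifact components
#'
#' Flags a component when (a) the absolute correlation of its source with
#' the frontal blink proxy (mean of Fp1 and Fp2) exceeds `blink_cor`, or
#' (b) its kurtosis (plain fourth-moment definition; 3 for a Gaussian)
#' exceeds `kurtosis`. Scores for every component are recorded. An empty
#' rejection set is a valid outcome.
#'
#' @param ica An `ica_result` fitted on `rec`.
#' @param rec The [eeg_recording()] the ICA was fitted on.
#' @param criteria List with thresholds `blink_cor` and `kurtosis`; use
#'   `Inf` to disable a criterion.
#' @return The `ica_result` with `rejected` and `rejection_scores` filled in.
#' @export
reject_artifact_components <- function(ica, rec,
                                       criteria = list(blink_cor = 0.8,
                                                       kurtosis = 5)) {
  stopifnot(inherits(ica, "ica_result"))
  x <- if (inherits(rec, "eeg_recording")) rec$data else rec
  ch_names <- rownames(x)
  fp <- which(ch_names %in% c("Fp1", "Fp2"))
  proxy <- if (length(fp)) colMeans(x[fp, , drop = FALSE]) else colMeans(x)

  k <- nrow(ica$sources)
  blink_cor <- vapply(seq_len(k), function(i) {
    abs(stats::cor(ica$sources[i, ], proxy))
  }, numeric(1))
  kurt <- vapply(seq_len(k), function(i) {
    s <- ica$sources[i, ]
    m2 <- mean((s - mean(s))^2)
    mean((s - mean(s))^4) / m2^2
  }, numeric(1))

  flagged <- which(blink_cor >= criteria$blink_cor |
                     abs(kurt) >= criteria$kurtosis)
  ica$rejected <- flagged
  ica$rejection_scores <- data.frame(component = seq_len(k),
                                     blink_cor = blink_cor, kurtosis = kurt)
  ica
}

#' Reconstruct channel data from an ICA fit
#'
#' @param ica An `ica_result`.
#' @param rejected Component indices to drop; defaults to `ica$rejected`.
#' @return A channels x samples matrix with the rejected components removed.
#' @export
ica_reconstruct <- function(ica, rejected = ica$rejected) {
  keep <- setdiff(seq_len(nrow(ica$sources)), rejected)
  out <- ica$mixing[, keep, drop = FALSE] %*%
    ica$sources[keep, , drop = FALSE] + ica$means
  rownames(out) <- ica$channel_names
  out
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> %d components, %d rejected (%s after %d iter)\n",
              nrow(x$sources), length(x$rejected),
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$n_iter))
  invisible(x)
}
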