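#' Artifact content of a synthetic recording
#'
#' Rates and amplitudes of the stereotyped artifact processes mixed into
#' generated EEG: ocular blinks, 50 Hz power-line interference, brief
#' temporalis muscle bursts, and sub-0.1 Hz electrode drift.
#'
#' @param blink_rate Blink events per minute.
#' @param line_noise_amp Power-line (50 Hz) amplitude in uV.
#' @param muscle_burst_rate Muscle burst events per minute.
#' @param drift_amp Amplitude of slow (< 0.1 Hz) drift in uV.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(blink_rate = 12, line_noise_amp = 2,
                          muscle_burst_rate = 3, drift_amp = 10) {
  vals <- c(blink_rate, line_noise_amp, muscle_burst_rate, drift_amp)
  if (any(vals < 0)) stop("artifact rates/amplitudes must be >= 0", call. = FALSE)
  structure(list(blink_rate = blink_rate, line_noise_amp = line_noise_amp,
                 muscle_burst_rate = muscle_burst_rate, drift_amp = drift_amp),
            class = "artifact_spec")
}

#' Acquisition parameters of a synthetic recording
#'
#' Defaults mirror the acquisition protocol the classifier assumes:
#' 19-channel 10-20 EEG at 500 Hz, 10 minutes per resting-state condition
#' (eyes open and eyes closed), recorded before and after the treatment
#' course.
#'
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param duration Seconds of signal per condition (default 600).
#' @param conditions Conditions to generate per session.
#' @param artifacts An [artifact_spec()].
#' @param session_effect Relative increase of alpha-band amplitude in the
#'   post-treatment session (0 = no pre/post difference).
#' @param background_rms RMS of the 1/f background process, uV.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(sampling_rate = 500, duration = 600,
                           conditions = c("eyes_closed", "eyes_open"),
                           artifacts = artifact_spec(),
                           session_effect = 0.2,
                           background_rms = 15) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-9) {
    stop("duration x sampling_rate must be an integer sample count",
         call. = FALSE)
  }
  conditions <- match.arg(conditions, c("eyes_closed", "eyes_open"),
                          several.ok = TRUE)
  stopifnot(inherits(artifacts, "artifact_spec"))
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 conditions = conditions, artifacts = artifacts,
                 session_effect = session_effect,
                 background_rms = background_rms),
            class = "recording_spec")
}

#' Per-subject simulation profile
#'
#' @param subject_id Identifier string.
#' @param sex `"female"` or `"male"`.
#' @param bdi_pre,bdi_post Non-negative integer BDI-II scores before/after
#'   treatment. `bdi_pre` must be positive (a depressed cohort).
#' @param true_class_effect Effect size injected into the subject's spectra:
#'   the subject's alpha-band amplitude is scaled by `1 + true_class_effect`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, sex = c("female", "male"),
                            bdi_pre = 30L, bdi_post = 15L,
                            true_class_effect = 0) {
  sex <- match.arg(sex)
  if (bdi_pre <= 0) stop("bdi_pre must be > 0", call. = FALSE)
  if (bdi_post < 0) stop("bdi_post must be >= 0", call. = FALSE)
  structure(list(subject_id = subject_id, sex = sex,
                 bdi_pre = as.integer(bdi_pre),
                 bdi_post = as.integer(bdi_post),
                 true_class_effect = true_class_effect),
            class = "subject_profile")
}

# Fixed spatial weight tables for the 10-20 montage, montage order:
# Fp1 Fp2 F7 F3 Fz F4 F8 T3 C3 Cz C4 T4 T5 P3 Pz P4 T6 O1 O2
.alpha_weights <- c(0.30, 0.30, 0.35, 0.35, 0.35, 0.35, 0.35,
                    0.50, 0.45, 0.45, 0.45, 0.50,
                    0.70, 0.80, 0.80, 0.80, 0.70, 1.00, 1.00)
.left_channels <- c(1, 3, 4, 8, 9, 13, 14, 18)    # Fp1 F7 F3 T3 C3 T5 P3 O1
.right_channels <- c(2, 6, 7, 11, 12, 16, 17, 19) # Fp2 F4 F8 C4 T4 P4 T6 O2
.blink_weights <- c(1.00, 1.00, 0.40, 0.40, 0.35, 0.40, 0.40,
                    0.10, 0.15, 0.12, 0.15, 0.10,
                    0.05, 0.05, 0.05, 0.05, 0.05, 0.03, 0.03)
.muscle_weights <- c(0.15, 0.15, 0.80, 0.20, 0.10, 0.20, 0.80,
                     1.00, 0.15, 0.10, 0.15, 1.00,
                     0.60, 0.10, 0.05, 0.10, 0.60, 0.20, 0.20)

# 1/f ("pink") noise via spectral shaping of white noise; unit RMS.
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  fw <- stats::fft(w)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  scale <- 1 / sqrt(pmax(freq, 0.5))  # 0.5 Hz knee avoids DC blow-up
  scale[1] <- 0
  x <- Re(stats::fft(fw * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slowly varying non-negative amplitude envelope, mean ~1.
slow_envelope <- function(n, fs, cutoff = 0.5) {
  m <- max(16L, 2L * ceiling(n * cutoff / fs))
  ctrl <- stats::rnorm(m)
  env <- 1 + 0.4 * stats::approx(seq(0, 1, length.out = m), ctrl,
                                 xout = seq(0, 1, length.out = n))$y
  pmax(env, 0.05)
}

#' Generate one synthetic EEG recording
#'
#' Simulates a 19-channel resting-state EEG as the sum of spatially
#' correlated 1/f background noise, a posterior-dominant amplitude-modulated
#' alpha (10 Hz) rhythm carrying the class-conditional and session effects,
#' and the artifact processes configured in the [artifact_spec()]:
#' frontal-dominant blink transients, temporal muscle bursts, 50 Hz line
#' interference and slow drift. Deterministic given `seed`.
#'
#' The subject's `true_class_effect` scales alpha amplitude by
#' `1 + true_class_effect`; the post session scales it further by
#' `1 + session_effect`. Eyes-closed recordings have 2.5x the eyes-open
#' alpha amplitude, mimicking the Berger effect.
#'
#' @param profile A [subject_profile()].
#' @param spec A [recording_spec()].
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param session `"pre"` or `"post"`.
#' @param condition `"eyes_closed"` or `"eyes_open"`.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' rec <- generate_recording(subject_profile("S01"),
#'                           recording_spec(duration = 2), seed = 1)
#' dim(rec$data)
generate_recording <- function(profile, spec, seed,
                               session = c("pre", "post"),
                               condition = c("eyes_closed", "eyes_open")) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(spec, "recording_spec"))
  session <- match.arg(session)
  condition <- match.arg(condition)
  fs <- spec$sampling_rate
  n <- as.integer(round(spec$duration * fs))
  nch <- 19L
  art <- spec$artifacts

  with_seed(seed, {
    t <- seq_len(n) / fs

    # spatially correlated pink background: fixed neighbour-decay mixing
    latent <- matrix(0, nch, n)
    for (i in seq_len(nch)) latent[i, ] <- pink_noise(n, fs)
    mix <- exp(-abs(outer(seq_len(nch), seq_len(nch), "-")) / 4)
    mix <- mix / sqrt(rowSums(mix^2))
    x <- (mix %*% latent) * spec$background_rms

    # alpha rhythm with class/session/condition amplitude structure; the
    # class effect enters both as a band-power offset (amplitude scaling)
    # and as a frontal alpha-asymmetry offset (left up, right down)
    alpha_base <- if (condition == "eyes_closed") 10 else 4
    eff <- profile$true_class_effect
    amp <- alpha_base * (1 + eff) *
      (if (session == "post") 1 + spec$session_effect else 1)
    w_alpha <- .alpha_weights
    asym <- 1 + 0.5 * eff
    w_alpha[.left_channels] <- w_alpha[.left_channels] * asym
    w_alpha[.right_channels] <- w_alpha[.right_channels] / asym
    env <- slow_envelope(n, fs)
    # ~10 Hz carrier with slow frequency jitter (+/- ~0.5 Hz), so alpha is
    # not phase-locked across the recording as a pure sinusoid would be
    inst_freq <- 10 + 0.5 * (slow_envelope(n, fs, cutoff = 0.2) - 1) / 0.4
    phase <- stats::runif(1, 0, 2 * pi) + 2 * pi * cumsum(inst_freq) / fs
    carrier <- sin(phase) * env
    x <- x + amp * w_alpha %o% carrier

    # ocular blinks: ~350 ms raised-cosine transients, frontal-dominant
    n_blinks <- stats::rpois(1, art$blink_rate * spec$duration / 60)
    if (n_blinks > 0 && art$blink_rate > 0) {
      blink_len <- round(0.35 * fs)
      template <- 120 * sin(pi * seq_len(blink_len) / blink_len)^2
      onsets <- sort(sample.int(max(n - blink_len, 1L), n_blinks,
                                replace = TRUE))
      blink_tr <- numeric(n)
      for (o in onsets) {
        idx <- o:min(o + blink_len - 1L, n)
        blink_tr[idx] <- blink_tr[idx] + template[seq_along(idx)]
      }
      x <- x + .blink_weights %o% blink_tr
    }

    # muscle bursts: 500 ms broadband noise at temporal sites
    n_bursts <- stats::rpois(1, art$muscle_burst_rate * spec$duration / 60)
    if (n_bursts > 0 && art$muscle_burst_rate > 0) {
      burst_len <- round(0.5 * fs)
      for (k in seq_len(n_bursts)) {
        o <- sample.int(max(n - burst_len, 1L), 1)
        idx <- o:min(o + burst_len - 1L, n)
        taper <- sin(pi * seq_along(idx) / length(idx))
        burst <- 25 * stats::rnorm(length(idx)) * taper
        x[, idx] <- x[, idx] + .muscle_weights %o% burst
      }
    }

    # 50 Hz line interference, near-common phase across channels
    if (art$line_noise_amp > 0) {
      phi <- stats::runif(1, 0, 2 * pi) + stats::rnorm(nch, sd = 0.05)
      line <- art$line_noise_amp *
        sin(outer(phi, 2 * pi * 50 * t, "+"))
      x <- x + line
    }

    # slow electrode drift (< 0.1 Hz sinusoids, random per channel)
    if (art$drift_amp > 0) {
      f_drift <- stats::runif(nch, 0.02, 0.08)
      ph_drift <- stats::runif(nch, 0, 2 * pi)
      scale_drift <- art$drift_amp * stats::runif(nch, 0.3, 1)
      for (i in seq_len(nch)) {
        x[i, ] <- x[i, ] + scale_drift[i] * sin(2 * pi * f_drift[i] * t +
                                                  ph_drift[i])
      }
    }

    eeg_recording(x, fs, montage_1020(), profile$subject_id,
                  session, condition)
  })
}

# Group means/SDs of BDI-II used to draw synthetic scores (per sex x response).
bdi_group_defaults <- function() {
  list(
    male = list(responder = c(pre_mean = 30.66, pre_sd = 7.79,
                              post_mean = 7.94, post_sd = 5.43),
                nonresponder = c(pre_mean = 35.42, pre_sd = 9.12,
                                 post_mean = 27.14, post_sd = 7.98)),
    female = list(responder = c(pre_mean = 30.45, pre_sd = 8.46,
                                post_mean = 8.36, post_sd = 5.46),
                  nonresponder = c(pre_mean = 32.64, pre_sd = 7.73,
                                   post_mean = 20.00, post_sd = 4.94))
  )
}

# Draw integer BDI pre/post consistent with the intended response label:
# responder iff post <= pre/2 (the >= 50% reduction rule, exactly).
draw_bdi <- function(sex, responder, params = bdi_group_defaults()) {
  g <- params[[sex]][[if (responder) "responder" else "nonresponder"]]
  pre <- max(2L, as.integer(round(stats::rnorm(1, g["pre_mean"], g["pre_sd"]))))
  post <- as.integer(round(stats::rnorm(1, g["post_mean"], g["post_sd"])))
  half <- floor(pre / 2)
  post <- if (responder) max(0L, min(post, half)) else max(post, half + 1L)
  c(pre = pre, post = post)
}

#' Generate a synthetic cohort
#'
#' Draws subject profiles (sex, BDI-II scores, injected spectral effect) and
#' generates one recording per subject x session x condition. BDI-II post
#' scores are drawn so that exactly the intended subjects satisfy the
#' treatment-response rule (>= 50% BDI reduction). Responders carry
#' `true_class_effect = class_effect`; nonresponders carry 0.
#'
#' @param n_female,n_male Cohort sizes per sex.
#' @param responder_fraction Named numeric, fractions in \[0, 1\] for
#'   `female` and `male`; the number of responders per sex is
#'   `round(fraction * n)`.
#' @param spec A [recording_spec()].
#' @param seed Integer seed; the whole cohort is deterministic in it.
#' @param sessions Sessions to generate (default both `"pre"` and `"post"`).
#' @param class_effect Alpha-amplitude effect size separating responders
#'   from nonresponders (0 = null cohort with no class signal).
#' @param bdi_params Group means/SDs for BDI draws, see [bdi_group_defaults()].
#' @param out_dir If non-NULL, recordings are written as EDF files to this
#'   directory (plus `metadata.csv`) instead of being returned in memory.
#' @return A list with `subjects` (data frame: subject_id, sex, responder,
#'   bdi_pre, bdi_post, true_class_effect), `index` (one row per recording:
#'   subject_id, session, condition, and `file` when `out_dir` is used), and
#'   `recordings` (list of [eeg_recording()], `NULL` when `out_dir` is used).
#' @export
generate_cohort <- function(n_female = 25, n_male = 25,
                            responder_fraction = c(female = 11 / 25,
                                                   male = 18 / 25),
                            spec = recording_spec(), seed = 1,
                            sessions = c("pre", "post"),
                            class_effect = 0,
                            bdi_params = bdi_group_defaults(),
                            out_dir = NULL) {
  if (n_female + n_male <= 0) stop("cohort size must be positive", call. = FALSE)
  if (n_female < 0 || n_male < 0) stop("negative cohort size", call. = FALSE)
  if (any(responder_fraction < 0 | responder_fraction > 1)) {
    stop("responder fractions must lie in [0, 1]", call. = FALSE)
  }
  sessions <- match.arg(sessions, c("pre", "post"), several.ok = TRUE)

  subjects <- with_seed(seed, {
    sex <- c(rep("female", n_female), rep("male", n_male))
    ids <- sprintf("S%02d", seq_along(sex))
    responder <- logical(length(sex))
    for (s in c("female", "male")) {
      is_s <- which(sex == s)
      k <- round(responder_fraction[[s]] * length(is_s))
      if (k > 0) responder[sample(is_s, k)] <- TRUE
    }
    bdi <- t(vapply(seq_along(sex),
                    function(i) draw_bdi(sex[i], responder[i], bdi_params),
                    numeric(2)))
    data.frame(subject_id = ids, sex = sex, responder = responder,
               bdi_pre = as.integer(bdi[, "pre"]),
               bdi_post = as.integer(bdi[, "post"]),
               true_class_effect = ifelse(responder, class_effect, 0),
               stringsAsFactors = FALSE)
  })

  grid <- expand.grid(condition = spec$conditions, session = sessions,
                      subject_id = subjects$subject_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("subject_id", "session", "condition")]

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  recordings <- if (is.null(out_dir)) vector("list", nrow(grid)) else NULL
  files <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    subj <- subjects[subjects$subject_id == grid$subject_id[r], ]
    prof <- subject_profile(subj$subject_id, subj$sex, subj$bdi_pre,
                            subj$bdi_post, subj$true_class_effect)
    rec_seed <- seed + r * 1009L
    rec <- generate_recording(prof, spec, rec_seed,
                              session = grid$session[r],
                              condition = grid$condition[r])
    if (is.null(out_dir)) {
      recordings[[r]] <- rec
    } else {
      f <- file.path(out_dir, sprintf("%s_%s_%s.edf", subj$subject_id,
                                      grid$session[r], grid$condition[r]))
      write_edf(rec, f)
      files[r] <- f
    }
  }
  index <- grid
  if (!is.null(out_dir)) {
    index$file <- files
    meta <- merge(index, subjects, by = "subject_id", sort = FALSE)
    utils::write.csv(
      meta[, c("subject_id", "sex", "session", "condition",
               "bdi_pre", "bdi_post", "file")],
      file.path(out_dir, "metadata.csv"), row.names = FALSE)
  }
  list(subjects = subjects, index = index, recordings = recordings)
}
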