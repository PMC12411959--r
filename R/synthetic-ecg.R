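#' Morphology and rhythm configuration for the synthetic ECG generator
#'
#' Collects the rhythm and waveform parameters used when scheduling and
#' rendering synthetic beat-annotated records. Class-dependent structure
#' follows the three AAMI-style beat classes: ventricular ectopic (V) beats
#' carry a widened QRS and, by default, no P wave; supraventricular ectopic
#' (S) beats are premature, shortening the RR interval that precedes them.
#'
#' @param fs Sampling rate in Hz.
#' @param mean_rr Mean RR interval in seconds for normal rhythm.
#' @param rr_jitter Fractional standard deviation of multiplicative RR noise.
#' @param s_prematurity Fraction by which an S beat shortens its preceding RR
#'   interval (in (0, 1)).
#' @param v_qrs_widen Multiplicative QRS-width factor for V beats (> 1).
#' @param p_noP Probability that a V beat has no P annotation.
#' @param noise_sd Standard deviation of additive Gaussian baseline noise.
#' @param p_width,qrs_width,t_width Nominal segment widths in seconds.
#' @param p_amp,qrs_amp,t_amp Segment template amplitudes (arbitrary units).
#' @param v_amp_scale Amplitude scale applied to the QRS of V beats.
#' @param pr_gap Gap between P offset and QRS onset, seconds.
#' @param st_gap Gap between QRS offset and T onset, seconds.
#' @param width_jitter Fractional sd of per-beat multiplicative width noise.
#' @return An object of class `morphology_config`.
#' @export
morphology_config <- function(fs = 250, mean_rr = 0.8, rr_jitter = 0.04,
                              s_prematurity = 0.35, v_qrs_widen = 1.8,
                              p_noP = 1.0, noise_sd = 0.02,
                              p_width = 0.10, qrs_width = 0.08, t_width = 0.16,
                              p_amp = 0.15, qrs_amp = 1.0, t_amp = 0.30,
                              v_amp_scale = 1.2,
                              pr_gap = 0.04, st_gap = 0.09,
                              width_jitter = 0.05) {
  if (fs <= 0) stopf("fs must be positive")
  if (s_prematurity <= 0 || s_prematurity >= 1)
    stopf("s_prematurity must be in (0, 1)")
  if (v_qrs_widen <= 1) stopf("v_qrs_widen must be > 1")
  structure(list(
    fs = fs, mean_rr = mean_rr, rr_jitter = rr_jitter,
    s_prematurity = s_prematurity, v_qrs_widen = v_qrs_widen,
    p_noP = p_noP, noise_sd = noise_sd,
    p_width = p_width, qrs_width = qrs_width, t_width = t_width,
    p_amp = p_amp, qrs_amp = qrs_amp, t_amp = t_amp,
    v_amp_scale = v_amp_scale,
    pr_gap = pr_gap, st_gap = st_gap, width_jitter = width_jitter
  ), class = "morphology_config")
}

# Record duration (s) of a standard window, and the margin a beat needs
# before/after its R peak so every segment fits inside the record.
RECORD_DUR <- 10

beat_margins <- function(morph, widen = 1) {
  qw <- morph$qrs_width * widen / 2
  pre <- qw + morph$pr_gap + morph$p_width
  post <- qw + morph$st_gap + morph$t_width
  c(pre = pre, post = post)
}

#' Schedule beats for a synthetic record from a class pattern
#'
#' Lays out R-peak times and per-beat P/QRS/T segment boundaries (in seconds)
#' for a beat-class pattern such as `"NNNNSSSS"`. S beats shorten their
#' preceding RR interval by `s_prematurity`; V beats get a widened QRS and,
#' with probability `p_noP`, no P segment. The schedule is truncated to the
#' beats that fit completely inside a 10-second record.
#'
#' @param pattern Non-empty string over the alphabet `N`, `S`, `V`.
#' @param morph A [morphology_config()].
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return An object of class `beat_schedule` with fields `beat_classes`,
#'   `r_times` and `segment_bounds` (per beat, a named list of
#'   `c(onset, offset)` pairs in seconds; absent segments are missing).
#' @export
generate_beat_schedule <- function(pattern, morph = morphology_config(),
                                   seed = NULL) {
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern))
    stopf("pattern must be a non-empty string over {N,S,V}")
  classes <- strsplit(pattern, "")[[1]]
  if (!all(classes %in% BEAT_CLASSES))
    stopf("invalid beat class in pattern '%s': allowed characters are N, S, V",
          pattern)
  with_seed_(seed, schedule_beats(classes, morph))
}

schedule_beats <- function(classes, morph) {
  n <- length(classes)
  # widest possible beat bounds the minimal safe RR
  marg_wide <- beat_margins(morph, morph$v_qrs_widen * (1 + 3 * morph$width_jitter))
  min_rr <- marg_wide[["pre"]] + marg_wide[["post"]] + 0.02

  rr <- if (n > 1) {
    g <- morph$mean_rr * exp(stats::rnorm(n - 1, 0, morph$rr_jitter))
    prem <- classes[-1] == "S"
    g[prem] <- g[prem] * (1 - morph$s_prematurity)
    pmax(g, min_rr)
  } else numeric(0)

  t0 <- marg_wide[["pre"]] + 0.02
  r_times <- t0 + cumsum(c(0, rr))

  bounds <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    wj <- exp(stats::rnorm(3, 0, morph$width_jitter))
    qw <- morph$qrs_width * wj[1] * if (cls == "V") morph$v_qrs_widen else 1
    pw <- morph$p_width * wj[2]
    tw <- morph$t_width * wj[3]
    r <- r_times[i]
    seg <- list(QRS = c(r - qw / 2, r + qw / 2))
    has_p <- !(cls == "V" && stats::runif(1) < morph$p_noP)
    if (has_p)
      seg$P <- c(r - qw / 2 - morph$pr_gap - pw, r - qw / 2 - morph$pr_gap)
    seg$T <- c(r + qw / 2 + morph$st_gap, r + qw / 2 + morph$st_gap + tw)
    bounds[[i]] <- seg
  }

  # truncate to complete beats inside the record
  last_off <- vapply(bounds, function(s) s$T[2], numeric(1))
  keep <- which(last_off <= RECORD_DUR - 0.01)
  keep <- if (length(keep)) seq_len(max(keep)) else integer(0)
  if (!length(keep)) stopf("no complete beat fits inside the record")

  structure(list(
    beat_classes = classes[keep],
    r_times = r_times[keep],
    segment_bounds = bounds[keep]
  ), class = "beat_schedule")
}

# Smooth unimodal bump for P and T; sharp biphasic deflection for QRS.
segment_template <- function(type, t, onset, offset, amp) {
  mid <- (onset + offset) / 2
  w <- offset - onset
  if (type == "QRS") {
    amp * (exp(-((t - mid) / (w / 7))^2) -
             0.5 * exp(-((t - (mid + w / 4)) / (w / 5))^2))
  } else {
    amp * exp(-((t - mid) / (w / 5))^2)
  }
}

#' Render a scheduled set of beats into an annotated waveform record
#'
#' Synthesises the waveform as a sum of per-segment templates (Gaussian bumps
#' for P and T, a biphasic difference-of-Gaussians for QRS) plus Gaussian
#' baseline noise, and emits sample-index annotations (0-based, half-open)
#' exactly where templates were placed.
#'
#' @param schedule A `beat_schedule`.
#' @param morph A [morphology_config()].
#' @param seed Optional integer seed for the noise.
#' @param patient_id,record_id Provenance identifiers.
#' @return An object of class `ecg_record` with fields `patient_id`,
#'   `record_id`, `fs`, `samples` and `beats` (per beat: `class` and
#'   `segments`, a named list of 0-based half-open `c(onset, offset)` sample
#'   index pairs).
#' @export
render_record <- function(schedule, morph = morphology_config(), seed = NULL,
                          patient_id = "p1", record_id = "r1") {
  stopifnot(inherits(schedule, "beat_schedule"))
  fs <- morph$fs
  n_samp <- round(RECORD_DUR * fs)
  with_seed_(seed, {
    samples <- stats::rnorm(n_samp, 0, morph$noise_sd)
    tgrid <- (seq_len(n_samp) - 1) / fs
    beats <- vector("list", length(schedule$beat_classes))
    for (b in seq_along(beats)) {
      cls <- schedule$beat_classes[b]
      segs <- list()
      for (type in SEGMENT_TYPES) {
        bd <- schedule$segment_bounds[[b]][[type]]
        if (is.null(bd)) next
        on_i <- max(0L, as.integer(round(bd[1] * fs)))
        off_i <- min(n_samp, as.integer(round(bd[2] * fs)))
        if (off_i - on_i < 2L) off_i <- min(n_samp, on_i + 2L)
        amp <- switch(type, P = morph$p_amp, T = morph$t_amp,
                      QRS = morph$qrs_amp *
                        if (cls == "V") morph$v_amp_scale else 1)
        idx <- (on_i + 1L):off_i
        samples[idx] <- samples[idx] +
          segment_template(type, tgrid[idx], bd[1], bd[2], amp)
        segs[[type]] <- c(on_i, off_i)
      }
      beats[[b]] <- list(class = cls, segments = segs)
    }
    rec <- structure(list(
      patient_id = patient_id, record_id = record_id,
      fs = fs, samples = samples, beats = beats
    ), class = "ecg_record")
    validate_record(rec)
    rec
  })
}

#' Generate a synthetic beat-annotated ECG dataset
#'
#' Produces `n_patients * records_per_patient` 10-second records. Beat classes
#' are either drawn to track a target N/S/V mixture (a deficit-proportional
#' sampler keeps realised proportions within a fraction of a percentage point
#' of the target over a few hundred beats) or forced by explicit `pattern`
#' strings. One master seed drives per-patient child seeds, so the dataset is
#' fully reproducible and patient subsets are independently reproducible.
#'
#' @param n_patients Number of patients.
#' @param records_per_patient Records per patient.
#' @param class_mix Named or ordered length-3 numeric, target proportions of
#'   N, S, V; must sum to 1 (small numerical slack allowed).
#' @param seed Integer master seed.
#' @param morph A [morphology_config()].
#' @param pattern Optional character vector of explicit beat patterns,
#'   recycled across records; overrides `class_mix`.
#' @param beats_range Integer length-2, range of beats per record requested
#'   before 10-second truncation (ignored when `pattern` is given).
#' @return A list of `ecg_record` objects (class `ecg_dataset`).
#' @export
generate_dataset <- function(n_patients, records_per_patient,
                             class_mix = c(N = 0.75, S = 0.152, V = 0.104),
                             seed = 1, morph = morphology_config(),
                             pattern = NULL, beats_range = NULL) {
  class_mix <- class_mix / sum(class_mix)
  if (length(class_mix) != 3 || any(class_mix < 0))
    stopf("class_mix must be 3 non-negative proportions")
  names(class_mix) <- BEAT_CLASSES

  max_beats <- max(2L, floor((RECORD_DUR - 0.6) / morph$mean_rr) + 1L)
  if (is.null(beats_range)) beats_range <- c(max(4L, max_beats - 4L), max_beats)

  counts <- c(N = 0, S = 0, V = 0)
  records <- vector("list", n_patients * records_per_patient)
  k <- 0L
  for (p in seq_len(n_patients)) {
    pseed <- child_seed(seed, p)
    with_seed_(pseed, {
      for (r in seq_len(records_per_patient)) {
        if (!is.null(pattern)) {
          pat <- pattern[(k %% length(pattern)) + 1L]
          classes <- strsplit(pat, "")[[1]]
        } else {
          nb <- sample(beats_range[1]:beats_range[2], 1)
          classes <- character(nb)
          for (b in seq_len(nb)) {
            tot <- sum(counts)
            pr <- pmax(class_mix * (tot + 1) - counts, 1e-3)
            classes[b] <- sample(BEAT_CLASSES, 1, prob = pr)
            counts[classes[b]] <- counts[classes[b]] + 1
          }
        }
        sched <- schedule_beats(classes, morph)
        k <- k + 1L
        records[[k]] <- render_record(
          sched, morph,
          patient_id = sprintf("p%03d", p),
          record_id = sprintf("p%03d_r%03d", p, r))
      }
    })
  }
  structure(records[seq_len(k)], class = "ecg_dataset")
}

#' Generate a synthetic dataset for the scalability verification protocol
#'
#' Emulates the data layout the pattern/size scalability experiments need:
#' training-side patients own only 8-beat records whose minority (S/V) beats
#' are scattered (runs of at most 3), while test-side patients own
#' qualifying 8-beat pattern records (>= 1 N beat and >= 4 consecutive S or
#' V beats, e.g. `NNNNSSSS`), control 8-beat records with scattered
#' minorities, and larger records (`size_beats` beats). Patient group
#' membership is therefore recoverable from the data alone by
#' [scalability_splits()].
#'
#' @param n_train_patients,n_test_patients Patients per group.
#' @param records_per_patient Records per training patient; each test
#'   patient owns `records_per_patient` records split evenly across
#'   pattern/control/size roles.
#' @param class_mix Target N/S/V mixture of scattered records.
#' @param size_beats Beat count of the Size-set records.
#' @param seed Integer master seed.
#' @param morph A [morphology_config()].
#' @return A list of `ecg_record` (class `ecg_dataset`).
#' @export
generate_scalability_dataset <- function(n_train_patients = 20,
                                         n_test_patients = 8,
                                         records_per_patient = 6,
                                         class_mix = c(N = 0.75, S = 0.152,
                                                       V = 0.104),
                                         size_beats = 11, seed = 1,
                                         morph = morphology_config()) {
  class_mix <- class_mix / sum(class_mix)
  scattered <- function(n) {
    repeat {
      cls <- sample(BEAT_CLASSES, n, replace = TRUE, prob = class_mix)
      runs <- rle(cls %in% c("S", "V"))
      if (!any(runs$lengths[runs$values] >= 4)) return(paste(cls, collapse = ""))
    }
  }
  qualifying <- function() {
    run_len <- sample(4:6, 1)
    run_cls <- sample(c("S", "V"), 1)
    cls <- rep("N", 8)
    at <- sample(seq_len(8 - run_len + 1), 1)
    cls[at:(at + run_len - 1)] <- run_cls
    paste(cls, collapse = "")
  }

  train_pat <- with_seed_(child_seed(seed, 1), {
    vapply(seq_len(n_train_patients * records_per_patient),
           function(i) scattered(8), character(1))
  })
  train <- generate_dataset(n_train_patients, records_per_patient,
                            seed = child_seed(seed, 2), morph = morph,
                            pattern = train_pat)

  per_role <- max(1L, records_per_patient %/% 3L)
  test_pat <- with_seed_(child_seed(seed, 3), {
    unlist(lapply(seq_len(n_test_patients), function(p) c(
      vapply(seq_len(per_role), function(i) qualifying(), character(1)),
      vapply(seq_len(per_role), function(i) scattered(8), character(1)),
      vapply(seq_len(per_role), function(i) scattered(size_beats),
             character(1))
    )))
  })
  test <- generate_dataset(n_test_patients, 3L * per_role,
                           seed = child_seed(seed, 4), morph = morph,
                           pattern = test_pat)
  for (i in seq_along(test)) {
    test[[i]]$patient_id <- sub("^p", "q", test[[i]]$patient_id)
    test[[i]]$record_id <- sub("^p", "q", test[[i]]$record_id)
  }
  structure(c(train, test), class = "ecg_dataset")
}

#' Beat-class labels of a record or dataset
#'
#' @param x An `ecg_record` or list of records.
#' @return Character vector (record) or list of character vectors (dataset).
#' @export
beat_labels <- function(x) {
  if (inherits(x, "ecg_record"))
    return(vapply(x$beats, function(b) b$class, character(1)))
  lapply(x, beat_labels)
}
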