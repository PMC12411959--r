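#' Validate an annotated ECG record
#'
#' Checks the structural invariants of an `ecg_record`: sampling rate and
#' samples present, beat classes in {N,S,V}, every beat carrying exactly one
#' QRS annotation, all annotations 0-based half-open with onset < offset,
#' sorted chronologically and non-overlapping, and indices within the signal.
#'
#' @param record An `ecg_record`.
#' @return The record, invisibly; violations raise an error naming the
#'   offending beat.
#' @export
validate_record <- function(record) {
  if (!is.list(record) || is.null(record$fs) || is.null(record$samples) ||
      is.null(record$beats))
    stopf("not an annotated ECG record (fs, samples, beats required)")
  if (record$fs <= 0) stopf("fs must be positive")
  n <- length(record$samples)
  prev_off <- -Inf
  prev_onset <- -Inf
  for (b in seq_along(record$beats)) {
    beat <- record$beats[[b]]
    if (!beat$class %in% BEAT_CLASSES)
      stopf("beat %d: invalid class '%s'", b, beat$class)
    segs <- beat$segments
    if (is.null(segs[["QRS"]]))
      stopf("beat %d: missing QRS annotation", b)
    bad <- setdiff(names(segs), SEGMENT_TYPES)
    if (length(bad)) stopf("beat %d: unknown segment type '%s'", b, bad[1])
    for (type in intersect(SEGMENT_TYPES, names(segs))) {
      sg <- segs[[type]]
      if (length(sg) != 2 || sg[1] >= sg[2])
        stopf("beat %d: segment %s must satisfy onset < offset", b, type)
      if (sg[1] < 0 || sg[2] > n)
        stopf("beat %d: segment %s outside signal [0, %d)", b, type, n)
      if (sg[1] < prev_off)
        stopf("beat %d: segment %s overlaps the preceding segment", b, type)
      if (sg[1] < prev_onset)
        stopf("beat %d: segments out of chronological order", b)
      prev_off <- sg[2]
      prev_onset <- sg[1]
    }
  }
  invisible(record)
}

#' Write / read an annotated ECG record in the CSV+JSON on-disk format
#'
#' A record is stored as two files in `dir`: `signal.csv` with columns
#' `sample_index,value`, and `annotations.json` holding `patient_id`,
#' `record_id`, `fs` and the per-beat class and segment index ranges
#' (0-based, half-open). The JSON layout is described by the schema shipped
#' at `system.file("extdata", "ecg-record-schema.json", package =
#' "ecgraphnet")`. Annotations round-trip exactly; samples round-trip to the
#' printed precision (10 significant digits).
#'
#' @param record An `ecg_record`.
#' @param dir Directory to write to (created if missing).
#' @return `write_record` returns the directory invisibly; `read_record`
#'   returns the validated `ecg_record`.
#' @export
write_record <- function(record, dir) {
  validate_record(record)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- data.frame(sample_index = seq_along(record$samples) - 1L,
                    value = sprintf("%.10g", record$samples))
  utils::write.csv(sig, file.path(dir, "signal.csv"),
                   row.names = FALSE, quote = FALSE)
  ann <- list(
    patient_id = record$patient_id,
    record_id = record$record_id,
    fs = record$fs,
    beats = lapply(record$beats, function(b) {
      list(class = b$class,
           segments = lapply(b$segments, function(sg) as.integer(sg)))
    })
  )
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_record
#' @export
read_record <- function(dir) {
  sig_path <- file.path(dir, "signal.csv")
  ann_path <- file.path(dir, "annotations.json")
  if (!file.exists(sig_path) || !file.exists(ann_path))
    stopf("'%s' does not contain signal.csv + annotations.json", dir)
  sig <- utils::read.csv(sig_path)
  if (!identical(names(sig), c("sample_index", "value")))
    stopf("signal.csv must have columns sample_index,value")
  ann <- jsonlite::read_json(ann_path)
  if (is.null(ann$fs) || is.null(ann$beats))
    stopf("annotations.json missing required fields (fs, beats)")
  beats <- lapply(ann$beats, function(b) {
    segs <- lapply(b$segments, function(sg) as.numeric(unlist(sg)))
    list(class = b$class, segments = segs)
  })
  rec <- structure(list(
    patient_id = ann$patient_id %||% "unknown",
    record_id = ann$record_id %||% basename(dir),
    fs = as.numeric(ann$fs),
    samples = as.numeric(sig$value),
    beats = beats
  ), class = "ecg_record")
  validate_record(rec)
  rec
}

#' Split a record into consecutive 10-second windows
#'
#' Beats are assigned to the window containing their QRS onset; segments are
#' clamped to the window. A short tail window is kept when it contains at
#' least one beat. The beat multiset is preserved: no beat is duplicated or
#' dropped.
#'
#' @param record An `ecg_record` of arbitrary duration.
#' @return A list of `ecg_record` windows (possibly empty).
#' @export
window_10s <- function(record) {
  validate_record(record)
  fs <- record$fs
  wlen <- as.integer(round(RECORD_DUR * fs))
  n <- length(record$samples)
  n_win <- ceiling(n / wlen)
  if (n_win == 0 || !length(record$beats)) return(list())
  qrs_on <- vapply(record$beats, function(b) b$segments$QRS[1], numeric(1))
  win_of <- pmin(floor(qrs_on / wlen), n_win - 1)
  out <- list()
  for (w in 0:(n_win - 1)) {
    ib <- which(win_of == w)
    if (!length(ib)) next
    lo <- w * wlen
    hi <- min(n, lo + wlen)
    beats <- lapply(record$beats[ib], function(b) {
      b$segments <- lapply(b$segments, function(sg) {
        sg2 <- pmin(pmax(sg - lo, 0), hi - lo)
        if (sg2[2] - sg2[1] < 1) return(NULL)
        sg2
      })
      b$segments <- Filter(Negate(is.null), b$segments)
      b
    })
    # a clamped-away P/T is dropped; QRS always survives (it defined membership)
    keep <- vapply(beats, function(b) !is.null(b$segments$QRS), logical(1))
    if (!any(keep)) next
    rec <- structure(list(
      patient_id = record$patient_id,
      record_id = sprintf("%s_w%02d", record$record_id, w + 1),
      fs = fs,
      samples = record$samples[(lo + 1):hi],
      beats = beats[keep]
    ), class = "ecg_record")
    out[[length(out) + 1]] <- rec
  }
  out
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s/%s: %.1f s @ %g Hz, %d beats (%s)>\n",
              x$patient_id, x$record_id, length(x$samples) / x$fs, x$fs,
              length(x$beats), paste(beat_labels(x), collapse = "")))
  invisible(x)
}
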