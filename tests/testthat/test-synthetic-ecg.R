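test_that("beat schedules follow the pattern and the prematurity rule", {
  morph <- morphology_config(mean_rr = 1.0, rr_jitter = 0)
  sch <- generate_beat_schedule("NNNNNNNN", morph, seed = 1)
  expect_length(sch$beat_classes, 8)
  expect_true(all(sch$beat_classes == "N"))
  expect_equal(diff(sch$r_times), rep(1.0, 7))

  morph2 <- morphology_config(mean_rr = 0.9, rr_jitter = 0,
                              s_prematurity = 0.3)
  sch2 <- generate_beat_schedule("NNSN", morph2, seed = 1)
  rr <- diff(sch2$r_times)
  # hand-applied rule: the RR preceding the S beat is shortened by 30%
  expect_equal(rr[2], 0.7 * 0.9, tolerance = 1e-12)
  expect_equal(rr[1], 0.9, tolerance = 1e-12)
  expect_equal(rr[3], 0.9, tolerance = 1e-12)
})

test_that("invalid patterns are rejected with explanatory errors", {
  expect_error(generate_beat_schedule(""), "non-empty")
  expect_error(generate_beat_schedule("NNXN"), "invalid beat class")
  expect_error(generate_beat_schedule(42), "non-empty")
})

test_that("rendered records have the declared length and sound annotations", {
  rec <- pattern_record("NNNNNN")
  expect_equal(length(rec$samples), 2500)  # 250 Hz x 10 s
  expect_silent(validate_record(rec))

  rec2 <- pattern_record("NVN")
  segs <- lapply(rec2$beats, `[[`, "segments")
  expect_null(segs[[2]]$P)              # V beat: no P annotation
  expect_false(is.null(segs[[1]]$P))
  qw <- vapply(segs, function(s) diff(s$QRS), numeric(1))
  expect_gt(qw[2], mean(qw[c(1, 3)]))   # widened V QRS
})

test_that("datasets track the target class mixture and are reproducible", {
  ds <- generate_dataset(20, 3, seed = 3)
  labs <- unlist(beat_labels(ds))
  expect_gt(length(labs), 500)
  props <- table(factor(labs, c("N", "S", "V"))) / length(labs)
  expect_true(abs(props[["N"]] - 0.75) < 0.03)
  expect_true(abs(props[["S"]] - 0.152) < 0.03)
  expect_true(abs(props[["V"]] - 0.104) < 0.03)

  ds2 <- generate_dataset(20, 3, seed = 3)
  expect_identical(ds, ds2)

  all_n <- generate_dataset(3, 2, class_mix = c(1, 0, 0), seed = 4)
  expect_true(all(unlist(beat_labels(all_n)) == "N"))
})

test_that("every generated record satisfies the annotation invariants", {
  ds <- c(fix_dataset(), generate_dataset(15, 4, seed = 77))
  for (rec in ds) {
    expect_silent(validate_record(rec))
    for (b in rec$beats) expect_true("QRS" %in% names(b$segments))
  }
})

test_that("class-conditional structure holds at the configured effect sizes", {
  ds <- generate_dataset(15, 4, seed = 8)
  qrs_w <- list(N = c(), V = c())
  rr_before <- list(N = c(), S = c())
  for (rec in ds) {
    labs <- beat_labels(rec)
    qon <- vapply(rec$beats, function(b) b$segments$QRS[1], numeric(1))
    w <- vapply(rec$beats, function(b) diff(b$segments$QRS), numeric(1))
    for (cl in c("N", "V"))
      qrs_w[[cl]] <- c(qrs_w[[cl]], w[labs == cl])
    if (length(labs) > 1) {
      rr <- diff(qon)
      for (cl in c("N", "S")) {
        sel <- which(labs[-1] == cl)
        rr_before[[cl]] <- c(rr_before[[cl]], rr[sel])
      }
    }
  }
  expect_gt(mean(qrs_w$V), 1.5 * mean(qrs_w$N))
  expect_lt(mean(rr_before$S), 0.8 * mean(rr_before$N))
})

test_that("the scalability dataset exposes recoverable patient groups", {
  ds <- generate_scalability_dataset(n_train_patients = 6,
                                     n_test_patients = 3, seed = 5)
  sp <- scalability_splits(ds)
  expect_length(sp$test_patients, 3)
  expect_length(sp$train_patients, 6)
  expect_true(all(lengths(beat_labels(sp$train8)) == 8))
  expect_true(all(lengths(beat_labels(sp$size)) >= 9))
  expect_identical(ds, generate_scalability_dataset(n_train_patients = 6,
                                                    n_test_patients = 3,
                                                    seed = 5))
})
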