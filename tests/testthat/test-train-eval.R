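test_that("interpatient folds partition patients near-equally", {
  ids <- sprintf("p%02d", 1:10)
  f <- interpatient_folds(ids, k = 5, seed = 2)
  expect_setequal(names(f), ids)
  expect_true(all(table(f) == 2))
  expect_identical(f, interpatient_folds(ids, k = 5, seed = 2))
  expect_error(interpatient_folds(ids[1:3], k = 5), "at least k")

  f2 <- interpatient_folds(sprintf("p%02d", 1:11), k = 5, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
})

test_that("beat metrics match the hand-built confusion matrix", {
  rep <- evaluate_beats(list(c("N", "S", "S", "V")),
                        list(c("N", "N", "S", "V")))
  expect_equal(rep$acc, 0.75)
  f1 <- setNames(rep$per_class$F1, rep$per_class$class)
  expect_equal(unname(f1), c(2 / 3, 2 / 3, 1))
  expect_equal(rep$macro_f1, 7 / 9)

  perfect <- evaluate_beats(list(c("N", "S", "V")), list(c("N", "S", "V")))
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_true(all(perfect$per_class$Sn == 1))

  # absent class: Sn undefined, dropped from the Macro F1 denominator
  rep2 <- evaluate_beats(list(c("N", "N")), list(c("N", "N")))
  expect_true(is.na(rep2$per_class$Sn[2]))
  expect_equal(rep2$macro_f1, 1)
  rep3 <- evaluate_beats(list(c("N", "S")), list(c("N", "N")),
                         absent = "zero")
  expect_equal(rep3$macro_f1, mean(c(2 / 3, 0, 0)))
})

test_that("metrics agree with a brute-force oracle on random vectors", {
  brute <- function(pred, lab) {
    cls <- c("N", "S", "V")
    f1 <- acc_n <- 0
    nf1 <- 0
    for (cl in cls) {
      tp <- sum(pred == cl & lab == cl)
      fp <- sum(pred == cl & lab != cl)
      fn <- sum(pred != cl & lab == cl)
      if (tp + fn > 0) { f1 <- f1 + 2 * tp / (2 * tp + fp + fn); nf1 <- nf1 + 1 }
    }
    c(acc = mean(pred == lab), macro = f1 / nf1)
  }
  set.seed(77)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    lab <- sample(c("N", "S", "V"), n, replace = TRUE,
                  prob = c(0.6, 0.25, 0.15))
    pred <- ifelse(runif(n) < 0.7, lab, sample(c("N", "S", "V"), n, TRUE))
    rep <- evaluate_beats(list(pred), list(lab))
    ref <- brute(pred, lab)
    expect_equal(rep$acc, unname(ref["acc"]))
    expect_equal(rep$macro_f1, unname(ref["macro"]))
  }
})

test_that("end exclusion drops exactly the first and last beat per graph", {
  # 3-beat graph: only the middle beat counts
  rep <- evaluate_beats(list(c("V", "S", "V")), list(c("N", "S", "N")),
                        exclude_ends = TRUE)
  expect_equal(rep$acc, 1)
  expect_equal(rep$n_beats, 1)

  # corrupting only end-beat labels leaves the end-excluded report unchanged
  labs <- list(c("N", "S", "V", "N"), c("N", "N", "S", "V", "N"))
  preds <- list(c("N", "S", "V", "N"), c("N", "N", "S", "S", "N"))
  base <- evaluate_beats(preds, labs, exclude_ends = TRUE)
  corrupted <- lapply(labs, function(l) {
    l[1] <- "V"; l[length(l)] <- "S"; l
  })
  rep2 <- evaluate_beats(preds, corrupted, exclude_ends = TRUE)
  expect_equal(rep2$per_class, base$per_class)
  expect_equal(rep2$acc, base$acc)
  expect_equal(rep2$macro_f1, base$macro_f1)
})

test_that("exact match counts whole graphs, honouring end exclusion", {
  labs <- list(c("N", "S", "N"), c("N", "V", "N"))
  expect_equal(exact_match(labs, labs), 1)
  preds <- list(c("N", "S", "N"), c("N", "N", "N"))  # one wrong interior
  expect_equal(exact_match(preds, labs), 0.5)
  preds_end <- list(c("S", "S", "N"), c("N", "V", "V"))  # wrong only at ends
  expect_equal(exact_match(preds_end, labs, exclude_ends = TRUE), 1)
  expect_equal(exact_match(preds_end, labs), 0)
})

test_that("soft voting averages member probabilities with the N<S<V tie rule", {
  m1 <- matrix(c(0.6, 0.3, 0.1), 1)
  m2 <- matrix(c(0.2, 0.5, 0.3), 1)
  avg <- ensemble_predict(probs = list(list(m1), list(m2)))[[1]]
  expect_equal(unname(avg), matrix(c(0.4, 0.4, 0.2), 1))
  cls <- ensemble_predict(probs = list(list(m1), list(m2)), type = "class")
  expect_equal(cls[[1]], "N")      # 0.4 tie between N and S -> N
  expect_equal(rowSums(avg), 1)

  # identical members reproduce a single member
  one <- ensemble_predict(probs = list(list(m1), list(m1)))[[1]]
  expect_equal(unname(one), m1)
  expect_error(ensemble_predict(probs = list(list(m1),
                                             list(rbind(m1, m1)))),
               "beat count")
})

test_that("early stopping halts after `patience` non-improving epochs", {
  graphs <- fix_graphs()[1:10]
  # zero learning rate: the monitored loss is flat after the first epoch
  fit <- graphnet_fit(graphs, graphnet_config(ch_pqrst = c(8, 8),
                                              ch_qrs = c(8, 8), fc = 8),
                      seed = 4, lr = 0, max_epochs = 50, patience = 3,
                      min_epochs = 0)
  expect_equal(nrow(fit$history), 3 + 1)
  expect_equal(fit$best_epoch, 1)

  # the warmup floor delays the stop but not the best-checkpoint choice
  fit2 <- graphnet_fit(graphs, graphnet_config(ch_pqrst = c(8, 8),
                                               ch_qrs = c(8, 8), fc = 8),
                       seed = 4, lr = 0, max_epochs = 50, patience = 3,
                       min_epochs = 10)
  expect_equal(nrow(fit2$history), 10 + 3)
  expect_equal(fit2$best_epoch, 1)
  expect_error(graphnet_fit(list(), graphnet_config()), "empty")
})

test_that("patient leakage between training and validation is rejected", {
  graphs <- fix_graphs()
  expect_error(graphnet_fit(graphs[1:6], graphnet_config(), val = graphs[3]),
               "leakage")
})

test_that("grid search is exhaustive, robust and picks the argmax", {
  ds <- fix_dataset()
  grid <- list(
    list(arch = "pqrst", ch_pqrst = c(12, 12), fc = 12),
    list(arch = "pqrst", ch_pqrst = 0),          # deliberately broken cell
    list(arch = "pqrst", ch_pqrst = c(8, 8), fc = 8))
  gs <- grid_search(grid, ds, k = 3, seed = 6,
                    ae_opts = list(epochs = 15),
                    fit_opts = list(max_epochs = 10, patience = 5))
  expect_true(is.na(gs$results$macro_f1[2]))
  expect_match(gs$results$error[2], "positive")
  valid <- which(!is.na(gs$results$macro_f1))
  expect_equal(gs$results$macro_f1[gs$best_index],
               max(gs$results$macro_f1[valid]))

  one <- grid_search(grid[1], ds, k = 3, seed = 6,
                     ae_opts = list(epochs = 15),
                     fit_opts = list(max_epochs = 5, patience = 5))
  expect_equal(one$best_index, 1)
})

test_that("scalability splits recover patient groups from the data alone", {
  patterns <- c("NNNNNNNN", "NNNNNNNN",    # p001
                "NNSNNNNN", "NNNNNNNN",    # p002
                "NNNNSSSS", "NNNNNNNN",    # p003 -> test
                "NNNNNNNN", "NNNNNNNN",    # p004
                "NNNNNNNN", "NNNNNNNNNNN", # p005 (11-beat size record)
                "NNNNNNNN", "NNNNNNNN",    # p006
                "NNNVVVVN", "NNNNNNNNNNN", # p007 -> test
                "NNNNNNNN", "NNNNNNNN")    # p008
  ds <- generate_dataset(8, 2, seed = 3, pattern = patterns)
  sp <- scalability_splits(ds)
  expect_equal(sp$test_patients, c("p003", "p007"))
  expect_equal(length(sp$train8), 11)
  expect_equal(vapply(sp$pattern, `[[`, character(1), "record_id"),
               c("p003_r001", "p007_r001"))
  # the 11-beat record of test patient p007 lands in the Size set,
  # p005's stays on the training side and is excluded from train8
  expect_equal(vapply(sp$size, `[[`, character(1), "record_id"), "p007_r002")
  # 8-beat non-qualifying record of a test patient -> Control set
  expect_equal(vapply(sp$control, `[[`, character(1), "record_id"),
               "p003_r002")

  all_n <- generate_dataset(3, 1, seed = 4, pattern = "NNNNNNNN")
  expect_error(scalability_splits(all_n), "no patient")
})
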