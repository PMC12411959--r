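# Scalability verification: pattern/size generalisation of models trained
# only on 8-beat graphs, evaluated by a soft-voting ensemble of the k fold
# models.

max_minority_run <- function(labs) {
  r <- rle(labs %in% c("S", "V"))
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

has_pattern_rule <- function(labs)
  any(labs == "N") && max_minority_run(labs) >= 4

#' Split a dataset for the scalability verification protocol
#'
#' Test patients are those owning at least one 8-beat record containing
#' >= 1 N beat and >= 4 consecutive S or V beats; all remaining patients are
#' training patients. Four record sets are derived: the 8-beat training set
#' (8-beat records of training patients), the Pattern test set (qualifying
#' 8-beat records of test patients), the Size test set (records of test
#' patients with >= 9 beats) and the Control test set (8-beat records of
#' test patients that do not satisfy the pattern rule). Training and test
#' patient sets are disjoint by construction.
#'
#' @param records List of `ecg_record` with patient provenance.
#' @return An object of class `scalability_splits`.
#' @export
scalability_splits <- function(records) {
  labs <- beat_labels(records)
  pats <- vapply(records, function(r) r$patient_id, character(1))
  nb <- lengths(labs)
  qualifies <- nb == 8 & vapply(labs, has_pattern_rule, logical(1))
  test_patients <- sort(unique(pats[qualifies]))
  if (!length(test_patients))
    stopf(paste("no patient owns an 8-beat record with >= 1 N beat and >= 4",
                "consecutive S or V beats; generate records with explicit",
                "patterns (e.g. 'NNNNSSSS') to populate the test group"))
  train_patients <- sort(setdiff(unique(pats), test_patients))
  if (!length(train_patients))
    stopf("every patient qualified as a test patient; none left for training")
  is_test <- pats %in% test_patients
  structure(list(
    train_patients = train_patients,
    test_patients = test_patients,
    train8 = records[!is_test & nb == 8],
    pattern = records[is_test & qualifies],
    size = records[is_test & nb >= 9],
    control = records[is_test & nb == 8 & !qualifies]
  ), class = "scalability_splits")
}

#' Run the scalability verification protocol
#'
#' Trains k fold models by interpatient cross-validation restricted to the
#' 8-beat training set (each member with its own training-fold autoencoders
#' and optional minority-class augmentation), then evaluates the Pattern,
#' Size and Control test sets with a soft-voting ensemble of all members —
#' without any reconfiguration, since the model is size-agnostic.
#'
#' @inheritParams cross_validate
#' @param augment_targets Optional minority-class targets applied to each
#'   member's training graphs.
#' @return An object of class `scalability_result` with the 8-beat CV
#'   summary and, per test set, an [evaluate_beats()] report and the
#'   exact-match accuracy.
#' @export
scalability_run <- function(records, k = 5, cfg = graphnet_config(),
                            gcfg = graph_config(), seed = 1,
                            augment_targets = NULL, exclude_ends = FALSE,
                            ae_opts = list(), fit_opts = list(),
                            aug_opts = list()) {
  splits <- scalability_splits(records)
  tr8 <- splits$train8
  pats <- vapply(tr8, function(r) r$patient_id, character(1))
  folds <- interpatient_folds(pats, k, seed)
  fold_of <- folds[pats]

  members <- vector("list", k)
  val_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- tr8[fold_of != f]
    va <- tr8[fold_of == f]
    aes <- do.call(fit_segment_embeddings,
                   c(list(tr, seed = child_seed(seed, 100 + f)), ae_opts))
    gtr <- build_graphs(tr, aes, gcfg)
    gva <- build_graphs(va, aes, gcfg)
    if (!is.null(augment_targets))
      gtr <- do.call(augment_graphs,
                     c(list(gtr, targets = augment_targets,
                            seed = child_seed(seed, 200 + f)), aug_opts))
    fit <- do.call(graphnet_fit,
                   c(list(gtr, cfg = cfg, val = gva,
                          seed = child_seed(seed, 300 + f)), fit_opts))
    val_reports[[f]] <- evaluate_beats(
      predict(fit, gva, type = "class"),
      lapply(gva, `[[`, "beat_labels"), exclude_ends = exclude_ends)
    members[[f]] <- list(aes = aes, fit = fit)
  }

  eval_set <- function(set_records) {
    if (!length(set_records)) return(NULL)
    probs <- lapply(members, function(m) {
      g <- build_graphs(set_records, m$aes, gcfg)
      predict(m$fit, g, type = "prob")
    })
    avg <- ensemble_predict(probs = probs, type = "class")
    labels <- beat_labels(set_records)
    list(report = evaluate_beats(avg, labels, exclude_ends = exclude_ends),
         exact_match = exact_match(avg, labels,
                                   exclude_ends = exclude_ends))
  }

  macro8 <- vapply(val_reports, `[[`, numeric(1), "macro_f1")
  structure(list(
    splits = splits,
    cv8 = list(macro_f1 = mean(macro8),
               macro_f1_range = (max(macro8) - min(macro8)) / 2,
               folds = val_reports),
    pattern = eval_set(splits$pattern),
    size = eval_set(splits$size),
    control = eval_set(splits$control),
    members = members
  ), class = "scalability_result")
}

#' @export
print.scalability_result <- function(x, ...) {
  cat("Scalability verification (soft-voting ensemble of fold models)\n")
  cat(sprintf("  8-beat training CV: Macro F1 %.4f (+/- %.4f)\n",
              x$cv8$macro_f1, x$cv8$macro_f1_range))
  for (s in c("pattern", "size", "control")) {
    if (is.null(x[[s]])) next
    cat(sprintf("  %-8s Macro F1 %.4f  Acc %.4f  exact match %.4f\n",
                paste0(s, ":"), x[[s]]$report$macro_f1, x[[s]]$report$acc,
                x[[s]]$exact_match))
  }
  invisible(x)
}
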