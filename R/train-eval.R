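#' Interpatient cross-validation folds
#'
#' Partitions patients into k folds of near-equal size (difference at most
#' one patient), deterministically given the seed. Every patient belongs to
#' exactly one fold, so no patient contributes data to both the training and
#' validation side of any split.
#'
#' @param patient_ids Character vector of patient identifiers (duplicates
#'   allowed; folds are over unique patients).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector mapping each patient to a fold in `1:k`.
#' @export
interpatient_folds <- function(patient_ids, k = 5, seed = 1) {
  ids <- unique(patient_ids)
  if (length(ids) < k)
    stopf("need at least k = %d patients, got %d", k, length(ids))
  shuffled <- with_seed_(seed, sample(ids))
  fold <- rep(seq_len(k), length.out = length(ids))
  stats::setNames(fold, shuffled)
}

trim_ends <- function(x) if (length(x) > 2) x[-c(1, length(x))] else x[0]

#' Per-class beat classification metrics
#'
#' Computes the confusion-matrix-derived metrics per class — sensitivity
#' `Sn = TP/(TP+FN)`, positive predictive value `PPV = TP/(TP+FP)` and F1 —
#' plus overall accuracy and Macro F1 (unweighted mean of the class F1s).
#' With `exclude_ends = TRUE`, the first and last beat of every graph are
#' dropped before counting (end nodes have low graph connectivity). A class
#' absent from the labels has undefined Sn and is excluded from the Macro F1
#' mean by default (`absent = "drop"`); `absent = "zero"` scores it 0.
#'
#' @param preds List of per-graph predicted label vectors (or probability
#'   matrices, converted by argmax with ties broken in class order N < S < V).
#' @param labels List of per-graph true label vectors, aligned with `preds`.
#' @param exclude_ends Drop the first and last beat of every graph.
#' @param absent Convention for classes absent from the labels.
#' @return An object of class `eval_report`.
#' @export
evaluate_beats <- function(preds, labels, exclude_ends = FALSE,
                           absent = c("drop", "zero")) {
  absent <- match.arg(absent)
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(labels)) labels <- list(labels)
  if (length(preds) != length(labels))
    stopf("preds and labels must align per graph")
  preds <- lapply(preds, function(p)
    if (is.matrix(p)) prob_to_class(p) else p)
  for (i in seq_along(preds))
    if (length(preds[[i]]) != length(labels[[i]]))
      stopf("graph %d: %d predictions for %d labels", i,
            length(preds[[i]]), length(labels[[i]]))
  if (exclude_ends) {
    preds <- lapply(preds, trim_ends)
    labels <- lapply(labels, trim_ends)
  }
  p <- factor(unlist(preds), levels = BEAT_CLASSES)
  l <- factor(unlist(labels), levels = BEAT_CLASSES)
  conf <- table(truth = l, pred = p)

  per_class <- data.frame(class = BEAT_CLASSES, Sn = NA_real_,
                          PPV = NA_real_, F1 = NA_real_)
  for (i in seq_along(BEAT_CLASSES)) {
    tp <- conf[i, i]
    fn <- sum(conf[i, ]) - tp
    fp <- sum(conf[, i]) - tp
    per_class$Sn[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per_class$PPV[i] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per_class$F1[i] <- if (tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp)
    else NA_real_
  }
  present <- rowSums(conf) > 0
  f1s <- per_class$F1
  if (absent == "zero") f1s[is.na(f1s)] <- 0 else f1s <- f1s[present]
  structure(list(
    per_class = per_class,
    acc = if (length(l)) mean(p == l) else NA_real_,
    macro_f1 = mean(f1s),
    confusion = conf,
    exclude_ends = exclude_ends,
    n_beats = length(l)
  ), class = "eval_report")
}

#' Exact-match accuracy over graphs
#'
#' Fraction of graphs whose every (optionally end-excluded) beat prediction
#' equals the label. Graphs left with no beats after end exclusion count as
#' matched (vacuously).
#'
#' @inheritParams evaluate_beats
#' @return A single number in \[0, 1\].
#' @export
exact_match <- function(preds, labels, exclude_ends = FALSE) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(labels)) labels <- list(labels)
  preds <- lapply(preds, function(p)
    if (is.matrix(p)) prob_to_class(p) else p)
  ok <- vapply(seq_along(preds), function(i) {
    p <- preds[[i]]; l <- labels[[i]]
    if (exclude_ends) { p <- trim_ends(p); l <- trim_ends(l) }
    all(p == l)
  }, logical(1))
  mean(ok)
}

#' Soft-voting ensemble prediction
#'
#' Averages the per-beat softmax probability outputs of several trained
#' models and takes the class with the highest mean probability (ties broken
#' by the fixed class order N < S < V).
#'
#' @param models List of `graphnet_fit` objects (ignored when `probs` is
#'   given).
#' @param graphs List of `ecg_graph` to predict on.
#' @param probs Alternatively, precomputed member outputs: a list (one
#'   element per member) of lists of per-graph probability matrices.
#' @param type `"prob"` or `"class"`.
#' @return Per-graph list of averaged probability matrices or label vectors.
#' @export
ensemble_predict <- function(models = NULL, graphs = NULL, probs = NULL,
                             type = c("prob", "class")) {
  type <- match.arg(type)
  if (is.null(probs)) {
    if (!length(models)) stopf("need at least one model")
    probs <- lapply(models, function(m) {
      pr <- predict(m, graphs, type = "prob")
      if (is.matrix(pr)) list(pr) else pr
    })
  }
  probs <- lapply(probs, function(mp) if (is.matrix(mp)) list(mp) else mp)
  ng <- unique(vapply(probs, length, integer(1)))
  if (length(ng) != 1) stopf("members predicted different numbers of graphs")
  out <- lapply(seq_len(ng), function(g) {
    dims <- vapply(probs, function(mp) nrow(mp[[g]]), integer(1))
    if (length(unique(dims)) != 1)
      stopf("members disagree on the beat count of graph %d", g)
    avg <- Reduce(`+`, lapply(probs, `[[`, g)) / length(probs)
    if (type == "class") prob_to_class(avg) else avg
  })
  out
}

#' Interpatient k-fold cross-validation of the full pipeline
#'
#' For each fold: fits the three segment autoencoders on training-fold
#' records only, builds graphs for both sides with the frozen embeddings,
#' optionally augments the training graphs toward minority-class targets,
#' trains the classifier with early stopping on the validation fold, and
#' evaluates per-beat metrics on the validation fold. Patient disjointness
#' between training and validation is asserted at every step.
#'
#' @param records List of `ecg_record` with patient provenance.
#' @param k Number of folds.
#' @param cfg A [graphnet_config()], or a named list of them to compare
#'   several architectures on identical folds, embeddings and graphs.
#' @param gcfg A [graph_config()].
#' @param seed Integer master seed (fold assignment, per-fold autoencoder,
#'   augmentation and training seeds all derive from it).
#' @param augment_targets Optional N/S/V proportions passed to
#'   [augment_graphs()] on training folds only.
#' @param exclude_ends Passed to [evaluate_beats()].
#' @param ae_opts,fit_opts,aug_opts Lists of extra arguments for
#'   [fit_segment_embeddings()], [graphnet_fit()] and [augment_graphs()].
#' @param keep_fits Keep the fitted member models in the result.
#' @return An object of class `cv_result`: per-fold reports, fold mean and
#'   error range (max minus min over folds, halved) of accuracy and Macro F1.
#'   With a list of configs, a named list of `cv_result`s.
#' @export
cross_validate <- function(records, k = 5, cfg = graphnet_config(),
                           gcfg = graph_config(), seed = 1,
                           augment_targets = NULL, exclude_ends = FALSE,
                           ae_opts = list(), fit_opts = list(),
                           aug_opts = list(), keep_fits = FALSE) {
  single <- inherits(cfg, "graphnet_config")
  cfgs <- if (single) list(cfg) else cfg
  if (!all(vapply(cfgs, inherits, logical(1), "graphnet_config")))
    stopf("cfg must be a graphnet_config or a list of them")
  pats <- vapply(records, function(r) r$patient_id, character(1))
  folds <- interpatient_folds(pats, k, seed)
  fold_of <- folds[pats]
  reports <- lapply(cfgs, function(.) vector("list", k))
  fits <- lapply(cfgs, function(.) vector("list", k))
  for (f in seq_len(k)) {
    tr <- records[fold_of != f]
    va <- records[fold_of == f]
    aes <- do.call(fit_segment_embeddings,
                   c(list(tr, seed = child_seed(seed, 100 + f)), ae_opts))
    gtr <- build_graphs(tr, aes, gcfg)
    gva <- build_graphs(va, aes, gcfg)
    if (!is.null(augment_targets))
      gtr <- do.call(augment_graphs,
                     c(list(gtr, targets = augment_targets,
                            seed = child_seed(seed, 200 + f)), aug_opts))
    labs_va <- lapply(gva, `[[`, "beat_labels")
    for (ci in seq_along(cfgs)) {
      fit <- do.call(graphnet_fit,
                     c(list(gtr, cfg = cfgs[[ci]], val = gva,
                            seed = child_seed(seed, 300 + f)), fit_opts))
      preds <- predict(fit, gva, type = "class")
      reports[[ci]][[f]] <- evaluate_beats(preds, labs_va,
                                           exclude_ends = exclude_ends)
      if (keep_fits) fits[[ci]][[f]] <- fit
    }
  }
  out <- lapply(seq_along(cfgs), function(ci) {
    macro <- vapply(reports[[ci]], `[[`, numeric(1), "macro_f1")
    acc <- vapply(reports[[ci]], `[[`, numeric(1), "acc")
    structure(list(
      folds = reports[[ci]], fits = if (keep_fits) fits[[ci]],
      macro_f1 = mean(macro), macro_f1_range = (max(macro) - min(macro)) / 2,
      macro_f1_sd = stats::sd(macro),
      acc = mean(acc), acc_range = (max(acc) - min(acc)) / 2,
      k = k, arch = cfgs[[ci]]$arch, exclude_ends = exclude_ends
    ), class = "cv_result")
  })
  names(out) <- names(cfgs)
  if (single) out[[1]] else out
}

#' Exhaustive grid search over architecture configurations
#'
#' Evaluates every cell of a configuration grid by interpatient k-fold
#' cross-validation and selects the winner by the highest mean Macro F1;
#' ties are broken by smaller parameter count, then by grid order. A cell
#' whose configuration or training fails is reported as failed and the
#' search continues.
#'
#' @param grid A list of argument lists for [graphnet_config()].
#' @param records List of `ecg_record`.
#' @param k,seed,... Passed to [cross_validate()].
#' @return A list with `best_cfg`, `best_index`, a `results` data frame
#'   (macro F1, parameter count, error message per cell) and the per-cell
#'   `cv_result`s.
#' @export
grid_search <- function(grid, records, k = 5, seed = 1, ...) {
  if (!length(grid)) stopf("grid must contain at least one configuration")
  cells <- vector("list", length(grid))
  res <- data.frame(cell = seq_along(grid), macro_f1 = NA_real_,
                    n_params = NA_real_, error = NA_character_)
  for (i in seq_along(grid)) {
    out <- tryCatch({
      cfg <- do.call(graphnet_config, grid[[i]])
      cv <- cross_validate(records, k = k, cfg = cfg, seed = seed,
                           keep_fits = TRUE, ...)
      list(cv = cv, cfg = cfg,
           np = n_params(cv$fits[[1]]$params))
    }, error = function(e) list(error = conditionMessage(e)))
    if (!is.null(out$error)) {
      res$error[i] <- out$error
    } else {
      cells[[i]] <- out$cv
      res$macro_f1[i] <- out$cv$macro_f1
      res$n_params[i] <- out$np
    }
  }
  if (all(is.na(res$macro_f1))) stopf("every grid cell failed")
  ord <- order(-res$macro_f1, res$n_params, res$cell, na.last = TRUE)
  best <- ord[1]
  list(best_cfg = do.call(graphnet_config, grid[[best]]),
       best_index = best, results = res, cv = cells)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Beat classification over %d beats%s\n", x$n_beats,
              if (x$exclude_ends) " (both end beats excluded)" else ""))
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %s: Sn %.3f  PPV %.3f  F1 %.3f\n", pc$class[i],
                pc$Sn[i], pc$PPV[i], pc$F1[i]))
  cat(sprintf("  Acc %.3f  Macro F1 %.3f\n", x$acc, x$macro_f1))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold interpatient CV of %s%s\n", x$k, x$arch,
              if (x$exclude_ends) " (both end beats excluded)" else ""))
  cat(sprintf("  Macro F1 %.4f (+/- %.4f)   Acc %.4f (+/- %.4f)\n",
              x$macro_f1, x$macro_f1_range, x$acc, x$acc_range))
  invisible(x)
}
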