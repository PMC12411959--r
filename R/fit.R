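#' Fit a graph convolutional beat classifier
#'
#' Trains the configured architecture on a list of ECG graphs by minimising
#' the per-beat cross-entropy with the Adam optimizer. When validation
#' graphs are supplied, early stopping monitors the validation loss and the
#' parameters with the best validation loss are returned. Batch
#' normalisation uses batch-of-graphs statistics during training and running
#' averages at inference.
#'
#' @param graphs List of `ecg_graph` training graphs (with beat labels).
#' @param cfg A [graphnet_config()].
#' @param val Optional list of `ecg_graph` validation graphs; their patient
#'   set must be disjoint from the training patients (asserted).
#' @param seed Integer seed: parameter initialisation and minibatch order are
#'   deterministic given the seed.
#' @param lr Adam learning rate.
#' @param max_epochs,patience Early-stopping budget: training stops when the
#'   validation loss has not improved for `patience` consecutive epochs.
#' @param min_epochs Warmup floor: non-improving epochs are not counted
#'   against `patience` before this epoch, so the stopper cannot fire during
#'   the early transient in which batch-norm statistics and the
#'   majority-class plateau are still settling.
#' @param batch_size Number of graphs per minibatch.
#' @return An object of class `graphnet_fit`.
#' @export
graphnet_fit <- function(graphs, cfg = graphnet_config(), val = NULL,
                         seed = 1, lr = 2e-3, max_epochs = 100,
                         patience = 10, min_epochs = 15, batch_size = 64) {
  if (!length(graphs)) stopf("empty training set")
  d <- ncol(graphs[[1]]$X)
  if (!is.null(val) && length(val)) {
    tr_pat <- unique(vapply(graphs, function(g) g$patient_id, character(1)))
    va_pat <- unique(vapply(val, function(g) g$patient_id, character(1)))
    if (length(intersect(tr_pat, va_pat)))
      stopf("patient leakage: %s appear in both training and validation",
            paste(intersect(tr_pat, va_pat), collapse = ", "))
  }

  ord <- with_seed_(child_seed(seed, 1), sample.int(length(graphs)))
  nb <- max(1L, ceiling(length(graphs) / batch_size))
  splits <- split(ord, rep(seq_len(nb), length.out = length(graphs),
                           each = ceiling(length(graphs) / nb)))
  batches <- lapply(splits, function(idx) compile_batch(graphs[idx], cfg))
  val_batch <- if (!is.null(val) && length(val)) compile_batch(val, cfg)

  params <- init_params(cfg, d = d, seed = child_seed(seed, 2))
  st <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(max_epochs)) {
    tl <- 0
    for (b in batches) {
      fw <- forward_batch(params, b, cfg, training = TRUE)
      params <- fw$params
      tl <- tl + ce_loss(fw$probs, b$Y) * nrow(b$Y)
      grads <- backward_batch(params, b, cfg, fw)
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params; st <- upd$state
    }
    tl <- tl / sum(vapply(batches, function(b) nrow(b$Y), numeric(1)))
    vl <- if (!is.null(val_batch))
      ce_loss(forward_batch(params, val_batch, cfg, FALSE)$probs,
              val_batch$Y) else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tl,
                                val_loss = vl))
    monitor <- if (is.na(vl)) tl else vl
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = params, epoch = epoch)
      wait <- 0L
    } else if (epoch > min_epochs) {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }

  structure(list(params = best$params, cfg = cfg, history = history,
                 best_epoch = best$epoch, best_loss = best$loss,
                 d = d, seed = seed,
                 n_train_graphs = length(graphs),
                 n_train_beats = sum(vapply(graphs, function(g)
                   length(g$beat_labels), integer(1)))),
            class = "graphnet_fit")
}

#' Predict beat classes for new ECG graphs
#'
#' @param object A `graphnet_fit`.
#' @param newdata A single `ecg_graph` or a list of them.
#' @param type `"prob"` for per-beat probability matrices, `"class"` for
#'   label vectors (argmax, ties broken by the fixed class order N < S < V).
#' @param ... Unused.
#' @return A list (one element per graph) of B x 3 probability matrices or
#'   label vectors; a single graph input returns the element itself.
#' @export
predict.graphnet_fit <- function(object, newdata, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "ecg_graph")
  graphs <- if (single) list(newdata) else newdata
  if (!length(graphs)) return(list())
  batch <- compile_batch(graphs, object$cfg)
  fw <- forward_batch(object$params, batch, object$cfg, training = FALSE)
  probs <- fw$probs
  colnames(probs) <- BEAT_CLASSES
  idx <- rep(seq_along(graphs), batch$nbeats)
  out <- lapply(seq_along(graphs), function(i) {
    pm <- probs[idx == i, , drop = FALSE]
    if (type == "class") prob_to_class(pm) else pm
  })
  if (single) out[[1]] else out
}

# argmax with the documented tie rule: first (lowest-index) class among ties,
# in the fixed order N < S < V.
prob_to_class <- function(pm) BEAT_CLASSES[max.col(pm, ties.method = "first")]

#' @export
print.graphnet_fit <- function(x, ...) {
  cat(sprintf("<graphnet_fit %s: %d params, trained on %d graphs/%d beats>\n",
              x$cfg$arch, n_params(x$params), x$n_train_graphs,
              x$n_train_beats))
  cat(sprintf("  best epoch %d, monitored loss %.4f (%d epochs run)\n",
              x$best_epoch, x$best_loss, nrow(x$history)))
  invisible(x)
}

#' @export
summary.graphnet_fit <- function(object, ...) {
  cat(sprintf("Graph convolutional beat classifier (%s)\n", object$cfg$arch))
  cat(sprintf("  segment-level GC widths: %s\n",
              paste(object$cfg$ch_pqrst, collapse = ", ")))
  if (object$cfg$arch != "pqrst")
    cat(sprintf("  beat-level GC widths: %s (skip: %s)\n",
                paste(object$cfg$ch_qrs, collapse = ", "),
                if (object$cfg$arch == "ecg_graphnet") object$cfg$skip
                else "n/a"))
  cat(sprintf("  prediction block: FC %d -> %d -> 3, pooling c = %g\n",
              pred_in_width(object$cfg), object$cfg$fc, object$cfg$c))
  cat(sprintf("  parameters: %d; input feature dimension d = %d\n",
              n_params(object$params), object$d))
  cat(sprintf("  epochs run: %d, best epoch: %d, best monitored loss: %.4f\n",
              nrow(object$history), object$best_epoch, object$best_loss))
  invisible(object)
}

#' @export
coef.graphnet_fit <- function(object, ...) object$params

#' @export
plot.graphnet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", ylim = range(
                   c(h$train_loss, h$val_loss), na.rm = TRUE), ...)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
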