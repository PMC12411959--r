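#' Minority-class graph augmentation
#'
#' Rebalances a set of training graphs toward target N/S/V beat proportions
#' by generating additional minority-centered graphs, operating purely on
#' the graph representation (raw signals are never touched). Each new graph
#' is a beat-window subgraph extracted around a randomly chosen minority
#' (S or V) beat — the run of consecutive minority beats containing it,
#' clipped to at most `w` beats — with its adjacency and distance features
#' rebuilt by the graph-construction rules, and multiplicative Gaussian
#' jitter applied to the width and distance features (one-hot and embedding
#' coordinates are left untouched, since they encode segment identity and
#' morphology). Because extracted windows contain only minority beats, the
#' N beat count never increases. Generation repeats until every realised
#' class proportion is within `tol` of its target or the cap is reached.
#' Original graphs are never mutated.
#'
#' @param graphs List of `ecg_graph` training graphs with beat labels.
#' @param targets Length-3 N/S/V target proportions (summing to 1).
#' @param tol Tolerance on realised proportions, as a fraction (0.02 = 2
#'   percentage points).
#' @param w Maximum beats per extracted window.
#' @param jitter_sd Standard deviation of the multiplicative jitter.
#' @param seed Integer seed; the augmented set is deterministic given it.
#' @param max_factor Cap: at most `max_factor * length(graphs)` new graphs;
#'   hitting it emits a warning reporting the achieved proportions.
#' @return The original graphs followed by the generated graphs, with an
#'   `augmentation` attribute summarising before/after counts.
#' @export
augment_graphs <- function(graphs, targets = c(N = 0.4, S = 0.3, V = 0.3),
                           tol = 0.02, w = 8, jitter_sd = 0.05, seed = 1,
                           max_factor = 20) {
  targets <- targets / sum(targets)
  if (length(targets) != 3 || any(targets < 0))
    stopf("targets must be 3 non-negative proportions")
  names(targets) <- BEAT_CLASSES

  labs <- lapply(graphs, `[[`, "beat_labels")
  counts <- vapply(BEAT_CLASSES, function(cl) sum(unlist(labs) == cl),
                   numeric(1))
  for (cl in c("S", "V"))
    if (targets[cl] > 0 && counts[cl] == 0)
      stopf("target > 0 for class %s but no such beat exists in the input", cl)

  # candidate minority beats with their containing minority run
  cand <- list()
  for (g in seq_along(graphs)) {
    lb <- labs[[g]]
    r <- rle(lb %in% c("S", "V"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      for (b in starts[i]:ends[i]) {
        cand[[length(cand) + 1]] <- list(g = g, beat = b, class = lb[b],
                                         run = c(starts[i], ends[i]))
      }
    }
  }
  cand_class <- vapply(cand, `[[`, character(1), "class")

  n_before <- counts
  new_graphs <- list()
  cap <- max_factor * length(graphs)
  capped <- FALSE

  with_seed_(seed, {
    repeat {
      props <- counts / sum(counts)
      if (all(abs(props - targets) <= tol)) break
      if (length(new_graphs) >= cap) { capped <- TRUE; break }
      deficit <- targets - props
      pick_class <- names(which.max(deficit[c("S", "V")]))
      pool <- which(cand_class == pick_class)
      if (!length(pool)) pool <- which(cand_class %in% c("S", "V"))
      ci <- cand[[pool[sample.int(length(pool), 1)]]]

      lo <- ci$run[1]; hi <- ci$run[2]
      if (hi - lo + 1 > w) {
        lo <- max(ci$run[1], ci$beat - (w - 1) %/% 2)
        hi <- min(ci$run[2], lo + w - 1)
        lo <- max(ci$run[1], hi - w + 1)
      }
      sub <- extract_beat_window(graphs[[ci$g]], lo:hi,
                                 sprintf("aug%04d", length(new_graphs) + 1))
      sub <- jitter_graph_features(sub, jitter_sd)
      new_graphs[[length(new_graphs) + 1]] <- sub
      for (cl in sub$beat_labels) counts[cl] <- counts[cl] + 1
    }
  })
  if (capped)
    warning(sprintf(
      "augmentation cap reached; achieved proportions N %.3f / S %.3f / V %.3f",
      counts["N"] / sum(counts), counts["S"] / sum(counts),
      counts["V"] / sum(counts)))

  out <- c(graphs, new_graphs)
  attr(out, "augmentation") <- list(
    targets = targets, tol = tol,
    n_before = n_before, n_after = counts,
    achieved = counts / sum(counts),
    n_new_graphs = length(new_graphs), capped = capped)
  out
}

# Subgraph of the beats in `beats` (indices), with adjacency and distance
# features rebuilt from the retained node metadata.
extract_beat_window <- function(graph, beats, tag) {
  idx <- which(graph$node_meta$beat %in% beats)
  meta <- graph$node_meta[idx, , drop = FALSE]
  meta$beat <- match(meta$beat, beats)
  rownames(meta) <- NULL
  core <- graph$X[idx, seq_len(graph$d - 2), drop = FALSE]
  graph_from_meta(meta, core, graph$cfg, graph$beat_labels[beats],
                  graph$patient_id, paste0(graph$record_id, "_", tag))
}

# Multiplicative Gaussian jitter on the width and distance feature columns.
jitter_graph_features <- function(graph, sd) {
  cols <- c(4L, graph$d - 1L, graph$d)
  n <- nrow(graph$X)
  jit <- matrix(1 + stats::rnorm(n * length(cols), 0, sd), n)
  graph$X[, cols] <- pmax(graph$X[, cols] * jit, 0)
  graph
}
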