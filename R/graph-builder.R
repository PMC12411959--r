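#' Configuration of the ECG graph representation
#'
#' Controls the edge scheme, edge-weight parameters and pooling constant used
#' when converting annotated records into graphs.
#'
#' @param edges Same-type edge scheme: `"qrs"` (QRS-QRS edges within the
#'   window; the default configuration), `"pp"` (P-P edges), `"both"`, or
#'   `"none"` (only chronologically adjacent edges and self-loops).
#' @param window Same-type edge window size; 5 means each QRS connects to up
#'   to 2 preceding and 2 following QRS nodes (5 nodes including itself).
#' @param alpha,delta0 Parameters of the logistic edge-weight function
#'   [edge_weight()], in 1/s and s.
#' @param c Weight-decay constant of QRS-centered pooling.
#' @param pool_exclusive If `TRUE`, the pooling window excludes the
#'   neighbouring QRS nodes themselves (sum runs to the nodes strictly
#'   between consecutive QRS complexes).
#' @param qrs_edge_mode Edge weights of the beat-level graph: `"sigmoid"`
#'   transforms the RR interval through [edge_weight()]; `"raw"` uses the RR
#'   interval itself.
#' @param alpha_qrs,delta0_qrs Logistic parameters for the beat-level graph.
#'   RR intervals live on a different time scale (roughly 0.4-1.5 s) than
#'   inter-segment gaps (tens of milliseconds), so the midpoint sits at a
#'   typical resting RR of 1 s with a gentler slope; with the segment-scale
#'   midpoint all RR edges would be near zero and the beat-level graph would
#'   carry no rhythm information.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(edges = c("qrs", "pp", "both", "none"), window = 5,
                         alpha = 10, delta0 = 0.3, c = 0.1,
                         pool_exclusive = FALSE,
                         qrs_edge_mode = c("sigmoid", "raw"),
                         alpha_qrs = 4, delta0_qrs = 1.0) {
  edges <- match.arg(edges)
  qrs_edge_mode <- match.arg(qrs_edge_mode)
  if (alpha <= 0 || alpha_qrs <= 0)
    stopf("alpha must be > 0 (edge weights must decrease with time gap)")
  if (window < 1) stopf("window must be >= 1")
  if (c < 0) stopf("pooling constant c must be >= 0")
  structure(list(edges = edges, window = window, alpha = alpha,
                 delta0 = delta0, c = c, pool_exclusive = pool_exclusive,
                 qrs_edge_mode = qrs_edge_mode,
                 alpha_qrs = alpha_qrs, delta0_qrs = delta0_qrs),
            class = "graph_config")
}

#' Logistic edge weight as a function of the time gap
#'
#' `w = 1 / (1 + exp(alpha * (delta_t - delta0)))`: strictly decreasing in
#' the gap, 0.5 at `delta0`, approaching 1 for coincident segments and 0 for
#' distant ones — segments closer in time get higher weights.
#'
#' @param delta_t Time gap in seconds (>= 0), vectorised.
#' @param alpha Steepness in 1/s (> 0).
#' @param delta0 Midpoint in seconds.
#' @return Weights in (0, 1).
#' @export
edge_weight <- function(delta_t, alpha = 10, delta0 = 0.3) {
  if (alpha <= 0) stopf("alpha must be > 0")
  if (any(delta_t < 0)) stopf("delta_t must be >= 0")
  1 / (1 + exp(alpha * (delta_t - delta0)))
}

# Assemble an ecg_graph from node metadata + core features (one-hot, width,
# embedding). Distance features and the adjacency are (re)computed here, so
# subgraph extraction during augmentation reuses exactly the same rules.
graph_from_meta <- function(meta, core, cfg, beat_labels, patient_id,
                            record_id) {
  M <- nrow(meta)
  if (M == 0) stopf("record has no annotated segments")
  if (is.unsorted(meta$onset, strictly = FALSE))
    stopf("segments out of chronological order")

  # distance features: gap between the end of one segment and the start of
  # the next, in seconds; boundary nodes use 0 for the missing side
  dp <- c(0, pmax(meta$onset[-1] - meta$offset[-M], 0))
  dn <- c(pmax(meta$onset[-1] - meta$offset[-M], 0), 0)
  X <- cbind(core, dist_prev = dp, dist_next = dn)

  A <- diag(1, M)
  if (M > 1) {
    gap <- pmax(meta$onset[-1] - meta$offset[-M], 0)
    w <- edge_weight(gap, cfg$alpha, cfg$delta0)
    for (i in seq_len(M - 1)) A[i, i + 1] <- A[i + 1, i] <- w[i]
  }
  half <- (cfg$window - 1) %/% 2
  add_same_type <- function(A, type) {
    pos <- which(meta$type == type)
    np <- length(pos)
    if (np > 1) for (a in seq_len(np - 1)) {
      for (b in (a + 1):min(np, a + half)) {
        i <- pos[a]; j <- pos[b]
        g <- abs(meta$onset[j] - meta$onset[i])
        A[i, j] <- A[j, i] <- edge_weight(g, cfg$alpha, cfg$delta0)
      }
    }
    A
  }
  if (cfg$edges %in% c("qrs", "both")) A <- add_same_type(A, "QRS")
  if (cfg$edges %in% c("pp", "both")) A <- add_same_type(A, "P")

  structure(list(X = X, A = A, node_meta = meta, beat_labels = beat_labels,
                 patient_id = patient_id, record_id = record_id,
                 cfg = cfg, d = ncol(X)),
            class = "ecg_graph")
}

#' Build the segment-level ECG graph from an annotated record
#'
#' One node per annotated P/QRS/T segment, in chronological order. Node
#' features (d = 22 under default config) are: one-hot segment type (3),
#' segment width in seconds (1), autoencoder embedding (16), and distances in
#' seconds to the previous and next node (2; boundary sides are 0). Edges:
#' self-loops with weight 1, chronologically adjacent pairs, and same-type
#' pairs within the configured window (QRS-QRS by default), all weighted by
#' [edge_weight()] on the inter-segment time gap (same-type gaps measured
#' onset-to-onset, adjacent gaps offset-to-next-onset).
#'
#' @param record An `ecg_record`.
#' @param aes An `ae_set` from [fit_segment_embeddings()].
#' @param cfg A [graph_config()].
#' @return An object of class `ecg_graph` with fields `X`, `A`, `node_meta`,
#'   `beat_labels`, provenance ids and `cfg`.
#' @export
build_graph <- function(record, aes, cfg = graph_config()) {
  validate_record(record)
  if (!length(record$beats)) stopf("record has no beats")
  fs <- record$fs

  rows <- list()
  for (b in seq_along(record$beats)) {
    beat <- record$beats[[b]]
    for (type in intersect(SEGMENT_TYPES, names(beat$segments))) {
      sg <- beat$segments[[type]]
      rows[[length(rows) + 1]] <- data.frame(
        type = type, beat = b,
        onset = sg[1] / fs, offset = sg[2] / fs,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  ord <- order(meta$onset)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL

  latent <- aes$QRS$latent_dim
  onehot <- matrix(0, nrow(meta), 3,
                   dimnames = list(NULL, paste0("is_", SEGMENT_TYPES)))
  emb <- matrix(0, nrow(meta), latent,
                dimnames = list(NULL, paste0("emb", seq_len(latent))))
  for (type in SEGMENT_TYPES) {
    idx <- which(meta$type == type)
    if (!length(idx)) next
    onehot[idx, paste0("is_", type)] <- 1
    S <- t(vapply(idx, function(i) {
      sg_samples <- record$samples[(round(meta$onset[i] * fs) + 1):
                                     round(meta$offset[i] * fs)]
      resample_to_fixed(sg_samples, aes[[type]]$L_in)
    }, numeric(aes[[type]]$L_in)))
    emb[idx, ] <- embed_segment(aes[[type]], S)
  }
  core <- cbind(onehot, width = meta$offset - meta$onset, emb)

  graph_from_meta(meta, core, cfg, beat_labels(record),
                  record$patient_id, record$record_id)
}

#' @rdname build_graph
#' @param records A list of `ecg_record`.
#' @export
build_graphs <- function(records, aes, cfg = graph_config()) {
  lapply(records, build_graph, aes = aes, cfg = cfg)
}

# Pooling windows: for QRS node at position n, k/j are the node-position
# offsets to the nearest preceding/following QRS node, truncated at graph
# boundaries to the number of available nodes. Returns the sparse pooling
# operator (B x M) plus the per-beat (k, j).
pool_matrix <- function(node_meta, c = 0.1, exclusive = FALSE) {
  qpos <- which(node_meta$type == "QRS")
  B <- length(qpos)
  if (B == 0) stopf("graph has no QRS nodes")
  M <- nrow(node_meta)
  ii <- jj <- ww <- list()
  kvec <- jvec <- integer(B)
  for (b in seq_len(B)) {
    n <- qpos[b]
    k <- if (b > 1) n - qpos[b - 1] else n - 1L
    j <- if (b < B) qpos[b + 1] - n else M - n
    if (exclusive) { k <- max(k - 1L, 0L); j <- max(j - 1L, 0L) }
    kvec[b] <- k; jvec[b] <- j
    i_rng <- (-k):j
    w <- pmax(1 - c * abs(i_rng), 0) / (1 + k + j)
    ii[[b]] <- rep(b, length(i_rng))
    jj[[b]] <- n + i_rng
    ww[[b]] <- w
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(B, M))
  list(P = P, k = kvec, j = jvec, qpos = qpos)
}

#' QRS-centered weighted average pooling
#'
#' Aggregates node features at the beat level around each QRS node `n`:
#' `pool(f_n) = 1/(1+k+j) * sum_{i=-k}^{j} (1 - c*|i|) f_{n+i}`, where `k`
#' and `j` are the node-position offsets to the nearest preceding and
#' following QRS nodes (truncated at the graph boundary to the available
#' nodes). Weights decay linearly with distance from the central QRS node and
#' are floored at 0 when `1 - c|i| < 0`; the normaliser `1/(1+k+j)` is kept
#' as printed regardless of flooring.
#'
#' @param H Node-feature matrix (M x F), rows in the node order of
#'   `node_meta`.
#' @param node_meta The `node_meta` data frame of an `ecg_graph`.
#' @param c Decay constant (>= 0).
#' @param exclusive If `TRUE`, exclude the neighbouring QRS nodes from the
#'   window.
#' @return A B x F matrix (one row per beat) with attributes `k` and `j`.
#' @export
qrs_centered_pool <- function(H, node_meta, c = 0.1, exclusive = FALSE) {
  if (c < 0) stopf("c must be >= 0")
  H <- as.matrix(H)
  if (nrow(H) != nrow(node_meta))
    stopf("H rows (%d) must match node_meta rows (%d)", nrow(H),
          nrow(node_meta))
  pm <- pool_matrix(node_meta, c, exclusive)
  out <- as.matrix(pm$P %*% H)
  attr(out, "k") <- pm$k
  attr(out, "j") <- pm$j
  out
}

#' Beat-level graph over QRS complexes
#'
#' One node per QRS complex, edges only between chronologically consecutive
#' QRS nodes, weighted from the RR interval (onset-to-onset difference of
#' consecutive QRS complexes) — by default transformed through
#' [edge_weight()], optionally the raw RR interval. Self-loops carry
#' weight 1. A single-beat graph has only its self-loop.
#'
#' @param graph An `ecg_graph`.
#' @param beat_features Optional matrix of per-beat features (rows aligned
#'   with QRS nodes), e.g. a [qrs_centered_pool()] result.
#' @param cfg A [graph_config()]; defaults to the one stored in `graph`.
#' @return An object of class `qrs_graph` with fields `X`, `A`, `onsets`.
#' @export
build_qrs_graph <- function(graph, beat_features = NULL, cfg = graph$cfg) {
  qidx <- which(graph$node_meta$type == "QRS")
  B <- length(qidx)
  if (B == 0) stopf("graph has no QRS nodes")
  if (!is.null(beat_features) && nrow(beat_features) != B)
    stopf("beat_features rows (%d) must match QRS count (%d)",
          nrow(beat_features), B)
  onsets <- graph$node_meta$onset[qidx]
  A <- diag(1, B)
  if (B > 1) {
    rri <- diff(onsets)
    w <- if (cfg$qrs_edge_mode == "raw") rri else
      edge_weight(rri, cfg$alpha_qrs %||% cfg$alpha,
                  cfg$delta0_qrs %||% cfg$delta0)
    for (i in seq_len(B - 1)) A[i, i + 1] <- A[i + 1, i] <- w[i]
  }
  structure(list(X = beat_features, A = A, onsets = onsets,
                 beat_labels = graph$beat_labels),
            class = "qrs_graph")
}

#' @export
print.ecg_graph <- function(x, ...) {
  cat(sprintf("<ecg_graph %s/%s: M=%d nodes, d=%d, %d beats (%s), edges=%s>\n",
              x$patient_id, x$record_id, nrow(x$X), x$d,
              length(x$beat_labels), paste(x$beat_labels, collapse = ""),
              x$cfg$edges))
  invisible(x)
}
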