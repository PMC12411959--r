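test_that("edge weights are logistic in the time gap", {
  expect_equal(edge_weight(0.3, alpha = 10, delta0 = 0.3), 0.5)
  expect_gt(edge_weight(0.1), edge_weight(0.2))
  expect_lt(edge_weight(5), 1e-8)
  expect_error(edge_weight(0.1, alpha = 0), "alpha")
  expect_error(edge_weight(-0.1), "delta_t")
})

test_that("graphs enumerate nodes and edges by the construction rules", {
  rec <- pattern_record("NNN")
  g <- build_graph(rec, fix_aes())
  expect_equal(nrow(g$X), 9)          # 3 beats x (P, QRS, T)
  expect_equal(dim(g$X), c(9, 22))
  expect_equal(diag(g$A), rep(1, 9))
  # adjacent pairs all present
  for (i in 1:8) expect_gt(g$A[i, i + 1], 0)
  # QRS nodes sit at positions 2, 5, 8; window 5 connects all three pairs
  qpos <- which(g$node_meta$type == "QRS")
  expect_equal(qpos, c(2, 5, 8))
  expect_gt(g$A[2, 8], 0)
  # nothing else: count non-zero off-diagonal entries (8 adjacent + 3 QRS)
  expect_equal(sum(g$A[upper.tri(g$A)] > 0), 8 + 3)
  expect_equal(g$A, t(g$A))
})

test_that("QRS-QRS edges cover exactly the +/-2-position window", {
  rec <- pattern_record("NNNNNN")
  g <- build_graph(rec, fix_aes())
  qpos <- which(g$node_meta$type == "QRS")
  expect_length(qpos, 6)
  qq <- outer(seq_along(qpos), seq_along(qpos),
              function(a, b) g$A[cbind(qpos[a], qpos[b])] > 0)
  expected <- abs(outer(seq_along(qpos), seq_along(qpos), "-")) <= 2
  # adjacent-node rule never links two QRS nodes directly (P/T sit between)
  expect_equal(qq, expected)
})

test_that("graph size follows content and edges are translation invariant", {
  rec <- pattern_record("NNN")
  g <- build_graph(rec, fix_aes())
  rec2 <- rec
  rec2$beats[[2]]$segments$P <- NULL
  g2 <- build_graph(rec2, fix_aes())
  expect_equal(nrow(g2$X), nrow(g$X) - 1)
  # an untouched pair far from the removal keeps its weight
  expect_equal(g2$A[1, 2], g$A[1, 2])

  meta3 <- g$node_meta
  meta3$onset <- meta3$onset + 7.5
  meta3$offset <- meta3$offset + 7.5
  g3 <- ecgraphnet:::graph_from_meta(meta3, g$X[, 1:20], g$cfg,
                                     g$beat_labels, "p", "r")
  expect_equal(g3$A, g$A)
  expect_equal(g3$X, g$X, ignore_attr = TRUE)
})

test_that("QRS-centered pooling matches the printed formula", {
  # worked scalar case: c = 0.1, k = j = 2, features 1..5 centered at 3
  meta <- data.frame(type = c("QRS", "T", "QRS", "T", "QRS"),
                     beat = c(1, 1, 2, 2, 3),
                     onset = 1:5, offset = 1:5 + 0.5)
  H <- matrix(1:5, ncol = 1)
  out <- qrs_centered_pool(H, meta, c = 0.1)
  expect_equal(out[2, 1], 2.64)
  expect_equal(attr(out, "k")[2], 2)
  expect_equal(attr(out, "j")[2], 2)

  # isolated QRS node: output equals its own features for any c
  meta1 <- meta[3, , drop = FALSE]
  expect_equal(qrs_centered_pool(matrix(4.2), meta1, c = 0.7)[1, 1], 4.2)

  # c = 0 over identical vectors: plain average returns the vector
  meta7 <- data.frame(type = c("P", "T", "P", "QRS", "T", "P", "T"),
                      beat = 1, onset = 1:7, offset = 1:7 + 0.1)
  meta7$type[4] <- "QRS"
  v <- c(2, -1, 0.5)
  H7 <- matrix(rep(v, each = 7), 7)
  expect_equal(unname(qrs_centered_pool(H7, meta7, c = 0)[1, ]), v)
})

test_that("pooling agrees with a naive loop oracle on random instances", {
  naive_pool <- function(H, meta, c) {
    qpos <- which(meta$type == "QRS")
    M <- nrow(meta)
    out <- matrix(0, length(qpos), ncol(H))
    for (b in seq_along(qpos)) {
      n <- qpos[b]
      k <- if (b > 1) n - qpos[b - 1] else n - 1
      j <- if (b < length(qpos)) qpos[b + 1] - n else M - n
      acc <- 0
      for (i in (-k):j)
        acc <- acc + max(1 - c * abs(i), 0) * H[n + i, ]
      out[b, ] <- acc / (1 + k + j)
    }
    out
  }
  set.seed(31)
  for (rep in 1:100) {
    M <- sample(3:30, 1)
    types <- sample(c("P", "QRS", "T"), M, replace = TRUE)
    if (!any(types == "QRS")) types[sample(M, 1)] <- "QRS"
    meta <- data.frame(type = types, beat = 1,
                       onset = seq_len(M), offset = seq_len(M) + 0.4)
    H <- matrix(rnorm(M * 4), M)
    cc <- runif(1, 0, 0.6)
    expect_equal(qrs_centered_pool(H, meta, c = cc),
                 naive_pool(H, meta, cc), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("pooling weights decay monotonically away from the central QRS", {
  meta <- data.frame(type = c("P", "T", "P", "QRS", "T", "P", "T", "QRS"),
                     beat = c(1, 1, 1, 1, 1, 2, 2, 2),
                     onset = 1:8, offset = 1:8 + 0.1)
  meta$type[4] <- "QRS"; meta$type[8] <- "QRS"
  pm <- ecgraphnet:::pool_matrix(meta, c = 0.2)
  for (b in seq_len(nrow(pm$P))) {
    row <- pm$P[b, ]
    nz <- which(row != 0)
    center <- pm$qpos[b]
    offs <- abs(nz - center)
    w <- row[nz]
    expect_true(all(diff(w[order(offs)]) <= 1e-12))
  }
})

test_that("the beat-level graph is a weighted path over QRS nodes", {
  rec <- pattern_record("NNNNNNNN",
                        morphology_config(rr_jitter = 0, width_jitter = 0))
  g <- build_graph(rec, fix_aes())
  q <- build_qrs_graph(g)
  expect_equal(dim(q$A), c(8, 8))
  expect_equal(diag(q$A), rep(1, 8))
  offdiag <- which(q$A > 0 & row(q$A) != col(q$A), arr.ind = TRUE)
  expect_true(all(abs(offdiag[, 1] - offdiag[, 2]) == 1))
  expect_equal(nrow(offdiag), 14)  # 7 consecutive edges, both triangles
  # uniform RR (no jitter): all consecutive weights equal
  w <- q$A[cbind(1:7, 2:8)]
  expect_equal(max(w) - min(w), 0, tolerance = 1e-12)

  # premature beat shortens its RR, raising the corresponding edge weight
  rec2 <- pattern_record("NNSN")
  g2 <- build_graph(rec2, fix_aes())
  q2 <- build_qrs_graph(g2)
  expect_gt(q2$A[2, 3], q2$A[1, 2])
})
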