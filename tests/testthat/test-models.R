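test_that("gc_forward reproduces hand-evaluated propagation", {
  H <- matrix(c(1, -2, 3, 0.5), 2)
  # identity adjacency: propagation collapses to the rectifier
  expect_equal(gc_forward(H, diag(2), diag(2)), pmax(H, 0))

  # 2-node hand case: A = [[1, .5], [.5, 1]], D = 1.5 on both nodes,
  # Ahat = A / 1.5; H = (1, -2), W = 2
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  H1 <- matrix(c(1, -2), 2)
  W <- matrix(2)
  expected <- pmax((A / 1.5) %*% (H1 * 2), 0)
  expect_equal(gc_forward(H1, A, W), expected)

  expect_error(gc_forward(H1, diag(3), W), "square")
  expect_equal(nrow(gc_forward(fix_graphs()[[1]]$X, fix_graphs()[[1]]$A,
                               diag(22))),
               nrow(fix_graphs()[[1]]$X))
})

test_that("forward pass yields one probability row per beat for any size", {
  graphs <- fix_graphs()
  fit <- graphnet_fit(graphs, graphnet_config(ch_pqrst = c(16, 16),
                                              ch_qrs = c(16, 16), fc = 16),
                      seed = 5, max_epochs = 5)
  morph <- morphology_config(rr_jitter = 0, mean_rr = 0.47,
                             p_width = 0.06, qrs_width = 0.06,
                             t_width = 0.10, pr_gap = 0.03, st_gap = 0.05)
  sizes <- c(3, 8, 20)
  for (n in sizes) {
    rec <- pattern_record(strrep("N", n), morph)
    expect_length(rec$beats, n)
    g <- build_graph(rec, fix_aes())
    pr <- predict(fit, g, type = "prob")
    expect_equal(nrow(pr), n)
    expect_true(all(pr >= 0))
    expect_equal(rowSums(pr), rep(1, n))
  }
})

test_that("training and prediction are deterministic under a fixed seed", {
  graphs <- fix_graphs()
  cfg <- graphnet_config(ch_pqrst = c(12, 12), ch_qrs = c(12, 12), fc = 12)
  f1 <- graphnet_fit(graphs[1:20], cfg, val = graphs[31:36], seed = 9,
                     max_epochs = 8)
  f2 <- graphnet_fit(graphs[1:20], cfg, val = graphs[31:36], seed = 9,
                     max_epochs = 8)
  expect_identical(f1$params, f2$params)
  p1 <- predict(f1, graphs[[33]])
  expect_identical(p1, predict(f1, graphs[[33]]))
})

test_that("predictions are invariant to time translation of the record", {
  graphs <- fix_graphs()
  fit <- graphnet_fit(graphs, graphnet_config(ch_pqrst = c(16, 16),
                                              ch_qrs = c(16, 16), fc = 16),
                      seed = 5, max_epochs = 5)
  g <- graphs[[4]]
  meta2 <- g$node_meta
  meta2$onset <- meta2$onset + 123.4
  meta2$offset <- meta2$offset + 123.4
  g2 <- ecgraphnet:::graph_from_meta(meta2, g$X[, 1:20], g$cfg,
                                     g$beat_labels, g$patient_id,
                                     g$record_id)
  expect_equal(predict(fit, g2), predict(fit, g), tolerance = 1e-10)
})

test_that("the nested architectures collapse onto each other structurally", {
  graphs <- fix_graphs()[1:8]
  cfg_full <- graphnet_config("ecg_graphnet", ch_pqrst = c(16, 16),
                              ch_qrs = integer(0), skip = "none", fc = 16)
  cfg_pqrst <- graphnet_config("pqrst", ch_pqrst = c(16, 16), fc = 16)
  f_full <- graphnet_fit(graphs, cfg_full, seed = 3, max_epochs = 6)
  f_pqrst <- graphnet_fit(graphs, cfg_pqrst, seed = 3, max_epochs = 6)
  expect_equal(predict(f_full, graphs[[1]]), predict(f_pqrst, graphs[[1]]),
               tolerance = 1e-10)
})

test_that("every architecture fits an easy training set to high accuracy", {
  graphs <- fix_graphs()
  labels <- lapply(graphs, `[[`, "beat_labels")
  for (arch in c("pqrst", "pqrst_qrs", "ecg_graphnet")) {
    cfg <- graphnet_config(arch, ch_pqrst = c(32, 32), ch_qrs = c(32, 32),
                           fc = 32)
    fit <- graphnet_fit(graphs, cfg, seed = 13, lr = 5e-3, max_epochs = 250,
                        patience = 250)
    rep <- evaluate_beats(predict(fit, graphs, type = "class"), labels)
    expect_gt(rep$acc, 0.95)
  }
})
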