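# Shared fixtures, built once per test run and memoised. The "easy" regime
# strengthens the class-conditional contrasts (wide V QRS, strongly
# premature S beats, low noise) so learning-based checks converge quickly.

easy_morph <- function() {
  morphology_config(v_qrs_widen = 2.2, s_prematurity = 0.45, noise_sd = 0.01)
}

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fix_dataset <- function() memo("ds", generate_dataset(12, 3, seed = 42,
                                                      morph = easy_morph()))

fix_aes <- function() memo("aes", fit_segment_embeddings(fix_dataset(),
                                                         seed = 7,
                                                         epochs = 50))

fix_graphs <- function() memo("graphs", build_graphs(fix_dataset(),
                                                     fix_aes()))

extract_qrs_segments <- function(records) {
  ecgraphnet:::extract_segments(records, "QRS")
}

# one rendered record from an explicit pattern, no RR jitter
pattern_record <- function(pattern, morph = morphology_config(rr_jitter = 0),
                           seed = 5) {
  sched <- generate_beat_schedule(pattern, morph, seed = seed)
  render_record(sched, morph, seed = seed + 1)
}
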