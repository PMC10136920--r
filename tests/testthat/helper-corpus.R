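# corpora are expensive to simulate; cache them per parameter set for the
# duration of the test run
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(n_normal = 45, n_apnea = 45, seed = 1L) {
  key <- paste(n_normal, n_apnea, seed, sep = "_")
  if (is.null(.corpus_cache[[key]])) {
    .corpus_cache[[key]] <- generate_corpus(n_normal = n_normal,
                                            n_apnea = n_apnea, seed = seed)
  }
  .corpus_cache[[key]]
}

make_peak_train <- function(idx, fs = 100, amps = NULL) {
  idx <- as.integer(idx)
  if (is.null(amps)) amps <- rep(1, length(idx))
  structure(list(peak_indices = idx, peak_amplitudes = amps,
                 sampling_rate_hz = fs),
            class = "peak_train")
}
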