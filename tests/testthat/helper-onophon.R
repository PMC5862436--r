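# shared fixtures: the default feature table and small synthetic corpora
ono_table <- load_feature_table()

small_corpus <- function(n_speakers = 12L, ...) {
  generate_corpus(synth_config(n_speakers = n_speakers, ...))
}

# a tiny well-separated 2-class cloud for classifier tests
make_clouds <- function(n = 40, p = 4, sep = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, mean = sep), n))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(c("a", "b"), each = n)))
}
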