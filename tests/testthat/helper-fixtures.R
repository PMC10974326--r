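# Shared fixtures, built in code. The tiny dataset (2 participants x 2
# positions x 20 s) is cached for the session so each test file does not
# re-simulate it.

.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- simulate_dataset(
      n_participants = 2, positions = c("prone", "back"),
      duration_s = 20, seed = 42
    )
  }
  .fixture_cache$tiny
}

tiny_features <- function() {
  if (is.null(.fixture_cache$tiny_feats)) {
    .fixture_cache$tiny_feats <- build_feature_matrix(tiny_dataset())
  }
  .fixture_cache$tiny_feats
}

# Linearly separable two-cluster toy problem: positives near all-ones,
# negatives near all-zeros, with a wide margin relative to the spread.
separable_toy <- function(n_per_class = 50, sd = 0.05, seed = 11) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per_class * 12, mean = 1, sd = sd), ncol = 12),
    matrix(rnorm(n_per_class * 12, mean = 0, sd = sd), ncol = 12)
  )
  colnames(X) <- feature_names()
  list(X = X, y = rep(c(1L, 0L), each = n_per_class))
}
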