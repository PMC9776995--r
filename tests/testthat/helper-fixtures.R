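# Shared small fixtures, generated in code at test time.

# Short-sequence separable dataset: fast to featurize, still cleanly
# separated at delta 0.9 (composition drives the moment features).
small_sep_features <- local({
  cache <- new.env(parent = emptyenv())
  function(n_per_class = 20, delta = 0.9, seed = 7) {
    key <- paste(n_per_class, delta, seed, sep = "_")
    if (is.null(cache[[key]])) {
      ds <- gen_separable_dataset(n_per_class, delta,
                                  length_range = c(80L, 100L), seed = seed)
      cache[[key]] <- extract_feature_table(ds)
    }
    cache[[key]]
  }
})

# Random (label-uninformative) feature table for fold-mechanics tests.
random_features <- function(n, seed = 1) {
  set.seed(seed)
  labels <- sample(RCCC_CLASSES, n, replace = TRUE)
  # ensure all three classes appear
  labels[1:3] <- RCCC_CLASSES
  out <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                    M1 = rnorm(n), M2 = abs(rnorm(n)), M3 = rnorm(n),
                    M4 = abs(rnorm(n)), Min = rnorm(n), Max = rnorm(n),
                    label = labels, stringsAsFactors = FALSE)
  out$Max <- out$Min + abs(out$Max)
  out
}

tiny_references <- function() {
  data.frame(id = c("g1", "g2"),
             sequence = c("ACGTACGTAC", "TTTTGGGGCC"),
             stringsAsFactors = FALSE)
}
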