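test_that("apply_mutation substitutes exactly one base", {
  ref <- data.frame(id = "g1", sequence = "ACGT", stringsAsFactors = FALSE)
  mut <- data.frame(gene_id = "g1", position = 2L, ref_base = "C",
                    alt_base = "T", class_label = "kidney_tumor_driver",
                    stringsAsFactors = FALSE)
  s <- apply_mutation(ref, mut)
  expect_equal(s$sequence, "ATGT")
  expect_equal(s$label, "kidney_tumor_driver")
  expect_match(s$sample_id, "g1_c\\.2C>T")

  # involution: applying the reverse substitution restores the reference
  back <- apply_mutation(data.frame(id = "g1", sequence = s$sequence),
                         data.frame(gene_id = "g1", position = 2L,
                                    ref_base = "T", alt_base = "C",
                                    class_label = "unknown"))
  expect_equal(back$sequence, "ACGT")
})

test_that("apply_mutation enforces its contracts", {
  ref <- data.frame(id = "g1", sequence = "ACGT", stringsAsFactors = FALSE)
  bad_base <- data.frame(gene_id = "g1", position = 2L, ref_base = "G",
                         alt_base = "T", class_label = "unknown")
  expect_error(apply_mutation(ref, bad_base), "mismatch")
  expect_warning(out <- apply_mutation(ref, bad_base, strict = FALSE),
                 "skipping")
  expect_null(out)
  expect_error(apply_mutation(ref, transform(bad_base, position = 9L)),
               "out of range")
  expect_error(apply_mutation(ref, transform(bad_base, gene_id = "g2")),
               "gene_id mismatch")
})

test_that("apply_mutation changes exactly one position (property)", {
  set.seed(11)
  refs <- gen_references(10, c(30, 60), seed = 11)
  catalog <- gen_catalog(refs, c(4L, 3L, 3L), seed = 11)
  for (i in seq_len(nrow(catalog))) {
    ref <- refs[refs$id == catalog$gene_id[i], ]
    s <- apply_mutation(ref, catalog[i, ])
    a <- strsplit(ref$sequence, "")[[1]]
    b <- strsplit(s$sequence, "")[[1]]
    expect_equal(sum(a != b), 1)
    expect_equal(which(a != b), catalog$position[i])
  }
})

test_that("build_benchmark follows catalog order and handles skips", {
  refs <- tiny_references()
  catalog <- data.frame(
    gene_id = c("g1", "g2", "g1"), position = c(1L, 2L, 3L),
    ref_base = c("A", "T", "G"), alt_base = c("G", "A", "C"),
    class_label = c("kidney_tumor_driver", "other_tumor_driver", "unknown"),
    stringsAsFactors = FALSE)
  bench <- build_benchmark(refs, catalog)
  expect_equal(nrow(bench), 3)
  expect_equal(bench$label, catalog$class_label)

  ghost <- transform(catalog[1, ], gene_id = "gX")
  expect_error(build_benchmark(refs, ghost), "gX")
  expect_warning(none <- build_benchmark(refs, ghost, strict = FALSE),
                 "not among")
  expect_equal(nrow(none), 0)
  expect_equal(nrow(build_benchmark(refs, catalog[0, ])), 0)
})

test_that("redundancy_filter keeps non-redundant representatives", {
  mk <- function(...) {
    seqs <- c(...)
    data.frame(sample_id = paste0("s", seq_along(seqs)), sequence = seqs,
               label = "unknown", stringsAsFactors = FALSE)
  }
  expect_equal(nrow(redundancy_filter(mk("ACGTACGT", "ACGTACGT"), 0.7)), 1)
  expect_equal(nrow(redundancy_filter(mk("AAAA", "TTTT"), 0.7)), 2)
  # hand count: AAAAAAAAAA vs AAAAAAAATT share 8/10 positions = 0.8 >= 0.7
  surv <- redundancy_filter(mk("AAAAAAAAAA", "AAAAAAAATT", "TTTTTTTTTT"), 0.7)
  expect_equal(nrow(surv), 2)
  expect_setequal(surv$sequence, c("AAAAAAAAAA", "TTTTTTTTTT"))
  expect_error(redundancy_filter(mk("AAAA"), 0), "threshold")
  expect_error(redundancy_filter(mk("AAAA"), 1.2), "threshold")
})

test_that("redundancy_filter is idempotent and exact-duplicate-only at 1.0", {
  set.seed(5)
  samples <- gen_separable_dataset(6, 0.3, c(20, 40), seed = 5)
  once <- redundancy_filter(samples, 0.7)
  expect_identical(redundancy_filter(once, 0.7), once)

  dup <- rbind(samples, transform(samples[1, ], sample_id = "copy"))
  at1 <- redundancy_filter(dup, 1.0)
  expect_equal(nrow(at1), nrow(dup) - 1)
})

test_that("stratified_split hits the 70:30 ratio and stratifies", {
  ds <- random_features(100, seed = 3)
  ds$label <- rep(RCCC_CLASSES, times = c(40, 30, 30))
  split <- stratified_split(ds, 0.7, seed = 9)
  expect_equal(nrow(split$train), 70)
  expect_equal(nrow(split$test), 30)
  expect_equal(unname(table(split$train$label)[RCCC_CLASSES]),
               c(28L, 21L, 21L), ignore_attr = TRUE)

  # determinism and partition invariants over random inputs
  for (seed in 1:5) {
    n <- sample(20:80, 1)
    ds <- random_features(n, seed = seed + 100)
    s1 <- stratified_split(ds, 0.7, seed = seed)
    s2 <- stratified_split(ds, 0.7, seed = seed)
    expect_identical(s1$train$sample_id, s2$train$sample_id)
    expect_length(intersect(s1$train$sample_id, s1$test$sample_id), 0)
    expect_setequal(c(s1$train$sample_id, s1$test$sample_id), ds$sample_id)
    for (cl in RCCC_CLASSES) {
      total_cl <- sum(ds$label == cl)
      expect_lte(abs(sum(s1$train$label == cl) - 0.7 * total_cl), 1.5)
    }
  }
  expect_error(stratified_split(ds[0, ], 0.7, 1), "empty")
  # smallest stratum: 2 samples of one class at fraction 0.5
  two <- random_features(6, seed = 1)
  two$label <- rep(RCCC_CLASSES, each = 2)
  s <- stratified_split(two, 0.5, seed = 1)
  expect_equal(nrow(s$train), 3)
  expect_equal(unname(table(s$train$label)), c(1L, 1L, 1L), ignore_attr = TRUE)
})
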