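# Synthetic fixtures: random reference sequences, consistent mutation
# catalogs over them, and three-class datasets whose per-class base
# composition diverges by a controllable separation parameter. These stand
# in for the real driver-mutation catalog + reference-sequence inputs so
# the whole pipeline can be exercised without downloads.

.sample_dna <- function(length, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate random reference sequences
#'
#' @param count number of references (>= 1).
#' @param length_range integer pair (min, max) of sequence lengths.
#' @param seed integer seed.
#' @return data.frame with `id` ("gene_0001", ...) and `sequence`, as from
#'   [read_fasta()].
#' @export
gen_references <- function(count, length_range = c(800L, 1000L), seed = 1L) {
  if (count < 1) stop("count must be >= 1")
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            length_range[1] >= 1)
  set.seed(derive_seed(seed, 41L))
  lens <- sample(length_range[1]:length_range[2], count, replace = TRUE)
  data.frame(
    id = sprintf("gene_%04d", seq_len(count)),
    sequence = vapply(lens, .sample_dna, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Generate a mutation catalog consistent with a set of references
#'
#' Every record names an existing gene, a valid 1-based position, the true
#' base at that position as `ref_base`, and a different `alt_base`; class
#' labels are distributed according to `counts_per_class`. Generated
#' (gene, position) pairs are unique, so each record yields a distinct
#' sample.
#'
#' @param references data.frame from [gen_references()] / [read_fasta()].
#' @param counts_per_class integer triple: records per class, in canonical
#'   class order.
#' @param seed integer seed.
#' @param corrupt if TRUE, the first record's `ref_base` is deliberately
#'   wrong (negative control for strict mutation application).
#' @return mutation catalog data.frame (see [read_mutation_catalog()]).
#' @export
gen_catalog <- function(references, counts_per_class = c(5L, 5L, 5L),
                        seed = 1L, corrupt = FALSE) {
  stopifnot(length(counts_per_class) == 3, all(counts_per_class >= 0))
  total <- sum(counts_per_class)
  lens <- nchar(references$sequence)
  if (total > sum(lens)) {
    stop("requested ", total, " mutations but only ", sum(lens),
         " positions are available")
  }
  set.seed(derive_seed(seed, 43L))
  # sample distinct (gene, position) pairs from the pooled position space
  pool_gene <- rep.int(seq_len(nrow(references)), lens)
  pool_pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  pick <- sample.int(length(pool_gene), total)
  gi <- pool_gene[pick]
  pos <- pool_pos[pick]
  ref <- substr(references$sequence[gi], pos, pos)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  labels <- rep(RCCC_CLASSES, times = counts_per_class)
  if (corrupt && total >= 1) {
    ref[1] <- setdiff(bases, c(ref[1], alt[1]))[1]
  }
  data.frame(gene_id = references$id[gi], position = pos, ref_base = ref,
             alt_base = alt, class_label = labels, stringsAsFactors = FALSE)
}

# Per-class base-probability vectors: a uniform background shifted by delta
# toward a class-specific corner (class 1 A-rich, class 2 T-rich, class 3
# G-rich). delta = 0 makes the classes exchangeable; delta = 1 makes each
# class almost pure in its favored base.
.class_base_probs <- function(delta) {
  stopifnot(delta >= 0, delta <= 1)
  favored <- c(kidney_tumor_driver = "A", other_tumor_driver = "T",
               unknown = "G")
  bases <- c("A", "C", "G", "T")
  lapply(favored, function(b) {
    p <- rep(0.25, 4)
    names(p) <- bases
    p[b] <- 0.25 + 0.75 * delta
    p[bases != b] <- (1 - p[b]) / 3
    p
  })
}

#' Generate a three-class dataset with controllable class separability
#'
#' Sequences of class c are drawn i.i.d. from a class-specific base
#' composition diverging from uniform by `delta`. In the strong-separation
#' regime (`delta > 0.5`) all sequences share a fixed length (the midpoint
#' of `length_range`) so matrix size does not act as a confounding feature;
#' otherwise lengths are uniform over the range.
#'
#' @param n_per_class samples per class.
#' @param delta separation parameter in \[0, 1\].
#' @param length_range integer pair (min, max).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `sequence`, `label`.
#' @export
gen_separable_dataset <- function(n_per_class = 100L, delta = 0.9,
                                  length_range = c(800L, 1000L), seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            length_range[1] >= 1)
  probs <- .class_base_probs(delta)
  set.seed(derive_seed(seed, 47L))
  fixed_len <- delta > 0.5
  mid <- floor((length_range[1] + length_range[2]) / 2)
  rows <- lapply(seq_along(RCCC_CLASSES), function(ci) {
    lens <- if (fixed_len) rep(mid, n_per_class) else
      sample(length_range[1]:length_range[2], n_per_class, replace = TRUE)
    data.frame(
      sample_id = sprintf("synth_%s_%04d", RCCC_CLASSES[ci], seq_len(n_per_class)),
      sequence = vapply(lens, .sample_dna, character(1), probs = probs[[ci]]),
      label = RCCC_CLASSES[ci],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
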