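# Benchmark construction: apply catalog mutations to reference sequences,
# drop redundant sequences (greedy identity clustering), stratified splitting.

#' Apply a single-nucleotide substitution to a reference sequence
#'
#' @param reference one-row data.frame (or list) with `id` and `sequence`.
#' @param mutation one-row data.frame (or list) with `gene_id`, `position`
#'   (1-based), `ref_base`, `alt_base`, `class_label`.
#' @param strict if TRUE (default) a reference-base mismatch is an error;
#'   if FALSE the mutation is skipped with a warning and NULL is returned.
#' @return one-row data.frame with `sample_id`, `sequence`, `label`, or NULL
#'   when skipped in non-strict mode.
#' @export
apply_mutation <- function(reference, mutation, strict = TRUE) {
  if (!identical(as.character(reference$id), as.character(mutation$gene_id))) {
    stop("gene_id mismatch: reference '", reference$id,
         "' vs mutation '", mutation$gene_id, "'")
  }
  seq <- as.character(reference$sequence)
  pos <- as.integer(mutation$position)
  if (is.na(pos) || pos < 1 || pos > nchar(seq)) {
    stop("mutation position ", mutation$position, " out of range for gene '",
         reference$id, "' (length ", nchar(seq), ")")
  }
  have <- substr(seq, pos, pos)
  if (!identical(have, as.character(mutation$ref_base))) {
    msg <- paste0("reference base mismatch at ", reference$id, ":", pos,
                  " (sequence has '", have, "', catalog says '",
                  mutation$ref_base, "')")
    if (strict) stop(msg)
    warning(msg, "; skipping")
    return(NULL)
  }
  substr(seq, pos, pos) <- as.character(mutation$alt_base)
  data.frame(
    sample_id = paste0(reference$id, "_c.", pos, mutation$ref_base, ">",
                       mutation$alt_base),
    sequence = seq,
    label = as.character(mutation$class_label),
    stringsAsFactors = FALSE
  )
}

#' Build the labeled benchmark from references plus a mutation catalog
#'
#' Applies every catalog row to its reference (catalog order preserved).
#' Duplicate sample ids (identical mutation listed twice) are suffixed to
#' keep ids unique.
#'
#' @param references data.frame from [read_fasta()].
#' @param catalog data.frame from [read_mutation_catalog()].
#' @param strict if TRUE, unresolvable genes and base mismatches are errors;
#'   if FALSE they are skipped with warnings.
#' @return data.frame with `sample_id`, `sequence`, `label`.
#' @export
build_benchmark <- function(references, catalog, strict = TRUE) {
  idx <- match(catalog$gene_id, references$id)
  if (strict && anyNA(idx)) {
    stop("catalog names gene(s) absent from the references: ",
         paste(unique(catalog$gene_id[is.na(idx)]), collapse = ", "))
  }
  out <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    if (is.na(idx[[i]])) {
      warning("skipping catalog row ", i, ": gene '", catalog$gene_id[[i]],
              "' not among the references")
      next
    }
    out[[i]] <- apply_mutation(references[idx[[i]], ], catalog[i, ],
                               strict = strict)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(sample_id = character(), sequence = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  dup <- duplicated(res$sample_id)
  if (any(dup)) {
    res$sample_id <- make.unique(res$sample_id, sep = "_dup")
  }
  rownames(res) <- NULL
  res
}

# Ungapped identity of the shorter sequence laid onto the start of the
# longer: matching positions / length of the shorter.
.pair_identity <- function(a, b) {
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- strsplit(substr(a, 1, nchar(b)), "")[[1]]
  lb <- strsplit(b, "")[[1]]
  sum(la == lb) / length(lb)
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Greedy longest-first clustering in the style of CD-HIT: samples are
#' visited by decreasing length; a sample is kept as a new cluster
#' representative unless its identity to an already-kept representative is
#' at or above `threshold`. Identity is the fraction of matching positions
#' in an ungapped comparison of the shorter sequence onto the longer one.
#'
#' @param samples data.frame with `sample_id`, `sequence`, `label`.
#' @param threshold identity threshold in (0, 1]; default 0.7.
#' @return the surviving representatives, in retained (length-sorted) order.
#' @export
redundancy_filter <- function(samples, threshold = 0.7) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]")
  }
  if (nrow(samples) <= 1) return(samples)
  ord <- order(-nchar(samples$sequence))   # stable: ties keep input order
  sorted <- samples[ord, , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(sorted))) {
    redundant <- FALSE
    for (j in keep) {
      if (.pair_identity(sorted$sequence[[i]], sorted$sequence[[j]]) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) keep <- c(keep, i)
  }
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Per class, `round(train_fraction * class size)` samples are assigned to
#' the training partition after a seeded shuffle; the largest class is then
#' adjusted by at most one sample so the global training count equals
#' `round(train_fraction * n)`.
#'
#' @param samples data.frame with `sample_id` and `label` (plus any payload
#'   columns, carried along).
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with elements `train`, `test` (row subsets of `samples`) and
#'   `seed`.
#' @export
stratified_split <- function(samples, train_fraction = 0.7, seed = 1L) {
  if (nrow(samples) == 0) stop("cannot split an empty sample set")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  rnd <- function(x) floor(x + 0.5)  # deterministic half-up, not banker's
  classes <- unique(samples$label)
  target_total <- rnd(train_fraction * nrow(samples))
  set.seed(derive_seed(seed, 1L))
  train_idx <- integer(0)
  per_class <- lapply(classes, function(cl) which(samples$label == cl))
  names(per_class) <- classes
  n_train <- vapply(per_class, function(ix) rnd(train_fraction * length(ix)), double(1))
  excess <- sum(n_train) - target_total
  if (excess != 0) {
    big <- names(per_class)[which.max(vapply(per_class, length, integer(1)))]
    n_train[[big]] <- n_train[[big]] - excess
  }
  for (cl in classes) {
    ix <- per_class[[cl]]
    shuffled <- ix[sample.int(length(ix))]
    train_idx <- c(train_idx, shuffled[seq_len(n_train[[cl]])])
  }
  train_idx <- sort(train_idx)
  list(train = samples[train_idx, , drop = FALSE],
       test = samples[setdiff(seq_len(nrow(samples)), train_idx), , drop = FALSE],
       seed = seed)
}
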