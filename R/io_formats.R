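# On-disk formats: FASTA references, mutation-catalog CSV, feature-table CSV.
# One CSV dialect throughout: comma-separated, header row, UTF-8, "." decimal.

#' Read a FASTA file of reference sequences
#'
#' Sequences are upper-cased; wrapped lines are concatenated. Characters
#' outside A/C/G/T (ambiguity codes such as N) are retained and handled at
#' encoding time.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `sequence` (one row per record,
#'   input order preserved). An empty file yields zero rows.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[[1]], ">")) {
    stop("malformed FASTA: sequence data before the first '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("malformed FASTA: empty sequence under header(s): ",
         paste(ids[empty], collapse = ", "))
  }
  data.frame(id = unname(ids), sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records data.frame with columns `id` and `sequence` (a `sample_id`
#'   column is accepted in place of `id`).
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  id_col <- if ("id" %in% names(records)) "id" else "sample_id"
  stopifnot(id_col %in% names(records), "sequence" %in% names(records))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records[[id_col]]
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a mutation catalog CSV
#'
#' Expected columns: `gene_id`, `position` (1-based, within the named gene's
#' sequence), `ref`, `alt`, `label`. Every row either yields a record or a
#' located error; rows are never silently dropped.
#'
#' @param path path to the catalog CSV.
#' @return data.frame with columns `gene_id`, `position` (integer),
#'   `ref_base`, `alt_base`, `class_label`.
#' @export
read_mutation_catalog <- function(path) {
  if (!file.exists(path)) stop("mutation catalog not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("gene_id", "position", "ref", "alt", "label")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("mutation catalog is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(data.frame(gene_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      class_label = character(), stringsAsFactors = FALSE))
  }
  pos <- suppressWarnings(as.integer(raw$position))
  num <- suppressWarnings(as.numeric(raw$position))
  bad <- sort(unique(c(which(is.na(pos) | pos < 1 | num != round(num)),
                       which(is.na(num)))))
  if (length(bad) > 0) {
    stop("catalog row ", bad[[1]], ": position '", raw$position[bad[[1]]],
         "' is not a positive integer")
  }
  ref <- toupper(trimws(raw$ref))
  alt <- toupper(trimws(raw$alt))
  ok_base <- function(b) b %in% c("A", "C", "G", "T")
  bad <- which(!ok_base(ref) | !ok_base(alt))
  if (length(bad) > 0) {
    stop("catalog row ", bad[[1]], ": ref/alt must be single bases in A,C,G,T (got '",
         ref[bad[[1]]], "'/'", alt[bad[[1]]], "')")
  }
  bad <- which(ref == alt)
  if (length(bad) > 0) {
    stop("catalog row ", bad[[1]], ": ref and alt base are identical ('",
         ref[bad[[1]]], "')")
  }
  labels <- tryCatch(normalize_labels(raw$label), error = function(e) {
    key <- tolower(trimws(raw$label))
    bad <- which(!key %in% names(.label_aliases))
    stop("catalog row ", bad[[1]], ": ", conditionMessage(e))
  })
  data.frame(gene_id = raw$gene_id, position = pos, ref_base = ref,
             alt_base = alt, class_label = labels, stringsAsFactors = FALSE)
}

.feature_cols <- c("M1", "M2", "M3", "M4", "Min", "Max")

.validate_feature_table <- function(rows) {
  needed <- c("sample_id", .feature_cols)
  missing <- setdiff(needed, names(rows))
  if (length(missing) > 0) {
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.matrix(rows[, .feature_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (nrow(rows) > 0 && any(!is.finite(vals))) {
    stop("feature table contains non-finite values")
  }
  invisible(rows)
}

#' Write a feature table CSV
#'
#' Column order is fixed: `sample_id, M1, M2, M3, M4, Min, Max, label`.
#' Values round-trip through [read_feature_table()] to at least 12
#' significant digits.
#'
#' @param rows data.frame with `sample_id`, the six feature columns, and an
#'   optional `label` column.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(rows, path) {
  .validate_feature_table(rows)
  out <- data.frame(sample_id = as.character(rows$sample_id),
                    stringsAsFactors = FALSE)
  for (cn in .feature_cols) {
    # fixed 17-significant-digit formatting => byte-identical reruns and
    # lossless double round-trip
    out[[cn]] <- sprintf("%.17g", as.numeric(rows[[cn]]))
  }
  out$label <- if ("label" %in% names(rows)) as.character(rows$label) else ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path path written by [write_feature_table()] (or matching its schema).
#' @return data.frame with `sample_id`, the six numeric feature columns, and
#'   `label` (NA where absent).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    return(data.frame(sample_id = character(),
                      M1 = double(), M2 = double(), M3 = double(),
                      M4 = double(), Min = double(), Max = double(),
                      label = character(), stringsAsFactors = FALSE))
  }
  .validate_feature_table(raw)
  out <- data.frame(sample_id = as.character(raw$sample_id),
                    stringsAsFactors = FALSE)
  for (cn in .feature_cols) out[[cn]] <- as.numeric(raw[[cn]])
  lab <- if ("label" %in% names(raw)) as.character(raw$label) else NA_character_
  lab[!is.na(lab) & !nzchar(lab)] <- NA_character_
  out$label <- if (all(is.na(lab))) NA_character_ else normalize_labels_keep_na(lab)
  out
}

normalize_labels_keep_na <- function(labels) {
  out <- rep(NA_character_, length(labels))
  ok <- !is.na(labels)
  out[ok] <- normalize_labels(labels[ok])
  out
}

#' Write a sample_id -> label CSV
#' @param samples data.frame with `sample_id` and `label` columns.
#' @param path output path.
#' @export
write_labels <- function(samples, path) {
  stopifnot(all(c("sample_id", "label") %in% names(samples)))
  write.csv(samples[, c("sample_id", "label")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample_id -> label CSV
#' @param path path written by [write_labels()].
#' @export
read_labels <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("sample_id", "label") %in% names(raw)))
  raw$label <- normalize_labels(raw$label)
  raw
}
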