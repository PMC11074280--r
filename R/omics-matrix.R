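#' Annotated intensity matrix
#'
#' Container for a samples x features non-negative intensity matrix with
#' per-sample batch labels, class labels and pooled-QC flags. Missing values
#' are zero-coded by convention: LC-MS quantification software reports
#' non-detections as empty cells, and the whole pipeline treats 0 as
#' "missing / below detection".
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   All entries must be finite and non-negative; `NA` entries are set to 0.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to colnames of `values`).
#' @param batch_labels per-sample batch identifiers (coerced to character).
#' @param class_labels per-sample class labels (coerced to character).
#' @param qc_flags per-sample logical; `TRUE` marks pooled-QC injections.
#'
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `batch_labels`, `class_labels`,
#'   `qc_flags`.
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         batch_labels, class_labels,
                         qc_flags = rep(FALSE, nrow(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  batch_labels <- as.character(batch_labels)
  class_labels <- as.character(class_labels)
  qc_flags <- as.logical(qc_flags)
  values[is.na(values)] <- 0
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  for (nm in c("sample_ids", "batch_labels", "class_labels", "qc_flags")) {
    v <- get(nm)
    if (length(v) != n)
      stop(sprintf("%s has length %d but values has %d rows", nm, length(v), n))
  }
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length does not match number of columns")
  if (any(!is.finite(values)))
    stop("values contains non-finite entries")
  if (any(values < 0))
    stop("values contains negative entries; intensities must be >= 0")
  rownames(values) <- sample_ids
  colnames(values) <- feature_ids
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, batch_labels = batch_labels,
                 class_labels = class_labels, qc_flags = qc_flags),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  batches: %d (%s)\n", length(unique(x$batch_labels)),
              paste(utils::head(unique(x$batch_labels), 6), collapse = ", ")))
  cat(sprintf("  classes: %s\n",
              paste(unique(x$class_labels), collapse = ", ")))
  cat(sprintf("  QC samples: %d\n", sum(x$qc_flags)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Row-subset an omics_matrix by sample index
#'
#' @param m an `omics_matrix`.
#' @param idx integer or logical index over samples.
#' @return the subset `omics_matrix`.
#' @export
subset_samples <- function(m, idx) {
  stopifnot(inherits(m, "omics_matrix"))
  # direct rebuild: normalized matrices may hold negative z-scores, which
  # the loading-time constructor would reject
  structure(list(values = m$values[idx, , drop = FALSE],
                 sample_ids = m$sample_ids[idx],
                 feature_ids = m$feature_ids,
                 batch_labels = m$batch_labels[idx],
                 class_labels = m$class_labels[idx],
                 qc_flags = m$qc_flags[idx]),
            class = "omics_matrix")
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
}

#' Load an intensity matrix and its sample annotation from delimited text
#'
#' The matrix file has feature IDs in the first row and sample IDs in the
#' first column (TSV by default; comma-separated files are autodetected).
#' The annotation file must contain columns `sample_id`, `batch`, `label`
#' and `is_qc` (0/1). Empty or `NA` intensity cells become 0; negative or
#' unparseable cells are an error.
#'
#' @param path path to the intensity matrix file.
#' @param annotation_path path to the sample annotation file.
#' @return an [omics_matrix()].
#' @export
load_matrix <- function(path, annotation_path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw),
           dimnames = dimnames(raw)))
  bad <- is.na(vals) & !(as.matrix(raw) %in% c("", "NA", "NaN"))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable cell at sample '%s', feature '%s': '%s'",
                 rownames(raw)[i[1]], colnames(raw)[i[2]],
                 as.matrix(raw)[i[1], i[2]]))
  }
  vals[is.na(vals)] <- 0
  if (any(vals < 0)) {
    i <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative intensity at sample '%s', feature '%s'",
                 rownames(vals)[i[1]], colnames(vals)[i[2]]))
  }
  asep <- detect_sep(annotation_path)
  ann <- utils::read.table(annotation_path, header = TRUE, sep = asep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  need <- c("sample_id", "batch", "label", "is_qc")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation file lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample IDs in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  sid <- rownames(vals)
  missing_ann <- setdiff(sid, ann$sample_id)
  if (length(missing_ann))
    stop("no annotation for sample(s): ", paste(missing_ann, collapse = ", "))
  ann <- ann[match(sid, ann$sample_id), ]
  omics_matrix(vals, sample_ids = sid, feature_ids = colnames(vals),
               batch_labels = ann$batch, class_labels = ann$label,
               qc_flags = as.integer(ann$is_qc) != 0L)
}

#' Write an omics_matrix to matrix + annotation files
#'
#' Inverse of [load_matrix()]: a write-then-load round trip restores an
#' equal object.
#'
#' @param m an `omics_matrix`.
#' @param path output path for the intensity matrix (TSV).
#' @param annotation_path output path for the annotation table (TSV).
#' @param overwrite allow clobbering existing files.
#' @return invisibly, the two paths.
#' @export
write_matrix <- function(m, path, annotation_path, overwrite = FALSE) {
  stopifnot(inherits(m, "omics_matrix"))
  for (p in c(path, annotation_path))
    if (file.exists(p) && !overwrite)
      stop("refusing to overwrite existing file: ", p,
           " (use overwrite = TRUE)")
  df <- data.frame(sample_id = m$sample_ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = m$sample_ids, batch = m$batch_labels,
                    label = m$class_labels, is_qc = as.integer(m$qc_flags))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, annotation_path))
}

#' Natural log(1 + x) transform of the intensities
#'
#' Applied before any normalization or modeling. Zero-coded missing values
#' map to 0 (`log(1 + 0) = 0`), so "missing" stays a distinguishable code
#' after the transform, and all non-zero intensities stay positive.
#'
#' @param m an `omics_matrix` with non-negative values.
#' @return an `omics_matrix` with entries `log1p(v)`.
#' @export
log1p_transform <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (any(m$values < 0)) stop("log1p_transform requires non-negative values")
  m$values <- log1p(m$values)
  m
}
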