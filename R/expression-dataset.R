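#' Labelled expression dataset
#'
#' Container for a features x samples matrix of continuous, already-normalized
#' expression values together with case/control sample labels and (optionally)
#' a feature -> gene-symbol annotation. This is the object every other part of
#' the package consumes. Values are used as distributed (no re-normalization
#' or log transform is applied).
#'
#' @param values numeric matrix, features in rows and samples in columns, with
#'   unique rownames (feature/probe ids) and unique colnames (sample ids). All
#'   values must be finite.
#' @param sample_labels character vector of `"case"`/`"control"`, one per
#'   column of `values` (recycled names from `colnames(values)` if unnamed).
#' @param dataset_id single string identifying the dataset (e.g. a GEO
#'   accession).
#' @param feature_symbols optional named character vector mapping feature ids
#'   to gene symbols; features absent from the map (or mapped to `NA`) are
#'   treated as unannotated.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `values`, `sample_labels` and `feature_symbols` (a vector
#'   aligned with the features, `NA` where unannotated).
#' @export
expression_dataset <- function(values, sample_labels,
                               dataset_id = "dataset",
                               feature_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (features x samples)")
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("'values' must have rownames (feature ids)")
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("'values' must have colnames (sample ids)")
  }
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (length(values) && any(!is.finite(values))) {
    stop("expression values must all be finite")
  }
  if (length(sample_labels) != ncol(values)) {
    stop("'sample_labels' must have one entry per sample")
  }
  sample_labels <- as.character(sample_labels)
  bad <- setdiff(unique(sample_labels), c("case", "control"))
  if (length(bad)) {
    stop("sample labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  names(sample_labels) <- colnames(values)

  symbols <- rep(NA_character_, nrow(values))
  names(symbols) <- rownames(values)
  if (!is.null(feature_symbols)) {
    feature_symbols <- feature_symbols[!is.na(feature_symbols)]
    hit <- intersect(names(feature_symbols), rownames(values))
    symbols[hit] <- as.character(feature_symbols[hit])
  }

  structure(
    list(dataset_id = as.character(dataset_id)[1],
         values = values,
         sample_labels = sample_labels,
         feature_symbols = symbols),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d features x %d samples (%d case / %d control)\n",
              x$dataset_id, nrow(x$values), ncol(x$values),
              sum(x$sample_labels == "case"), sum(x$sample_labels == "control")))
  cat(sprintf("  annotated features: %d\n", sum(!is.na(x$feature_symbols))))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Feature and sample accessors
#'
#' @param ds an [expression_dataset()].
#' @return character vectors of ids.
#' @export
feature_ids <- function(ds) rownames(ds$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(ds) colnames(ds$values)

#' @rdname feature_ids
#' @export
control_ids <- function(ds) names(ds$sample_labels)[ds$sample_labels == "control"]

#' @rdname feature_ids
#' @export
case_ids <- function(ds) names(ds$sample_labels)[ds$sample_labels == "case"]

# internal: restrict to a feature subset, preserving the given order
subset_features <- function(ds, ids) {
  expression_dataset(ds$values[ids, , drop = FALSE], ds$sample_labels,
                     dataset_id = ds$dataset_id,
                     feature_symbols = ds$feature_symbols[ids])
}

#' Attach gene-symbol annotation to a dataset
#'
#' Features without an entry in the annotation are retained in the matrix but
#' remain unannotated; [partition_features()] sends them to the dropped set.
#' The original feature order is preserved. Multiple probes mapping to the
#' same symbol are all kept and all carry that symbol (probe-level analysis).
#'
#' @param ds an [expression_dataset()].
#' @param annotation named character vector (names = feature ids, values =
#'   gene symbols) or a two-column data frame `(feature_id, symbol)`.
#' @return the dataset with `feature_symbols` populated.
#' @export
annotate_features <- function(ds, annotation) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.data.frame(annotation)) {
    if (ncol(annotation) < 2) stop("annotation data frame needs two columns")
    annotation <- stats::setNames(as.character(annotation[[2]]),
                                  as.character(annotation[[1]]))
  }
  if (length(annotation) == 0) {
    warning("empty annotation: every feature will be dropped at partition")
    return(ds)
  }
  annotation <- annotation[nzchar(names(annotation)) & !is.na(annotation) &
                             nzchar(trimws(annotation))]
  expression_dataset(ds$values, ds$sample_labels,
                     dataset_id = ds$dataset_id,
                     feature_symbols = annotation)
}

# canonical symbol form: upper case, surrounding whitespace stripped
canonical_symbol <- function(x) toupper(trimws(x))

#' Partition features into TF, mRNA and dropped sets
#'
#' Features without a gene-symbol annotation are dropped; annotated features
#' whose (canonicalized) symbol appears in the TF catalogue become TF
#' features; the remainder are the mRNA features, i.e. the regression targets.
#' Symbols are matched after upper-casing and whitespace stripping; no alias
#' resolution is attempted.
#'
#' @param ds an annotated [expression_dataset()].
#' @param tf_symbols character vector of transcription-factor gene symbols
#'   (one catalogue entry per element).
#' @return An object of class `FeaturePartition`: list with `tf_features`,
#'   `mrna_features`, `dropped_features` (character vectors in dataset feature
#'   order) and `tf_catalogue_size`.
#' @export
partition_features <- function(ds, tf_symbols) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tf_symbols <- unique(canonical_symbol(tf_symbols))
  tf_symbols <- tf_symbols[nzchar(tf_symbols)]
  if (length(tf_symbols) == 0) {
    stop("TF catalogue is empty: at least one TF symbol is required")
  }
  sym <- canonical_symbol(ds$feature_symbols)
  dropped <- is.na(ds$feature_symbols)
  is_tf <- !dropped & sym %in% tf_symbols
  ids <- feature_ids(ds)
  structure(
    list(tf_features = ids[is_tf],
         mrna_features = ids[!dropped & !is_tf],
         dropped_features = ids[dropped],
         tf_catalogue_size = length(tf_symbols)),
    class = "FeaturePartition"
  )
}

#' @export
print.FeaturePartition <- function(x, ...) {
  cat(sprintf("FeaturePartition: %d TF, %d mRNA, %d dropped (catalogue of %d TF symbols)\n",
              length(x$tf_features), length(x$mrna_features),
              length(x$dropped_features), x$tf_catalogue_size))
  invisible(x)
}

#' Restrict two datasets to their common feature space
#'
#' Needed when datasets from the same platform ship different feature subsets
#' (e.g. a pre-screened export). Both returned datasets carry the intersection
#' of feature ids, in the first dataset's feature order; samples are
#' untouched.
#'
#' @param a,b [expression_dataset()] objects.
#' @return list with elements `a` and `b`, the restricted datasets.
#' @export
align_datasets <- function(a, b) {
  stopifnot(inherits(a, "ExpressionDataset"), inherits(b, "ExpressionDataset"))
  common <- intersect(feature_ids(a), feature_ids(b))
  if (length(common) == 0) stop("datasets share no feature ids")
  list(a = subset_features(a, common), b = subset_features(b, common))
}
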