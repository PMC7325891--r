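#' Read a GEO Series Matrix file
#'
#' Parses the Series Matrix dialect: "!"-prefixed metadata lines, then a
#' tab-separated expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` whose header row holds quoted sample ids.
#' Case/control labels are assigned by a caller-supplied rule of substring
#' patterns matched (case-insensitively) against each sample's `!Sample_*`
#' metadata fields, because every series encodes its groups differently.
#'
#' @param path path to a series matrix file (uncompressed text).
#' @param label_rule named character vector; names are labels (`"case"` or
#'   `"control"`), values are fixed substrings, e.g.
#'   `c(case = "tumor", control = "normal")`. Patterns are tried in order and
#'   the first match wins. A label may appear several times with different
#'   patterns.
#' @param dataset_id dataset identifier; defaults to the file's
#'   `!Series_geo_accession` when present, else the file name.
#' @return an [expression_dataset()].
#' @export
read_series_matrix <- function(path, label_rule, dataset_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_label_rule(label_rule)
  lines <- readLines(path, warn = FALSE)

  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || begin >= end) {
    stop("format error in ", path,
         ": expected one !series_matrix_table_begin/!series_matrix_table_end pair")
  }

  meta <- lines[seq_len(begin - 1)]
  meta <- meta[startsWith(meta, "!")]

  header <- split_sm_row(lines[begin + 1])
  if (length(header) < 2) {
    stop("format error at line ", begin + 1, ": table header has no samples")
  }
  smp_ids <- header[-1]
  if (anyDuplicated(smp_ids)) stop("duplicated sample ids in table header")

  body_idx <- seq(begin + 2, end - 1)
  if (end - begin < 2) stop("format error: series matrix table is empty")
  n_feat <- length(body_idx)
  vals <- matrix(NA_real_, nrow = n_feat, ncol = length(smp_ids))
  feat <- character(n_feat)
  for (i in seq_along(body_idx)) {
    cells <- split_sm_row(lines[body_idx[i]])
    if (length(cells) != length(header)) {
      stop(sprintf("format error at line %d: expected %d cells, found %d",
                   body_idx[i], length(header), length(cells)))
    }
    feat[i] <- cells[1]
    v <- suppressWarnings(as.numeric(cells[-1]))
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite expression value for feature '%s' (line %d)",
                   cells[1], body_idx[i]))
    }
    vals[i, ] <- v
  }
  rownames(vals) <- feat
  colnames(vals) <- smp_ids

  labels <- label_samples(meta, smp_ids, label_rule)

  if (is.null(dataset_id)) {
    acc <- grep("^!Series_geo_accession", meta, value = TRUE)
    dataset_id <- if (length(acc)) {
      strip_quotes(strsplit(acc[1], "\t", fixed = TRUE)[[1]][2])
    } else {
      basename(path)
    }
  }
  expression_dataset(vals, labels, dataset_id = dataset_id)
}

validate_label_rule <- function(label_rule) {
  if (is.null(names(label_rule)) ||
      !all(names(label_rule) %in% c("case", "control"))) {
    stop("label_rule must be a named character vector with names 'case'/'control'")
  }
  if (!all(c("case", "control") %in% names(label_rule))) {
    stop("label_rule must provide at least one pattern for each of 'case' and 'control'")
  }
  invisible(label_rule)
}

split_sm_row <- function(line) strip_quotes(strsplit(line, "\t", fixed = TRUE)[[1]])

strip_quotes <- function(x) sub('^"(.*)"$', "\\1", x)

# Per-sample metadata string: the i-th field of every per-sample "!Sample_*"
# metadata line, concatenated. Lines whose field count does not match the
# sample count (e.g. scalar series metadata) are ignored for labelling.
label_samples <- function(meta, smp_ids, label_rule) {
  per_sample <- rep("", length(smp_ids))
  smp_lines <- meta[startsWith(meta, "!Sample_")]
  for (ln in smp_lines) {
    cells <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(cells) == length(smp_ids) + 1) {
      per_sample <- paste(per_sample, strip_quotes(cells[-1]), sep = " | ")
    }
  }
  hay <- tolower(per_sample)
  labels <- rep(NA_character_, length(smp_ids))
  for (j in seq_along(label_rule)) {
    pat <- tolower(label_rule[[j]])
    hit <- is.na(labels) & grepl(pat, hay, fixed = TRUE)
    labels[hit] <- names(label_rule)[j]
  }
  if (anyNA(labels)) {
    stop("labelling error: sample(s) matched no label pattern: ",
         paste(smp_ids[is.na(labels)], collapse = ", "))
  }
  labels
}

#' Write a dataset in the Series Matrix dialect
#'
#' Emits the same dialect [read_series_matrix()] consumes, with the sample
#' label recorded as a `!Sample_characteristics_ch1` field `"group: <label>"`.
#' Values are printed with 17 significant digits so that a write/read
#' round-trip reproduces them bit-exactly. Reading back uses the rule
#' `c(case = "group: case", control = "group: control")`.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  q <- function(x) paste0('"', x, '"')
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("!Series_geo_accession\t", q(ds$dataset_id)),
    paste("!Sample_geo_accession", paste(q(sample_ids(ds)), collapse = "\t"),
          sep = "\t"),
    paste("!Sample_characteristics_ch1",
          paste(q(paste0("group: ", ds$sample_labels)), collapse = "\t"),
          sep = "\t"),
    "!series_matrix_table_begin",
    paste(c(q("ID_REF"), q(sample_ids(ds))), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(ds$values))) {
    writeLines(paste(c(q(feature_ids(ds)[i]),
                       sprintf("%.17g", ds$values[i, ])), collapse = "\t"), con)
  }
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Label rule matching the dialect written by [write_series_matrix()]
#' @return named character vector usable as `label_rule`.
#' @export
written_label_rule <- function() {
  c(case = "group: case", control = "group: control")
}

#' Read a two-column probe annotation table
#'
#' @param path TSV with feature id in the first column and gene symbol in the
#'   second (a GPL-style annotation export reduced to two columns).
#' @param header whether the file carries a header row.
#' @return named character vector feature id -> symbol; rows with an empty
#'   symbol are omitted (those probes stay unannotated).
#' @export
read_annotation <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, colClasses = "character",
                           quote = "\"", comment.char = "#")
  if (ncol(tab) < 2) stop("annotation file needs at least two columns")
  sym <- trimws(tab[[2]])
  keep <- nzchar(sym) & !is.na(sym)
  stats::setNames(sym[keep], trimws(tab[[1]])[keep])
}

#' Read a transcription-factor symbol catalogue
#'
#' @param path text file with one gene symbol per line (AnimalTFDB-style
#'   export); blank lines and `#` comments are skipped.
#' @return character vector of symbols.
#' @export
read_tf_catalogue <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
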