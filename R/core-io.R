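#' @keywords internal
"_PACKAGE"

# Orientation convention used throughout: samples are rows, features (ASVs or
# genera) are columns.  All identifiers are case-sensitive opaque strings.

`%||%` <- function(a, b) if (is.null(a)) b else a

reproducibility_header <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("cstmove"))
  cfg <- if (is.null(config)) "none" else config_hash(config)
  sprintf("# cstmove %s | samples as rows, features as columns | config=%s", ver, cfg)
}

config_hash <- function(config) {
  # stable short hash of a config list; no external digest dependency
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Validate an ASV feature table
#'
#' A feature table is an integer matrix of sequence-read counts with samples
#' as rows and ASVs (or genera, after aggregation) as columns.  Row and
#' column names are the sample and feature identifiers.
#'
#' @param counts numeric matrix with unique rownames (sample ids) and unique
#'   colnames (feature ids); all cells non-negative integers.
#' @return the validated matrix, invisibly classed as `feature_table`.
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table requires sample ids (rownames) and feature ids (colnames)")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  dup_f <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "double"
  class(counts) <- c("feature_table", "matrix", "array")
  counts
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features; library sizes %s..%s\n",
              nrow(x), ncol(x), format(min(library_sizes(x))),
              format(max(library_sizes(x)))))
  invisible(x)
}

#' Per-sample library sizes (total reads)
#' @param ft feature table
#' @return named numeric vector of row sums
#' @export
library_sizes <- function(ft) rowSums(unclass(ft))

#' Read a feature table from TSV
#'
#' Expects a header row, a leading `sample_id` column and one column per
#' ASV holding base-10 integer counts.  Lines starting with `#` are
#' treated as comments.
#'
#' @param path TSV file path
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse feature table '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("feature table '", path, "' is empty or has no count columns")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(num) <- ids
  feature_table(num)
}

#' Write a feature table to TSV
#' @param ft feature table
#' @param path output path
#' @param config optional config list recorded in the header comment
#' @export
write_feature_table <- function(ft, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  df <- data.frame(sample_id = rownames(ft), unclass(ft)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy map from TSV
#'
#' Columns: `asv_id`, `genus` (finer ranks, if present, are kept as extra
#' columns but unused).
#' @param path TSV file path
#' @return data.frame with columns asv_id, genus
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  if (!all(c("asv_id", "genus") %in% names(df)))
    stop("taxonomy file must have columns asv_id, genus")
  if (anyDuplicated(df$asv_id))
    stop("duplicate asv_id in taxonomy")
  df
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame
#' @param config optional config list recorded in the header comment
#' @export
write_taxonomy <- function(tax, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  utils::write.table(tax, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TIMEPOINT_LEVELS <- c("PRE", "ILI", "POST")

#' Validate per-sample metadata
#'
#' Required columns: `sample_id`, `subject_id`, `timepoint_class` (one of
#' PRE/ILI/POST), `collection_order` (integer, ordering samples within a
#' subject), `arm` (active/placebo).  Any extra columns are clinical
#' covariates; their types (continuous/binary/discrete) are declared in
#' `covariate_types`.
#'
#' @param md data.frame of per-sample metadata
#' @param covariate_types named character vector typing each extra column
#' @return validated data.frame with a `covariate_types` attribute
#' @export
sample_metadata <- function(md, covariate_types = character()) {
  req <- c("sample_id", "subject_id", "timepoint_class", "collection_order", "arm")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  if (!all(md$timepoint_class %in% TIMEPOINT_LEVELS))
    stop("timepoint_class must be one of ", paste(TIMEPOINT_LEVELS, collapse = "/"))
  if (!all(md$arm %in% c("active", "placebo")))
    stop("arm must be 'active' or 'placebo'")
  md$collection_order <- as.integer(md$collection_order)
  for (tp in c("PRE", "POST")) {
    tab <- table(md$subject_id[md$timepoint_class == tp])
    if (any(tab > 1))
      stop("subject(s) with more than one ", tp, " sample: ",
           paste(names(tab)[tab > 1], collapse = ", "))
  }
  # within-subject ordering must respect PRE < ILI < POST
  for (s in unique(md$subject_id)) {
    sub <- md[md$subject_id == s, ]
    sub <- sub[order(sub$collection_order), ]
    rank <- match(sub$timepoint_class, TIMEPOINT_LEVELS)
    if (is.unsorted(rank))
      stop("subject '", s, "': collection_order conflicts with PRE<ILI<POST")
  }
  covs <- setdiff(names(md), req)
  undeclared <- setdiff(covs, names(covariate_types))
  if (length(undeclared))
    stop("covariates without a declared type: ", paste(undeclared, collapse = ", "))
  if (!all(covariate_types[covs] %in% c("continuous", "binary", "discrete")))
    stop("covariate types must be continuous, binary or discrete")
  attr(md, "covariate_types") <- covariate_types[covs]
  md
}

#' Read sample metadata (TSV plus sidecar JSON of covariate types)
#'
#' The sidecar `<path>.types.json` maps each covariate column to
#' continuous/binary/discrete; it is required when covariates are present.
#' @param path metadata TSV path
#' @return validated metadata data.frame
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE,
                          na.strings = c("NA", ""))
  sidecar <- paste0(path, ".types.json")
  types <- character()
  if (file.exists(sidecar))
    types <- unlist(jsonlite::read_json(sidecar))
  sample_metadata(df, types)
}

#' @rdname read_sample_metadata
#' @param md validated metadata
#' @param config optional config list recorded in the header comment
#' @export
write_sample_metadata <- function(md, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  utils::write.table(md, con, sep = "\t", quote = FALSE, row.names = FALSE)
  types <- attr(md, "covariate_types")
  if (length(types))
    jsonlite::write_json(as.list(types), paste0(path, ".types.json"),
                         auto_unbox = TRUE)
  invisible(path)
}

#' Read a 16S qPCR copy-number table (columns sample_id, copies)
#' @param path TSV path
#' @return data.frame sample_id, copies
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  if (!all(c("sample_id", "copies") %in% names(df)))
    stop("qPCR file must have columns sample_id, copies")
  if (any(!is.finite(df$copies) | df$copies <= 0))
    stop("qPCR copies must be positive")
  df
}

#' @rdname read_qpcr
#' @param qpcr qPCR data.frame
#' @param config optional config list recorded in the header comment
#' @export
write_qpcr <- function(qpcr, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(reproducibility_header(config), con)
  utils::write.table(qpcr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle a cohort's tables into one validated dataset
#'
#' @param feature_table a [feature_table()]
#' @param taxonomy data.frame (asv_id, genus) covering the table's ASVs
#' @param metadata validated [sample_metadata()]
#' @param qpcr optional data.frame (sample_id, copies)
#' @return `study_dataset` S3 object
#' @export
study_dataset <- function(feature_table, taxonomy, metadata, qpcr = NULL) {
  ids <- rownames(feature_table)
  if (!setequal(ids, metadata$sample_id))
    stop("feature table and metadata sample ids differ")
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  ds <- structure(list(feature_table = feature_table, taxonomy = taxonomy,
                       metadata = metadata, qpcr = qpcr),
                  class = "study_dataset")
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d samples, %d ASVs, %d subjects%s\n",
              nrow(x$feature_table), ncol(x$feature_table),
              length(unique(x$metadata$subject_id)),
              if (is.null(x$qpcr)) "" else ", qPCR present"))
  invisible(x)
}

subset_dataset <- function(ds, keep_ids) {
  ft <- ds$feature_table[rownames(ds$feature_table) %in% keep_ids, ,
                         drop = FALSE]
  class(ft) <- c("feature_table", "matrix", "array")
  md <- ds$metadata[ds$metadata$sample_id %in% keep_ids, , drop = FALSE]
  attr(md, "covariate_types") <- attr(ds$metadata, "covariate_types")
  qp <- if (is.null(ds$qpcr)) NULL else
    ds$qpcr[ds$qpcr$sample_id %in% keep_ids, , drop = FALSE]
  structure(list(feature_table = ft, taxonomy = ds$taxonomy, metadata = md,
                 qpcr = qp), class = "study_dataset")
}

#' Remove samples with low 16S qPCR load
#'
#' Samples with fewer than `min_copies` 16S rRNA gene copies are removed
#' from every component of the dataset.  The comparison is strictly `<`, so
#' a sample at exactly the threshold is kept.
#'
#' @param ds a [study_dataset()] with a qPCR table
#' @param min_copies copy-number threshold (default 1e3)
#' @param missing_qpcr what to do with samples absent from the qPCR table:
#'   `"keep"` (default, with a warning) or `"remove"`
#' @return list with elements `dataset` (filtered) and `removed`
#'   (character vector of removed sample ids)
#' @export
filter_low_load <- function(ds, min_copies = 1e3,
                            missing_qpcr = c("keep", "remove")) {
  missing_qpcr <- match.arg(missing_qpcr)
  stopifnot(inherits(ds, "study_dataset"), min_copies > 0)
  if (is.null(ds$qpcr)) stop("dataset has no qPCR table")
  ids <- rownames(ds$feature_table)
  copies <- ds$qpcr$copies[match(ids, ds$qpcr$sample_id)]
  absent <- ids[is.na(copies)]
  if (length(absent)) {
    warning(length(absent), " sample(s) missing from qPCR table (policy: ",
            missing_qpcr, ")")
  }
  low <- ids[!is.na(copies) & copies < min_copies]
  removed <- c(low, if (missing_qpcr == "remove") absent)
  list(dataset = subset_dataset(ds, setdiff(ids, removed)), removed = removed)
}

#' Remove samples below a minimum read depth
#'
#' @param ft feature table
#' @param min_reads library-size floor; samples with fewer total reads are
#'   removed.  The realised post-QC minimum in typical mid-turbinate
#'   datasets is on the order of 1e3 reads; no default is imposed here.
#' @return list with `feature_table` (filtered) and `removed` ids
#' @export
filter_min_reads <- function(ft, min_reads) {
  stopifnot(min_reads >= 0)
  ls <- library_sizes(ft)
  removed <- names(ls)[ls < min_reads]
  if (length(removed) == nrow(ft))
    stop("min_reads = ", min_reads, " removes every sample")
  kept <- ft[!(rownames(ft) %in% removed), , drop = FALSE]
  class(kept) <- c("feature_table", "matrix", "array")
  list(feature_table = kept, removed = removed)
}

#' Convert counts to per-sample relative abundances
#' @param ft feature table (every library size must be positive)
#' @return matrix of proportions; each row sums to 1
#' @export
relative_abundance <- function(ft) {
  ls <- library_sizes(ft)
  if (any(ls == 0))
    stop("zero-sum sample(s): ", paste(names(ls)[ls == 0], collapse = ", "))
  sweep(unclass(ft), 1, ls, "/")
}

#' Aggregate ASV counts to genus level
#'
#' ASVs sharing a genus are summed; library sizes are conserved.  ASVs
#' without a taxonomy entry are pooled into `"unclassified"` with a warning.
#'
#' @param ft feature table keyed by ASV
#' @param tax taxonomy data.frame (asv_id, genus)
#' @return feature table keyed by genus
#' @export
aggregate_by_genus <- function(ft, tax) {
  genus <- tax$genus[match(colnames(ft), tax$asv_id)]
  if (anyNA(genus)) {
    warning(sum(is.na(genus)), " ASV(s) without taxonomy mapped to 'unclassified'")
    genus[is.na(genus)] <- "unclassified"
  }
  genus[genus == ""] <- "unclassified"
  out <- t(rowsum(t(unclass(ft)), group = genus))
  out <- out[, unique(genus), drop = FALSE]  # keep first-appearance order
  feature_table(out)
}
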