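# Tabular I/O for every matrix and map the pipeline touches. All files are
# tab-separated with a header row; lines starting with '#' are provenance
# comments and are skipped on read. Missing values are never permitted:
# a normalized expression matrix with NAs is an upstream error.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE, ...)
}

.as_expression_matrix <- function(values, feature_ids, sample_ids,
                                  context = "expression matrix") {
  m <- as.matrix(values)
  if (!is.numeric(m)) stop(context, ": non-numeric values present", call. = FALSE)
  if (nrow(m) == 0L || ncol(m) == 0L) stop(context, ": empty matrix", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) {
    stop(context, ": duplicate feature ID(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop(context, ": duplicate sample ID(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop(context, ": non-finite values (NA/NaN/Inf) present", call. = FALSE)
  }
  dimnames(m) <- list(feature_ids, sample_ids)
  m
}

#' Read a normalized expression matrix
#'
#' Reads a feature-by-sample matrix of normalized expression intensities
#' (typically log2-scale values from upstream RMA-style processing). Two
#' dialects are supported: plain TSV (first column feature IDs, one column
#' per sample) and GCT v1.2 (two header lines, then `Name`/`Description`
#' columns before the samples).
#'
#' Feature and sample IDs must be unique and every cell must be a finite
#' number; violations abort with an error naming the offending ID, so a
#' load never silently drops or mangles rows.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"gct"`.
#' @return A numeric matrix with feature IDs as rownames and sample IDs as
#'   colnames.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (format == "gct") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- read.delim(path, header = TRUE, sep = "\t", skip = 2,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("GCT file must have Name, Description and data columns",
                            call. = FALSE)
    return(.as_expression_matrix(df[, -(1:2), drop = FALSE], df[[1L]],
                                 colnames(df)[-(1:2)]))
  }
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("expression TSV must have a feature column and >= 1 sample",
                          call. = FALSE)
  .as_expression_matrix(df[, -1L, drop = FALSE], df[[1L]], colnames(df)[-1L])
}

#' Write an expression or signature matrix as TSV
#'
#' @param x Numeric matrix with rownames (features) and colnames (samples or
#'   cell types).
#' @param path Output path.
#' @param id_column Name for the first (ID) column.
#' @param header Optional character vector of `#`-prefixed provenance lines
#'   written before the table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_column = "feature_id",
                                    header = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  df <- cbind(rownames(x), format(x, digits = 17, trim = TRUE, scientific = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct and validate a sample annotation table
#'
#' A sample annotation assigns each reference sample to exactly one cell
#' type, optionally with a free-text subtype/treatment field. Duplicate
#' sample IDs and empty labels are errors. Cell types represented by fewer
#' than `min_replicates` samples trigger a warning: with few replicates the
#' per-type medians and the ANOVA ranking that the signature build relies on
#' become unstable.
#'
#' @param sample_id Character vector of unique sample IDs.
#' @param cell_type Character vector of cell-type labels, same length.
#' @param subtype Optional character vector (subtype or treatment), same
#'   length.
#' @param min_replicates Replicate count below which a warning is issued
#'   (default 9, the smallest per-type census in a well-powered reference
#'   compendium).
#' @return A `data.frame` with columns `sample_id`, `cell_type`, `subtype`,
#'   of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, cell_type, subtype = NULL,
                              min_replicates = 9L) {
  sample_id <- as.character(sample_id)
  cell_type <- as.character(cell_type)
  if (length(sample_id) != length(cell_type))
    stop("sample_id and cell_type lengths differ", call. = FALSE)
  if (length(sample_id) == 0L) stop("empty annotation", call. = FALSE)
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup)) stop("duplicate sample ID(s): ",
                        paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(is.na(cell_type) | cell_type == ""))
    stop("empty cell-type label", call. = FALSE)
  if (is.null(subtype)) subtype <- rep(NA_character_, length(sample_id))
  ann <- data.frame(sample_id = sample_id, cell_type = cell_type,
                    subtype = as.character(subtype),
                    stringsAsFactors = FALSE)
  census <- table(ann$cell_type)
  low <- names(census)[census < min_replicates]
  if (length(low)) {
    warning("cell type(s) with fewer than ", min_replicates, " replicates: ",
            paste0(low, " (", census[low], ")", collapse = ", "), call. = FALSE)
  }
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Read a sample annotation file
#'
#' Expects a TSV with columns `sample_id`, `cell_type` and optionally a
#' third subtype/treatment column (header names are free; order matters).
#'
#' @inheritParams sample_annotation
#' @param path Path to the annotation TSV.
#' @return A `sample_annotation` data frame.
#' @export
read_sample_annotation <- function(path, min_replicates = 9L) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("annotation file needs >= 2 columns", call. = FALSE)
  sample_annotation(df[[1L]], df[[2L]],
                    subtype = if (ncol(df) >= 3L) df[[3L]] else NULL,
                    min_replicates = min_replicates)
}

#' Cell-type census of an annotation
#'
#' @param ann A `sample_annotation` data frame.
#' @return Named integer vector of replicate counts per cell type, in
#'   alphabetical label order.
#' @export
cell_type_census <- function(ann) {
  tab <- table(ann$cell_type)
  setNames(as.integer(tab), names(tab))
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_symbol`). Several probes may map to one
#' gene (many-to-one), but a probe mapped to two distinct genes is an error.
#' Gene symbols are kept as opaque strings; no case folding is applied.
#'
#' @param path Path to the map TSV.
#' @return A `data.frame` with columns `probe_id` and `gene_symbol`
#'   (zero rows for an empty file).
#' @export
read_probe_gene_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(.read_tsv(path), error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(probe_id = character(), gene_symbol = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(df) < 2L) stop("probe map needs 2 columns", call. = FALSE)
  map <- data.frame(probe_id = as.character(df[[1L]]),
                    gene_symbol = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  dup <- map$probe_id[duplicated(map$probe_id)]
  if (length(dup)) {
    stop("probe(s) mapped to more than one gene: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  map
}

#' Read a cell-type aggregation map
#'
#' Maps each assay-level cell type (e.g. a flow-cytometry gate) to the set
#' of signature cell types whose predicted fractions are summed to estimate
#' it. Format: two-column TSV, `assay_cell_type` and a comma-separated list
#' of signature labels. A signature label may belong to at most one group.
#'
#' @param path Path to the map TSV.
#' @return A named list: names are assay cell types, values character
#'   vectors of signature cell types.
#' @export
read_celltype_map <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("cell-type map needs 2 columns", call. = FALSE)
  map <- lapply(strsplit(as.character(df[[2L]]), ","), trimws)
  names(map) <- as.character(df[[1L]])
  members <- unlist(map, use.names = FALSE)
  dup <- members[duplicated(members)]
  if (length(dup)) {
    stop("signature cell type(s) in more than one aggregation group: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  map
}

#' Read a signature matrix (genes x cell types) from TSV
#'
#' @param path Path to the TSV (first column gene IDs, one column per cell
#'   type).
#' @return Numeric matrix, genes x cell types.
#' @export
read_signature_matrix <- function(path) {
  m <- read_expression_matrix(path, format = "tsv")
  m
}

#' Write a fraction table
#'
#' Writes estimated cell-type fractions, one row per sample, one column per
#' cell type, plus a trailing `row_sum` column (a quick integrity check:
#' every row should sum to 1).
#'
#' @param fractions Numeric matrix, samples x cell types, with dimnames.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(fractions, path, header = NULL) {
  stopifnot(is.matrix(fractions), !is.null(rownames(fractions)),
            !is.null(colnames(fractions)))
  out <- cbind(fractions, row_sum = rowSums(fractions))
  write_expression_matrix(out, path, id_column = "sample_id", header = header)
}
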