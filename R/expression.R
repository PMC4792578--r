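# Expression matrices are plain numeric matrices, genes x samples, with
# unique rownames (gene ids) and colnames (sample ids), log2 scale.

#' Validate an expression matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix with unique gene ids as rownames and unique sample ids as
#' colnames, and (by default) no missing values.  Relative-ordering
#' statistics are undefined on missing entries, so the default is to
#' reject them; per-gene median imputation is available for loaders that
#' opt in.
#'
#' @param x numeric matrix, genes x samples.
#' @param allow_na logical; if `FALSE` (default) any `NA` aborts.
#' @return `x`, invisibly.
#' @export
validate_expression <- function(x, allow_na = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("gene ids (rownames) must be present and unique")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("sample ids (colnames) must be present and unique")
  if (!allow_na && anyNA(x))
    stop("expression matrix contains missing values; ",
         "impute or filter before use (see read_expression(impute=))")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns are samples, values on the log2
#' scale.  Missing values are rejected by default because within-sample
#' orderings are undefined on them; `impute = "median"` replaces each
#' gene's missing entries with that gene's median across samples.
#'
#' @param path file path.
#' @param impute `"none"` (default, reject missing values) or `"median"`.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path, impute = c("none", "median")) {
  impute <- match.arg(impute)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (ncol(dt) < 2L)
    stop("expression TSV needs a gene id column plus >=1 sample column: ",
         path)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) {
    if (impute == "none")
      stop("missing values in ", path,
           "; re-run with impute = \"median\" to impute per gene")
    med <- apply(m, 1L, median, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- med[idx[, 1L]]
    if (anyNA(m)) stop("genes with all values missing cannot be imputed")
  }
  validate_expression(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix, genes x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x, allow_na = TRUE)
  dt <- data.table::data.table(gene_id = rownames(x), x)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
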