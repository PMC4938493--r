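#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Duplicate gene ids are an error by default, or collapsed by row mean with
#' `duplicates = "mean"`.  Missing values are an error by default, or imputed
#' with the per-gene median with `impute = TRUE`.
#'
#' @param path TSV file path.
#' @param condition optional per-sample condition labels (recycled checks
#'   apply) or a samples TSV path with columns `sample`, `condition` and
#'   optional covariates.
#' @param duplicates `"error"` (default) or `"mean"`.
#' @param impute impute missing values with the per-gene median?
#' @return an `expression_study`: list with `expr` matrix, `condition`
#'   factor or NULL, `covariates` data frame or NULL.
#' @export
read_expression <- function(path, condition = NULL,
                            duplicates = c("error", "mean"), impute = FALSE) {
  duplicates <- match.arg(duplicates)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs gene ids plus >=1 sample")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression cells in ", path)
  if (anyDuplicated(ids)) {
    if (duplicates == "error")
      stop("duplicate gene id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mat <- rowsum(mat, ids, reorder = FALSE)
    cnt <- as.vector(table(ids)[rownames(mat)])
    mat <- mat / cnt
    ids <- rownames(mat)
  }
  rownames(mat) <- ids
  if (anyNA(mat)) {
    if (!impute) stop("missing values in expression matrix (set impute = TRUE)")
    for (i in which(rowSums(is.na(mat)) > 0)) {
      med <- stats::median(mat[i, ], na.rm = TRUE)
      mat[i, is.na(mat[i, ])] <- med
    }
  }
  covariates <- NULL
  if (is.character(condition) && length(condition) == 1 && file.exists(condition)) {
    smp <- utils::read.delim(condition, stringsAsFactors = FALSE)
    rownames(smp) <- smp$sample
    smp <- smp[colnames(mat), , drop = FALSE]
    condition <- smp$condition
    covariates <- smp[, setdiff(names(smp), c("sample", "condition")), drop = FALSE]
  }
  expression_study(mat, condition = condition, covariates = covariates)
}

#' Construct an expression study container
#'
#' @param expr numeric gene x sample matrix with unique dimnames.
#' @param condition optional per-sample labels.
#' @param covariates optional data frame, rows matching samples.
#' @return object of class `expression_study`.
#' @export
expression_study <- function(expr, condition = NULL, covariates = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene and sample ids")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (anyNA(expr)) stop("missing values in expression matrix")
  if (!is.null(condition)) {
    if (length(condition) != ncol(expr))
      stop("condition length must equal the sample count")
    condition <- as.factor(condition)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(expr))
      stop("covariate rows must match samples")
    rownames(covariates) <- colnames(expr)
  }
  structure(list(expr = expr, condition = condition, covariates = covariates),
            class = "expression_study")
}

#' Write an expression study to TSV
#' @param study an `expression_study` or plain matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(study, path) {
  mat <- if (inherits(study, "expression_study")) study$expr else study
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#' @param path GMT file (set name, description, tab-separated gene ids).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Read a two-column homology table
#' @param path TSV with two columns (species-1 gene, species-2 gene).
#' @return data frame with columns `a`, `b`, unique pairs.
#' @export
read_homology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("homology table needs two columns")
  out <- unique(data.frame(a = as.character(df[[1]]), b = as.character(df[[2]])))
  rownames(out) <- NULL
  out
}
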