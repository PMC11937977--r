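#' Construct an ExpressionDataset
#'
#' An `ExpressionDataset` bundles a gene-by-sample numeric matrix with
#' per-sample annotations and a flag declaring the measurement scale.
#' Raw counts are required to be non-negative integers; log-expression
#' values are unconstrained real numbers (typically log2-CPM or
#' log-normalized values from an upstream pipeline).
#'
#' @param values numeric matrix, genes as rows, samples as columns. Row and
#'   column names are used as gene and sample identifiers when `genes` /
#'   `samples` are not given.
#' @param annotations data.frame of per-sample annotations. Must contain a
#'   `Group` column; an optional `Batch` column is used as a fixed-effect
#'   covariate in the linear model. Rows are matched to matrix columns by a
#'   `Sample` column if present, otherwise by row names, otherwise by
#'   position.
#' @param scale one of `"raw_counts"` or `"log_expression"`.
#' @param genes,samples optional character vectors overriding dimnames.
#' @param uppercase_ids logical; if `TRUE`, gene identifiers are upper-cased
#'   before uniqueness checks. Off by default: silent case folding can create
#'   false joins across species naming conventions.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (named matrix), `genes`, `samples`, `scale`, `annotations`.
#' @export
expression_dataset <- function(values, annotations,
                               scale = c("raw_counts", "log_expression"),
                               genes = NULL, samples = NULL,
                               uppercase_ids = FALSE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"

  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(rownames(values))) {
    stop("gene identifiers are required (matrix row names or `genes`)")
  }
  if (is.null(colnames(values))) {
    stop("sample identifiers are required (matrix column names or `samples`)")
  }
  if (uppercase_ids) rownames(values) <- toupper(rownames(values))

  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers")
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale == "raw_counts") {
    if (any(values < 0)) stop("raw counts must be non-negative")
    if (any(abs(values - round(values)) > 1e-8)) {
      stop("raw counts must be integral")
    }
  }

  annotations <- as.data.frame(annotations)
  if ("Sample" %in% colnames(annotations)) {
    rownames(annotations) <- as.character(annotations$Sample)
  }
  if (!is.null(rownames(annotations)) &&
      !identical(rownames(annotations), as.character(seq_len(nrow(annotations))))) {
    missing <- setdiff(colnames(values), rownames(annotations))
    if (length(missing)) {
      stop("samples missing from the annotation sheet: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    annotations <- annotations[colnames(values), , drop = FALSE]
  } else if (nrow(annotations) == ncol(values)) {
    rownames(annotations) <- colnames(values)
  } else {
    stop("annotation rows do not match matrix columns")
  }

  if (!"Group" %in% colnames(annotations)) {
    stop("annotation sheet must contain a 'Group' column")
  }
  grp <- as.character(annotations$Group)
  if (anyNA(grp) || any(!nzchar(grp))) {
    stop("every sample needs a non-empty Group label")
  }
  annotations$Group <- grp
  if ("Batch" %in% colnames(annotations)) {
    annotations$Batch <- as.character(annotations$Batch)
  }

  structure(
    list(values = values,
         genes = rownames(values),
         samples = colnames(values),
         scale = scale,
         annotations = annotations),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s)\n",
              length(x$genes), length(x$samples), x$scale))
  tab <- table(x$annotations$Group)
  cat("Groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  if ("Batch" %in% colnames(x$annotations)) {
    cat("Batches:", paste(unique(x$annotations$Batch), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Subset an ExpressionDataset by genes and/or samples
#'
#' @param x an `ExpressionDataset`.
#' @param genes,samples character vectors of identifiers to keep (order
#'   preserved as given). `NULL` keeps everything.
#' @return A new `ExpressionDataset`.
#' @export
subset_dataset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionDataset"))
  g <- if (is.null(genes)) x$genes else intersect(genes, x$genes)
  s <- if (is.null(samples)) x$samples else intersect(samples, x$samples)
  expression_dataset(x$values[g, s, drop = FALSE],
                     x$annotations[s, , drop = FALSE],
                     scale = x$scale)
}

#' Group labels of a dataset
#' @param x an `ExpressionDataset`.
#' @return character vector of per-sample group labels.
#' @export
dataset_groups <- function(x) {
  stopifnot(inherits(x, "ExpressionDataset"))
  x$annotations$Group
}
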