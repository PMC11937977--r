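#' Read an expression matrix and sample sheet
#'
#' Supports two matrix layouts: a delimited text table (genes as rows, first
#' column or row names holding gene identifiers, header row holding sample
#' identifiers), or a MatrixMarket triplet file accompanied by
#' `<path>.rownames` / `<path>.colnames` side files with one identifier per
#' line. The sample sheet is a tab-delimited table with a sample identifier
#' column (named `Sample`, or the first column) plus `Group` and optional
#' `Batch` columns.
#'
#' The delimiter of a text matrix is inferred from the file extension
#' (`.tsv` vs `.csv`) unless `delimiter` is given.
#'
#' @param matrix_path path to the matrix file (`.tsv`, `.csv`, or `.mtx`).
#' @param samples_path path to the sample sheet (TSV).
#' @param scale `"raw_counts"` or `"log_expression"`.
#' @param delimiter optional field separator overriding extension inference.
#' @param uppercase_ids upper-case gene identifiers before matching.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, samples_path,
                            scale = c("raw_counts", "log_expression"),
                            delimiter = NULL, uppercase_ids = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(samples_path)) stop("sample sheet not found: ", samples_path)

  ext <- tolower(tools::file_ext(matrix_path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(matrix_path))
    rn_path <- paste0(matrix_path, ".rownames")
    cn_path <- paste0(matrix_path, ".colnames")
    if (!file.exists(rn_path) || !file.exists(cn_path)) {
      stop("MatrixMarket input needs ", basename(rn_path), " and ",
           basename(cn_path), " side files")
    }
    rownames(m) <- readLines(rn_path)
    colnames(m) <- readLines(cn_path)
  } else {
    sep <- delimiter
    if (is.null(sep)) sep <- if (ext == "csv") "," else "\t"
    tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
    if (!is.numeric(tab[[1]])) {
      rn <- as.character(tab[[1]])
      tab <- tab[, -1, drop = FALSE]
    } else {
      rn <- rownames(tab)
    }
    m <- as.matrix(tab)
    if (anyDuplicated(rn)) {
      stop("duplicate gene identifiers in ", matrix_path)
    }
    rownames(m) <- rn
  }

  ann <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (!"Sample" %in% colnames(ann)) {
    colnames(ann)[1] <- "Sample"
  }
  ann$Sample <- as.character(ann$Sample)

  expression_dataset(m, ann, scale = scale, uppercase_ids = uppercase_ids)
}

#' Write an expression dataset as TSV matrix + sample sheet
#'
#' @param dataset an `ExpressionDataset`.
#' @param matrix_path,samples_path output paths.
#' @return Invisibly, the matrix path.
#' @export
write_expression <- function(dataset, matrix_path, samples_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  tab <- data.frame(gene = dataset$genes,
                    dataset$values, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(Sample = dataset$samples,
                    dataset$annotations[, setdiff(colnames(dataset$annotations), "Sample"),
                                        drop = FALSE],
                    check.names = FALSE)
  utils::write.table(ann, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are dropped, first occurrence kept.
#'
#' @param path GMT file path.
#' @param uppercase_ids upper-case member genes on read.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, uppercase_ids = FALSE) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_set_collection(list()))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(short), collapse = ", "))
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate set names in GMT: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  descriptions <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (uppercase_ids) g <- toupper(g)
    g[!duplicated(g)]
  })
  names(sets) <- names_
  names(descriptions) <- names_
  gene_set_collection(sets, descriptions = descriptions)
}

#' Write gene sets to a GMT file
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- collection$descriptions[[nm]]
    if (is.null(desc) || !nzchar(desc)) desc <- "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a signature table
#'
#' Columns: `gene`, `rank_product`, `score`, `selected_by` (one of `rp`,
#' `keep_top`, `pool`), `snr` (empty when no background dataset was used).
#' Rows are ordered by ascending score.
#'
#' @param signature a `Signature` (see [select_genes()] / [constrain_to_pool()]).
#' @param path output TSV path.
#' @param snr_table optional `SnrTable` from [compute_snr()]; its `snr`
#'   column is joined by gene.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path, snr_table = NULL) {
  stopifnot(inherits(signature, "Signature"))
  tab <- as.data.frame(signature)
  tab$snr <- NA_real_
  if (!is.null(snr_table)) {
    idx <- match(tab$gene, snr_table$gene)
    tab$snr <- snr_table$snr[idx]
  }
  out <- tab[, c("gene", "rank_product", "score", "selected_by", "snr")]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "", format(v, digits = 15)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature table written by [write_signature()]
#'
#' @param path TSV path.
#' @return A `Signature`.
#' @export
read_signature <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c(gene = "character",
                                          rank_product = "numeric",
                                          score = "numeric",
                                          selected_by = "character",
                                          snr = "numeric"))
  new_signature(gene = tab$gene, rank_product = tab$rank_product,
                score = tab$score, selected_by = tab$selected_by)
}

#' Write an SNR table as TSV
#'
#' @param snr_table an `SnrTable` from [compute_snr()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_snr_table <- function(snr_table, path) {
  utils::write.table(snr_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
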