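#' Construct a GeneSetCollection
#'
#' A named list of gene sets together with per-gene provenance: for every
#' gene, the list of set names it came from. Provenance is kept machine
#' readable so that downstream steps (pool protection in the background
#' filter, audits) can query a gene's sources directly.
#'
#' @param sets named list of character vectors. Members are de-duplicated
#'   within each set, first occurrence kept.
#' @param descriptions optional named character vector of set descriptions.
#' @return An object of class `GeneSetCollection` with elements `sets`,
#'   `descriptions`, `provenance`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g[!duplicated(g)]
  })
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  prov <- list()
  for (nm in names(sets)) {
    for (g in sets[[nm]]) prov[[g]] <- c(prov[[g]], nm)
  }
  structure(list(sets = sets,
                 descriptions = descriptions,
                 provenance = prov),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s), %d unique gene(s)\n",
              length(x$sets), length(pool_genes(x))))
  for (nm in utils::head(names(x$sets), 10)) {
    cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  }
  invisible(x)
}

#' All unique genes in a collection, first-appearance order
#' @param collection a `GeneSetCollection`.
#' @return character vector.
#' @export
pool_genes <- function(collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  g <- unlist(collection$sets, use.names = FALSE)
  g[!duplicated(g)]
}

#' Merge marker collections into a single candidate pool
#'
#' The pooled gene list is the union of all member genes in input order
#' (first occurrence wins); the provenance of each gene records every source
#' set it appeared in, across all input collections. Merging is idempotent:
#' merging a merged pool with itself changes nothing.
#'
#' @param ... one or more `GeneSetCollection` objects (or a single list of
#'   them).
#' @param pool_name name given to the pooled set (default `"pool"`).
#' @return A `GeneSetCollection` holding one pooled set, with per-gene
#'   provenance tracing original set names.
#' @export
merge_markers <- function(..., pool_name = "pool") {
  inputs <- list(...)
  if (length(inputs) == 1L && !inherits(inputs[[1]], "GeneSetCollection")) {
    inputs <- inputs[[1]]
  }
  if (!length(inputs)) stop("at least one collection required")
  lapply(inputs, function(x) stopifnot(inherits(x, "GeneSetCollection")))
  if (all(vapply(inputs, function(x) length(pool_genes(x)) == 0L, TRUE))) {
    stop("all input collections are empty")
  }

  genes <- character(0)
  prov <- list()
  for (coll in inputs) {
    for (nm in names(coll$sets)) {
      for (g in coll$sets[[nm]]) {
        if (!g %in% genes) genes <- c(genes, g)
        # provenance may itself come from a prior merge; chase it through
        src <- coll$provenance[[g]]
        if (is.null(src)) src <- nm
        prov[[g]] <- union(prov[[g]], src)
      }
    }
  }
  out <- gene_set_collection(stats::setNames(list(genes), pool_name))
  out$provenance <- prov[genes]
  out
}

#' Tabulate the overlap structure of a gene-set collection
#'
#' Decomposes the union of all sets into disjoint membership regions (as in
#' an UpSet plot) and counts the genes in each non-empty region. Region
#' counts sum to the union size.
#'
#' @param collection a `GeneSetCollection` with at least two sets.
#' @return data.frame with columns `pattern` (set names joined by `&`),
#'   `n_sets`, `count`, ordered by decreasing `n_sets` then count.
#' @export
overlap_summary <- function(collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  sets <- collection$sets
  if (length(sets) < 2L) stop("need at least two sets to summarize overlap")
  universe <- pool_genes(collection)
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  counts <- table(pattern)
  out <- data.frame(pattern = names(counts),
                    n_sets = lengths(strsplit(names(counts), "&", fixed = TRUE)),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sets, -out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
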