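#' Construct a Signature
#'
#' A signature is an ordered table of selected genes: ascending permutation
#' score, ties broken by rank product then gene name, no duplicates.
#'
#' @param gene character vector of gene identifiers.
#' @param rank_product,score numeric vectors aligned with `gene`.
#' @param selected_by character vector of selection reasons (`"rp"`,
#'   `"keep_top"`, `"pool"`).
#' @param source_datasets optional character vector naming the dataset(s)
#'   each gene was selected in (aggregation provenance).
#' @return object of class `Signature` (a data.frame).
#' @export
new_signature <- function(gene, rank_product = NA_real_, score = NA_real_,
                          selected_by = "rp", source_datasets = NULL) {
  out <- data.frame(gene = as.character(gene),
                    rank_product = as.numeric(rank_product),
                    score = as.numeric(score),
                    selected_by = as.character(selected_by),
                    stringsAsFactors = FALSE)
  if (!is.null(source_datasets)) out$source_datasets <- source_datasets
  if (anyDuplicated(out$gene)) stop("duplicate genes in signature")
  ord <- order(out$score, out$rank_product, out$gene, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("Signature", "data.frame")
  out
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature: %d gene(s)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Constrain a signature to a marker pool
#'
#' Keeps only the signature genes that are also in the candidate marker
#' pool (common genes are retained), preserving the score order. With no
#' pool the signature passes through unchanged. An empty intersection is
#' allowed but warned about.
#'
#' @param signature a `Signature`.
#' @param pool a `GeneSetCollection` (or character vector of genes), or
#'   `NULL` for pass-through.
#' @return the constrained `Signature`.
#' @export
constrain_to_pool <- function(signature, pool = NULL) {
  stopifnot(inherits(signature, "Signature"))
  if (is.null(pool)) return(signature)
  genes <- if (inherits(pool, "GeneSetCollection")) pool_genes(pool) else as.character(pool)
  keep <- signature$gene %in% genes
  if (!any(keep)) {
    warning("signature and marker pool share no genes; empty signature")
  }
  out <- signature[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("Signature", "data.frame")
  out
}

#' Robust rank aggregation score
#'
#' For each gene with sorted normalized ranks r(1) <= ... <= r(m) over m
#' lists, the score is the minimum over k of the binomial tail probability
#' P(Binomial(m, r(k)) >= k) — how surprising it is, under uncorrelated
#' lists, that at least k of the m lists rank the gene within its k-th best
#' normalized rank — Bonferroni-corrected by m and capped at 1. Genes
#' missing from a list are imputed the worst normalized rank 1.
#'
#' @param rank_lists list of named numeric vectors; each vector gives the
#'   normalized ranks (in (0, 1]) of the genes present in that list.
#' @return named numeric vector of aggregation scores over the union of
#'   genes, smaller = more consistently top-ranked.
#' @export
rra_score <- function(rank_lists) {
  stopifnot(is.list(rank_lists), length(rank_lists) >= 1L)
  if (all(lengths(rank_lists) == 0L)) stop("all rank lists are empty")
  m <- length(rank_lists)
  universe <- unique(unlist(lapply(rank_lists, names)))
  if (is.null(universe)) stop("rank lists must be named by gene")

  vapply(universe, function(g) {
    r <- vapply(rank_lists, function(l) {
      v <- unname(l[g])
      if (is.na(v)) 1 else v
    }, numeric(1))
    if (any(r <= 0 | r > 1)) stop("normalized ranks must lie in (0, 1]")
    r <- sort(r)
    # P(Binom(m, r_k) >= k) for each order statistic k
    tails <- stats::pbinom(seq_len(m) - 1L, size = m, prob = r,
                           lower.tail = FALSE)
    min(1, m * min(tails))
  }, numeric(1))
}

#' Normalized ranks of a signature's genes
#'
#' Helper producing the rank vector RRA consumes: genes ordered by
#' ascending score, rank divided by the list length.
#'
#' @param signature a `Signature`.
#' @return named numeric vector in (0, 1].
#' @export
normalized_ranks <- function(signature) {
  stopifnot(inherits(signature, "Signature"))
  n <- nrow(signature)
  if (!n) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(seq_len(n) / n, signature$gene)
}

#' Aggregate signatures from multiple datasets
#'
#' `union` keeps every gene selected in any dataset; `intersect` keeps the
#' genes selected in all datasets; `RRA` re-scores the union by robust rank
#' aggregation of the per-dataset score orderings and keeps genes below
#' `rra_threshold`. Union and intersect order genes by the best (minimum)
#' per-dataset score; RRA orders by the aggregation score, which also
#' replaces the `score` column.
#'
#' @param signatures named list of `Signature` objects, one per dataset
#'   (>= 2 for `intersect` and `RRA`).
#' @param method `"union"`, `"intersect"`, or `"RRA"`.
#' @param rra_threshold significance threshold for the RRA route.
#' @return an aggregated `Signature` with a `source_datasets` column.
#' @export
aggregate_signatures <- function(signatures, method = c("union", "intersect", "RRA"),
                                 rra_threshold = 0.05) {
  method <- match.arg(method)
  stopifnot(is.list(signatures), length(signatures) >= 1L)
  lapply(signatures, function(s) stopifnot(inherits(s, "Signature")))
  if (is.null(names(signatures))) {
    names(signatures) <- paste0("dataset", seq_along(signatures))
  }
  if (method %in% c("intersect", "RRA") && length(signatures) < 2L) {
    stop(method, " aggregation needs at least two dataset signatures")
  }

  all_genes <- unique(unlist(lapply(signatures, `[[`, "gene")))
  sources <- lapply(all_genes, function(g) {
    names(signatures)[vapply(signatures, function(s) g %in% s$gene, TRUE)]
  })
  names(sources) <- all_genes
  best <- vapply(all_genes, function(g) {
    min(vapply(signatures, function(s) {
      v <- s$score[s$gene == g]
      if (length(v)) v else Inf
    }, numeric(1)))
  }, numeric(1))
  best_rp <- vapply(all_genes, function(g) {
    min(vapply(signatures, function(s) {
      v <- s$rank_product[s$gene == g]
      if (length(v)) v else Inf
    }, numeric(1)))
  }, numeric(1))

  genes <- switch(method,
    union = all_genes,
    intersect = all_genes[vapply(sources, length, 1L) == length(signatures)],
    RRA = {
      scores <- rra_score(lapply(signatures, normalized_ranks))
      best[names(scores)] <- scores  # RRA score becomes the ordering score
      names(scores)[scores < rra_threshold]
    })

  new_signature(gene = genes,
                rank_product = unname(best_rp[genes]),
                score = unname(best[genes]),
                selected_by = "rp",
                source_datasets = vapply(sources[genes], paste, "",
                                         collapse = ","))
}
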