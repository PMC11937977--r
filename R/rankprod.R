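#' Rank genes within each DE comparison
#'
#' Ranks are taken on the common gene universe (intersection of the result
#' tables): ascending in the chosen statistic, so rank 1 is the most
#' significant gene, except for `logFC` which ranks descending in |logFC|.
#' Ties receive the average rank.
#'
#' @param de_results named list of `DEResult` data.frames from
#'   [run_pairwise_de()].
#' @param statistic one of `"p_value"`, `"adj_p_value"`, `"logFC"`.
#' @return numeric matrix, genes x comparisons, of (possibly fractional)
#'   ranks; rownames = common gene universe, colnames = comparison names.
#' @export
rank_genes <- function(de_results,
                       statistic = c("p_value", "adj_p_value", "logFC")) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(de_results), length(de_results) >= 1L)
  universe <- Reduce(intersect, lapply(de_results, `[[`, "gene"))
  if (!length(universe)) stop("no genes common to all comparisons")

  ranks <- vapply(de_results, function(res) {
    v <- res[[statistic]][match(universe, res$gene)]
    if (statistic == "logFC") v <- -abs(v)
    rank(v, ties.method = "average")
  }, numeric(length(universe)))
  if (length(universe) == 1L) {
    ranks <- matrix(ranks, nrow = 1L, dimnames = list(universe, names(de_results)))
  } else {
    rownames(ranks) <- universe
  }
  ranks
}

#' Rank-product score
#'
#' For gene g across comparisons i, RP_g is the sum of natural-log ranks:
#' RP_g = sum_i ln(rank_{g,i}). A gene ranked first everywhere has RP = 0;
#' small values mean consistently top-ranked.
#'
#' @param ranks genes x comparisons rank matrix from [rank_genes()].
#' @return named numeric vector of RP values.
#' @export
compute_rp <- function(ranks) {
  ranks <- as.matrix(ranks)
  if (any(ranks < 1)) stop("ranks must be >= 1")
  rowSums(log(ranks))
}

#' Permutation probability score for rank products
#'
#' Bootstraps the null distribution of the rank product: in each of K
#' rounds the rank vector of every comparison is shuffled independently (a
#' random bijection of genes to the observed ranks), the random rank
#' product rp_g is recomputed, and the score of gene g is the empirical
#' probability P(RP_g > rp_g) — the fraction of rounds in which the
#' shuffled product falls strictly below the observed one. Smaller scores
#' are more significant; a gene ranked first in every comparison always
#' scores 0.
#'
#' With `exhaustive = TRUE` all (G!)^C combinations of within-comparison
#' shuffles are enumerated instead of sampled; feasible only for toy
#' instances.
#'
#' @param ranks genes x comparisons rank matrix.
#' @param K number of permutation rounds (ignored when exhaustive).
#' @param seed integer seed; permutation draws use R's default RNG,
#'   restored on exit.
#' @param exhaustive enumerate every shuffle combination exactly.
#' @param smooth use the (r+1)/(K+1) estimator instead of the plain
#'   empirical fraction, avoiding exact-zero scores.
#' @return object of class `RankProductResult`: data.frame with columns
#'   `gene`, `rank_product`, `score`; attributes `K`, `seed`, `ranks`.
#' @export
permutation_score <- function(ranks, K = 1000, seed = 1,
                              exhaustive = FALSE, smooth = FALSE) {
  ranks <- as.matrix(ranks)
  G <- nrow(ranks)
  C <- ncol(ranks)
  RP <- compute_rp(ranks)

  if (exhaustive) {
    perms <- all_permutations(G)
    n_perm <- nrow(perms)
    total <- n_perm^C
    if (total > 1e6) stop("exhaustive enumeration infeasible for this size")
    below <- numeric(G)
    idx <- rep(1L, C)
    logr <- log(ranks)
    repeat {
      rp <- numeric(G)
      for (j in seq_len(C)) rp <- rp + logr[perms[idx[j], ], j]
      below <- below + (rp < RP)
      # odometer increment over the C-fold product of permutations
      j <- 1L
      while (j <= C) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= n_perm) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > C) break
    }
    score <- if (smooth) (below + 1) / (total + 1) else below / total
    K_used <- total
  } else {
    stopifnot(K >= 1)
    logr <- log(ranks)
    below <- numeric(G)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    for (k in seq_len(K)) {
      rp <- numeric(G)
      for (j in seq_len(C)) rp <- rp + logr[sample.int(G), j]
      below <- below + (rp < RP)
    }
    score <- if (smooth) (below + 1) / (K + 1) else below / K
    K_used <- K
  }

  out <- data.frame(gene = rownames(ranks), rank_product = unname(RP),
                    score = unname(score), stringsAsFactors = FALSE)
  attr(out, "K") <- K_used
  attr(out, "seed") <- if (exhaustive) NA_integer_ else seed
  attr(out, "ranks") <- ranks
  class(out) <- c("RankProductResult", "data.frame")
  out
}

# all permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[i, ]
      out[r, ] <- row
    }
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Select signature genes from permutation scores
#'
#' Genes whose score falls strictly below `score_threshold` are selected
#' (reason `"rp"`). In addition, when `keep_group` names one or more
#' comparisons, the `keep_top` best-ranked genes of each named comparison's
#' own list are force-included regardless of score (reason `"keep_top"`) —
#' an escape hatch for targets with closely related sibling groups, where
#' the global threshold would starve the comparison that matters.
#'
#' @param rp_result `RankProductResult` from [permutation_score()].
#' @param score_threshold selection threshold on the permutation score
#'   (default 0.05).
#' @param keep_top number of top genes to rescue per kept comparison.
#' @param keep_group character vector of comparison names (column names of
#'   the rank matrix) whose top genes are rescued; required when
#'   `keep_top` is set.
#' @return object of class `Signature` (data.frame `gene`, `rank_product`,
#'   `score`, `selected_by`, ordered by ascending score).
#' @export
select_genes <- function(rp_result, score_threshold = 0.05,
                         keep_top = NULL, keep_group = NULL) {
  stopifnot(inherits(rp_result, "RankProductResult"))
  if (score_threshold <= 0 || score_threshold > 1) {
    stop("score_threshold must be in (0, 1]")
  }
  selected <- rp_result$score < score_threshold
  # threshold 1.0 is the documented "select everything" boundary
  if (score_threshold == 1) selected <- rep(TRUE, nrow(rp_result))
  reason <- ifelse(selected, "rp", NA_character_)

  if (!is.null(keep_top)) {
    if (is.null(keep_group)) stop("keep_top requires keep_group")
    ranks <- attr(rp_result, "ranks")
    unknown <- setdiff(keep_group, colnames(ranks))
    if (length(unknown)) {
      stop("keep_group names unknown comparison(s): ",
           paste(unknown, collapse = ", "))
    }
    for (cmp in keep_group) {
      top <- order(ranks[, cmp])[seq_len(min(keep_top, nrow(ranks)))]
      rescue <- top[!selected[top]]
      selected[rescue] <- TRUE
      reason[rescue] <- "keep_top"
    }
  }

  out <- rp_result[selected, c("gene", "rank_product", "score"), drop = FALSE]
  out$selected_by <- reason[selected]
  new_signature(gene = out$gene, rank_product = out$rank_product,
                score = out$score, selected_by = out$selected_by)
}
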