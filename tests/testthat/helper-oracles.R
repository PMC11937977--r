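# Independent brute-force oracles. These are deliberately written from the
# method definitions, not by calling the package or edgeR/limma internals.

# Trimmed weighted mean of M-values, per the published TMM recipe:
# reference = sample whose 75th count-percentile/library-size is closest to
# the mean; per sample, M = log2 ratio of depth-scaled counts to the
# reference, A = average log2 abundance, inverse-variance (delta-method)
# weights; drop non-finite pairs, doubly rank-trim M (30%) and A (5%),
# weighted-average the surviving M; factors scaled to geometric mean 1.
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(obs, nO, rf, nR) {
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1
    hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }

  f <- vapply(seq_len(ncol(counts)), function(j) {
    one_factor(counts[, j], lib[j], counts[, ref], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Count-filter rule: >= min_count CPM-equivalent (at the median library
# size) in at least k samples, k = smallest group size (soft-capped at
# large_n), and total count >= min_total.
oracle_filter_rule <- function(counts, group, min_count = 10, min_total = 15,
                               large_n = 10, min_prop = 0.7) {
  lib <- colSums(counts)
  k <- min(table(group))
  if (k > large_n) k <- large_n + (k - large_n) * min_prop
  cutoff <- min_count / stats::median(lib) * 1e6
  cpm <- t(t(counts) / lib) * 1e6
  tol <- 1e-14
  rowSums(cpm >= cutoff) >= (k - tol) & rowSums(counts) >= (min_total - tol)
}

# all permutations of a vector, lexicographic-by-construction (recursive
# selection of each leading element)
oracle_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- oracle_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

# Exhaustive rank-product permutation scores: enumerate every combination
# of within-comparison shuffles, count combinations whose random rank
# product falls strictly below the observed one.
oracle_exhaustive_scores <- function(ranks) {
  ranks <- as.matrix(ranks)
  G <- nrow(ranks)
  C <- ncol(ranks)
  RP <- rowSums(log(ranks))
  per_col <- lapply(seq_len(C), function(j) oracle_perms(ranks[, j]))
  n_perm <- nrow(per_col[[1]])
  combos <- expand.grid(rep(list(seq_len(n_perm)), C))
  below <- numeric(G)
  for (r in seq_len(nrow(combos))) {
    rp <- numeric(G)
    for (j in seq_len(C)) rp <- rp + log(per_col[[j]][combos[r, j], ])
    below <- below + (rp < RP)
  }
  setNames(below / nrow(combos), rownames(ranks))
}

# Ordinary per-gene weighted least-squares t-test of a contrast, via lm()
oracle_weighted_t <- function(y, design, weights, cvec, lfc = 0) {
  t(vapply(seq_len(nrow(y)), function(g) {
    w <- if (is.null(weights)) rep(1, ncol(y)) else weights[g, ]
    fit <- stats::lm(y[g, ] ~ 0 + design, weights = w)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    df <- fit$df.residual
    if (lfc == 0) {
      p <- 2 * stats::pt(-abs(est / se), df)
    } else {
      p <- stats::pt((abs(est) - lfc) / se, df, lower.tail = FALSE) +
        stats::pt((abs(est) + lfc) / se, df, lower.tail = FALSE)
    }
    c(logFC = est, p = p)
  }, numeric(2)))
}

# RRA score by explicit binomial tail sums (no pbinom)
oracle_rra <- function(r) {
  r <- sort(r)
  m <- length(r)
  tails <- vapply(seq_len(m), function(k) {
    sum(vapply(k:m, function(j) {
      choose(m, j) * r[k]^j * (1 - r[k])^(m - j)
    }, numeric(1)))
  }, numeric(1))
  min(1, m * min(tails))
}
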