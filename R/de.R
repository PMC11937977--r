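#' Build a group-means design matrix with optional batch covariates
#'
#' One indicator column per group (no intercept), plus treatment-coded batch
#' columns (reference batch omitted) when a `Batch` annotation is present.
#' Batch is modeled as a fixed effect rather than removed from the data
#' beforehand: covariate modeling preserves the count mean-variance
#' relationship that batch-corrected expression destroys.
#'
#' @param annotations per-sample data.frame with `Group` and optionally
#'   `Batch` columns (as in an `ExpressionDataset`).
#' @return numeric design matrix with attributes `group_labels` (character,
#'   one per group column) and `n_groups`.
#' @export
build_design <- function(annotations) {
  grp <- as.character(annotations$Group)
  groups <- unique(grp)
  if (length(groups) < 2L) stop("need at least two groups")

  design <- vapply(groups, function(g) as.numeric(grp == g),
                   numeric(length(grp)))
  colnames(design) <- groups
  rownames(design) <- rownames(annotations)

  if ("Batch" %in% colnames(annotations)) {
    bat <- as.character(annotations$Batch)
    batches <- unique(bat)
    if (length(batches) > 1L) {
      bcols <- vapply(batches[-1L], function(b) as.numeric(bat == b),
                      numeric(length(bat)))
      colnames(bcols) <- paste0("batch_", batches[-1L])
      design <- cbind(design, bcols)
    }
  }

  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient (a batch is confounded with a group)")
  }
  attr(design, "group_labels") <- groups
  attr(design, "n_groups") <- length(groups)
  design
}

#' Filter genes with too few counts to analyse
#'
#' Thin wrapper over `edgeR::filterByExpr`: keeps genes with at least
#' `min_count` counts-per-million-equivalent in at least k samples (k = the
#' smallest group size) and a total count of at least `min_total`.
#'
#' @param dataset an `ExpressionDataset` with `scale = "raw_counts"`.
#' @param min_count minimum per-sample count (CPM-equivalent at the median
#'   library size).
#' @param min_total minimum total count across all samples.
#' @return named logical vector over genes (`TRUE` = keep).
#' @export
filter_low_expression <- function(dataset, min_count = 10, min_total = 15) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$scale != "raw_counts") {
    stop("count filtering requires raw counts; see filter_low_logexpr()")
  }
  keep <- edgeR::filterByExpr(dataset$values,
                              group = dataset$annotations$Group,
                              min.count = min_count,
                              min.total.count = min_total)
  stats::setNames(as.logical(keep), dataset$genes)
}

#' Filter genes on the log-expression route
#'
#' For log-normalized input the count-based rule does not apply; genes are
#' kept when their mean log-expression reaches `min_mean` and at least k
#' samples (k = smallest group size by default) exceed `expr_floor`.
#'
#' @param dataset an `ExpressionDataset` with `scale = "log_expression"`.
#' @param min_mean minimum mean log2 expression (default 1.0).
#' @param expr_floor per-sample log2 expression floor (default 1.0).
#' @param min_samples number of samples that must exceed `expr_floor`;
#'   defaults to the smallest group size.
#' @return named logical vector over genes.
#' @export
filter_low_logexpr <- function(dataset, min_mean = 1.0, expr_floor = 1.0,
                               min_samples = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$scale != "log_expression") {
    stop("log-expression filtering requires scale = 'log_expression'")
  }
  if (is.null(min_samples)) {
    min_samples <- min(table(dataset$annotations$Group))
  }
  keep <- rowMeans(dataset$values) >= min_mean &
    rowSums(dataset$values >= expr_floor) >= min_samples
  stats::setNames(keep, dataset$genes)
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalization (`edgeR::calcNormFactors`,
#' method `"TMM"`): per-sample factors are inverse-variance-weighted means
#' of gene-wise log-ratios to a reference sample, after trimming the most
#' extreme 30% of M-values and 5% of A-values; factors are scaled so their
#' geometric mean is 1.
#'
#' @param counts gene-by-sample count matrix (or an `ExpressionDataset`
#'   with raw counts).
#' @param logratio_trim,sum_trim trim fractions for M and A values.
#' @return named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  if (inherits(counts, "ExpressionDataset")) {
    if (counts$scale != "raw_counts") stop("TMM requires raw counts")
    counts <- counts$values
  }
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Mean-variance precision weights (voom)
#'
#' Computes log2-CPM (0.5 count offset) and per-observation precision
#' weights from the fitted mean-variance trend (`limma::voom`): gene-wise
#' linear models are fit to the log2-CPM, a lowess curve of sqrt residual
#' standard deviation against mean log-count is interpolated at each fitted
#' value, and the weight is the inverse of the squared trend value.
#'
#' @param counts filtered count matrix.
#' @param design design matrix from [build_design()].
#' @param factors TMM factors from [tmm_factors()] (optional; unit factors
#'   if missing).
#' @return `limma::EList` with elements `E` (log2-CPM) and `weights`.
#' @export
precision_weights <- function(counts, design, factors = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("too few genes to estimate a mean-variance trend")
  if (ncol(counts) <= ncol(design)) {
    stop("no residual degrees of freedom for the mean-variance trend")
  }
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  limma::voom(counts, design, lib.size = lib * factors)
}

#' Fit gene-wise linear models and test a group contrast
#'
#' Weighted least squares per gene, empirical-Bayes moderation of the
#' residual variances, and a fold-change-threshold test of the contrast.
#' With `lfc_threshold = 0` this is the ordinary moderated t-test; with a
#' positive threshold the null hypothesis is |true logFC| <= threshold and
#' the p-value conservatively combines both shifted-null tails. Setting
#' `prior_df = 0` disables moderation, giving ordinary per-gene weighted
#' t-tests; `trend = TRUE` uses a mean-dependent prior variance trend (the
#' route for log-expression input without count-based weights).
#'
#' @param log_expr log-expression matrix, or the `EList` from
#'   [precision_weights()] (which carries the observation weights).
#' @param design design matrix from [build_design()].
#' @param contrast numeric contrast vector over design columns (target
#'   minus other on the group columns), or the name of the target and other
#'   group as a length-2 character vector.
#' @param lfc_threshold non-negative log2-fold-change threshold.
#' @param trend logical, mean-trended prior variance.
#' @param prior_df `NULL` (estimate by empirical Bayes) or `0` (no
#'   moderation).
#' @param weights optional observation weight matrix when `log_expr` is a
#'   plain matrix.
#' @return data.frame (`DEResult`): `gene`, `logFC`, `t`, `p_value`,
#'   `adj_p_value` (Benjamini-Hochberg within the comparison),
#'   `mean_expression`; attribute `comparison` names the contrast.
#' @export
fit_and_test <- function(log_expr, design, contrast, lfc_threshold = 0,
                         trend = FALSE, prior_df = NULL, weights = NULL) {
  if (lfc_threshold < 0) stop("lfc_threshold must be non-negative")

  if (is.character(contrast)) {
    stopifnot(length(contrast) == 2L)
    cvec <- numeric(ncol(design))
    names(cvec) <- colnames(design)
    if (!all(contrast %in% colnames(design))) {
      stop("contrast groups not in design: ", paste(contrast, collapse = " vs "))
    }
    cvec[contrast[1]] <- 1
    cvec[contrast[2]] <- -1
    comparison <- paste0(contrast[1], "-", contrast[2])
  } else {
    cvec <- contrast
    comparison <- paste(colnames(design)[cvec != 0], collapse = "-")
  }

  fit <- limma::lmFit(log_expr, design, weights = weights)
  fit <- limma::contrasts.fit(fit, contrasts = cvec)

  if (!is.null(prior_df) && prior_df == 0) {
    # no shrinkage: ordinary weighted least-squares t-tests on df.residual
    coef <- as.numeric(fit$coefficients)
    se <- as.numeric(fit$stdev.unscaled) * fit$sigma
    df <- fit$df.residual
    if (lfc_threshold == 0) {
      tstat <- coef / se
      p <- 2 * stats::pt(-abs(tstat), df = df)
    } else {
      t_right <- (abs(coef) - lfc_threshold) / se
      t_left <- (abs(coef) + lfc_threshold) / se
      p <- stats::pt(t_right, df = df, lower.tail = FALSE) +
        stats::pt(t_left, df = df, lower.tail = FALSE)
      tstat <- sign(coef) * t_right
    }
    res <- data.frame(gene = rownames(fit$coefficients),
                      logFC = coef, t = tstat, p_value = p,
                      mean_expression = fit$Amean,
                      stringsAsFactors = FALSE)
  } else {
    tr <- limma::treat(fit, lfc = lfc_threshold, trend = trend)
    res <- data.frame(gene = rownames(tr$coefficients),
                      logFC = as.numeric(tr$coefficients),
                      t = as.numeric(tr$t),
                      p_value = as.numeric(tr$p.value),
                      mean_expression = tr$Amean,
                      stringsAsFactors = FALSE)
  }
  res$adj_p_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[, c("gene", "logFC", "t", "p_value", "adj_p_value",
                 "mean_expression")]
  rownames(res) <- NULL
  attr(res, "comparison") <- comparison
  res
}

#' Differential expression of the target group against every other group
#'
#' The full DE stage: expression filtering, TMM normalization and voom
#' precision weighting for raw counts (or threshold filtering and the
#' mean-variance trend route for log-expression input), one linear model fit
#' over the group-means + batch design, then a threshold test of target
#' minus other for each of the n-1 non-target groups.
#'
#' @param dataset an `ExpressionDataset`.
#' @param target_group group label of interest.
#' @param lfc_threshold log2-fold-change threshold for the tests.
#' @param min_count,min_total count-filter thresholds (raw counts route).
#' @param min_mean,expr_floor log-expression filter thresholds.
#' @return named list of `DEResult` data.frames, one per comparison, names
#'   `"<target>-<other>"`.
#' @export
run_pairwise_de <- function(dataset, target_group, lfc_threshold = 0,
                            min_count = 10, min_total = 15,
                            min_mean = 1.0, expr_floor = 1.0) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  groups <- unique(dataset$annotations$Group)
  if (!target_group %in% groups) {
    stop("target group '", target_group, "' not present; groups: ",
         paste(groups, collapse = ", "))
  }
  if (length(groups) < 2L) stop("need at least two groups")
  design <- build_design(dataset$annotations)
  others <- setdiff(groups, target_group)

  if (dataset$scale == "raw_counts") {
    keep <- filter_low_expression(dataset, min_count = min_count,
                                  min_total = min_total)
    counts <- dataset$values[keep, , drop = FALSE]
    if (nrow(counts) < 2L) stop("fewer than two genes survive count filtering")
    factors <- tmm_factors(counts)
    v <- precision_weights(counts, design, factors)
    results <- lapply(others, function(g) {
      fit_and_test(v, design, contrast = c(target_group, g),
                   lfc_threshold = lfc_threshold)
    })
  } else {
    keep <- filter_low_logexpr(dataset, min_mean = min_mean,
                               expr_floor = expr_floor)
    E <- dataset$values[keep, , drop = FALSE]
    if (nrow(E) < 2L) stop("fewer than two genes survive expression filtering")
    results <- lapply(others, function(g) {
      fit_and_test(E, design, contrast = c(target_group, g),
                   lfc_threshold = lfc_threshold, trend = TRUE)
    })
  }
  names(results) <- paste0(target_group, "-", others)
  results
}
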