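#' Maximum-likelihood normal fit to one sample's log-expression
#'
#' Under the working null that genes within a sample are not differentially
#' expressed, the log-expression values across genes are modeled as
#' N(mu, sigma^2); mu is the sample mean and sigma the maximum-likelihood
#' (divide-by-n) standard deviation.
#'
#' @param x numeric vector of log-expression values for one sample.
#' @return list with elements `mu` and `sigma`.
#' @export
fit_sample_normal <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least two values")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate fit: all values identical")
  list(mu = mu, sigma = sigma)
}

#' Within-sample percentile transform of expression values
#'
#' Converts expression to within-sample relative expression: each entry
#' (g, s) becomes Phi((x_gs - mu_s) / sigma_s), the Gaussian CDF evaluated
#' with that sample's fitted parameters. The transform absorbs any per-
#' sample affine rescaling of the log-expression (location into mu, scale
#' into sigma), which is what makes signal and background datasets
#' comparable without joint renormalization. Raw counts are converted to
#' log2-CPM (0.5 prior count) first.
#'
#' @param dataset an `ExpressionDataset` (or plain log-expression matrix).
#' @return numeric matrix of percentiles in (0, 1), same dimnames.
#' @export
percentile_transform <- function(dataset) {
  if (inherits(dataset, "ExpressionDataset")) {
    x <- if (dataset$scale == "raw_counts") {
      edgeR::cpm(dataset$values, log = TRUE, prior.count = 0.5)
    } else {
      dataset$values
    }
  } else {
    x <- as.matrix(dataset)
  }
  out <- vapply(seq_len(ncol(x)), function(s) {
    fit <- fit_sample_normal(x[, s])
    stats::pnorm(x[, s], mean = fit$mu, sd = fit$sigma)
  }, numeric(nrow(x)))
  dimnames(out) <- dimnames(x)
  out
}

#' Percentile-based signal-to-noise ratio against a background dataset
#'
#' For each gene shared between the two datasets, a normal distribution is
#' fitted (MLE) to the gene's percentile values across the signal samples
#' and, separately, across the background samples. The median of each fit
#' is its mean (F^{-1}(0.5 | mu, sigma^2) = mu), so the statistic reduces
#' to a Cohen's-d-style effect size on within-sample relative expression:
#'
#'   snr = (xS - xB) / sigmaB
#'
#' where xS and xB are the mean signal and background percentiles of the
#' gene and sigmaB the (divide-by-n) SD of its background percentiles.
#'
#' @param signal_percentiles percentile matrix of the signal samples
#'   (typically the target-group columns of [percentile_transform()]
#'   output).
#' @param background_percentiles percentile matrix of the background
#'   dataset.
#' @return `SnrTable` data.frame: `gene`, `x_signal`, `x_background`,
#'   `sd_background`, `snr`. Genes with zero background SD get `NA` snr
#'   (flagged by downstream filtering).
#' @export
compute_snr <- function(signal_percentiles, background_percentiles) {
  sig <- as.matrix(signal_percentiles)
  bg <- as.matrix(background_percentiles)
  genes <- intersect(rownames(sig), rownames(bg))
  if (!length(genes)) stop("no genes shared between signal and background")
  sig <- sig[genes, , drop = FALSE]
  bg <- bg[genes, , drop = FALSE]

  if (ncol(sig) == 1L) {
    warning("single signal sample: the per-gene fit degenerates to a point")
  }
  x_s <- rowMeans(sig)
  x_b <- rowMeans(bg)
  sd_b <- sqrt(rowMeans((bg - x_b)^2))
  snr <- ifelse(sd_b > 0, (x_s - x_b) / sd_b, NA_real_)

  out <- data.frame(gene = genes, x_signal = unname(x_s),
                    x_background = unname(x_b),
                    sd_background = unname(sd_b),
                    snr = unname(snr), stringsAsFactors = FALSE)
  class(out) <- c("SnrTable", "data.frame")
  out
}

#' Refine a signature by its background signal-to-noise ratio
#'
#' Removes genes whose SNR against the background dataset falls below the
#' threshold — genes expressed just as highly in the microenvironment carry
#' no discriminative power — with two exceptions: genes in the protected
#' marker pool are always retained (they were curated as biologically
#' meaningful), and genes that could not be assessed (absent from the
#' background data, or undefined SNR with signal not above background when
#' the background SD is zero, handled conservatively) are retained with a
#' warning.
#'
#' @param signature a `Signature`.
#' @param snr_table `SnrTable` from [compute_snr()].
#' @param threshold minimum SNR to keep a gene (default 1).
#' @param pool protected `GeneSetCollection` (or gene vector), or `NULL`.
#' @return the refined `Signature`; pool-protected genes that failed the
#'   SNR cut carry `selected_by = "pool"`.
#' @export
filter_by_snr <- function(signature, snr_table, threshold = 1, pool = NULL) {
  stopifnot(inherits(signature, "Signature"))
  if (threshold < 0) stop("snr threshold must be non-negative")
  protected <- if (is.null(pool)) character(0) else {
    if (inherits(pool, "GeneSetCollection")) pool_genes(pool) else as.character(pool)
  }

  idx <- match(signature$gene, snr_table$gene)
  snr <- snr_table$snr[idx]
  assessed <- !is.na(idx)
  if (any(!assessed)) {
    warning(sum(!assessed), " signature gene(s) absent from the background ",
            "data; retained unassessed")
  }
  undefined <- assessed & is.na(snr)
  if (any(undefined)) {
    # zero background SD: keep only if the signal median clearly exceeds
    # the background median
    dx <- snr_table$x_signal[idx] - snr_table$x_background[idx]
    keep_undef <- undefined & dx > 0
    warning(sum(undefined), " gene(s) with zero background variance; ",
            "kept when signal exceeds background")
    snr[undefined] <- ifelse(keep_undef[undefined], Inf, -Inf)
  }

  passes <- !assessed | snr >= threshold
  is_protected <- signature$gene %in% protected
  keep <- passes | is_protected

  out <- signature[keep, , drop = FALSE]
  out$selected_by[!passes[keep] & is_protected[keep]] <- "pool"
  rownames(out) <- NULL
  class(out) <- c("Signature", "data.frame")
  out
}
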