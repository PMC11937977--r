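#' Simulate a multi-group bulk RNA-seq count dataset with planted markers
#'
#' Negative-binomial counts with log-normal base means, the standard
#' generative family for bulk RNA-seq. Each group receives a disjoint block
#' of planted marker genes whose expected expression is multiplied by
#' 2^lfc in that group only; optional multiplicative batch effects perturb
#' a random subset of genes per batch. The returned truth object records
#' everything needed to score a recovered signature.
#'
#' @param n_groups number of sample groups (labels `G1`, `G2`, ...).
#' @param n_per_group samples per group.
#' @param n_genes total genes (`gene0001`, ...).
#' @param n_markers_per_group planted markers per group (disjoint blocks).
#' @param lfc planted log2 fold change of each marker in its group.
#' @param n_batches number of batches, assigned round-robin across samples;
#'   1 disables batch structure.
#' @param batch_sd SD of the per-batch per-gene log-normal effect.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param base_meanlog,base_sdlog log-normal parameters of gene base means.
#' @param seed integer seed (RNG state restored on exit).
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (class `SimulationTruth`): `markers` (named list per group),
#'   `base_means`, `lfc`, `batch_effects`, `dispersion`, `seed`.
#' @export
generate_counts <- function(n_groups = 4, n_per_group = 5, n_genes = 2000,
                            n_markers_per_group = 50, lfc = 2,
                            n_batches = 1, batch_sd = 0,
                            dispersion = 0.1,
                            base_meanlog = 4, base_sdlog = 1.2,
                            seed = 1) {
  stopifnot(n_groups >= 1, n_per_group >= 1, n_genes >= 1,
            n_markers_per_group >= 0, lfc >= 0, dispersion > 0)
  if (n_markers_per_group * n_groups > n_genes) {
    stop("total planted markers exceed the number of genes")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  groups <- paste0("G", seq_len(n_groups))
  n_samples <- n_groups * n_per_group
  samples <- sprintf("S%03d", seq_len(n_samples))
  group_of <- rep(groups, each = n_per_group)
  batch_of <- rep_len(paste0("B", seq_len(n_batches)), n_samples)

  base_means <- stats::rlnorm(n_genes, meanlog = base_meanlog,
                              sdlog = base_sdlog)
  names(base_means) <- genes

  markers <- list()
  taken <- 0L
  for (g in groups) {
    markers[[g]] <- genes[seq_len(n_markers_per_group) + taken]
    taken <- taken + n_markers_per_group
  }

  # expected value per gene x sample: base mean, marker boost in own group,
  # batch wobble
  mu <- matrix(base_means, nrow = n_genes, ncol = n_samples,
               dimnames = list(genes, samples))
  for (g in groups) {
    mu[markers[[g]], group_of == g] <- mu[markers[[g]], group_of == g] * 2^lfc
  }
  batch_effects <- NULL
  if (n_batches > 1 && batch_sd > 0) {
    batch_effects <- vapply(unique(batch_of), function(b) {
      exp(stats::rnorm(n_genes, mean = 0, sd = batch_sd))
    }, numeric(n_genes))
    rownames(batch_effects) <- genes
    for (b in colnames(batch_effects)) {
      mu[, batch_of == b] <- mu[, batch_of == b] * batch_effects[, b]
    }
  }

  counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                  mu = mu, size = 1 / dispersion),
                   nrow = n_genes, dimnames = list(genes, samples))
  ann <- data.frame(Sample = samples, Group = group_of,
                    stringsAsFactors = FALSE)
  if (n_batches > 1) ann$Batch <- batch_of

  truth <- structure(
    list(markers = markers, base_means = base_means, lfc = lfc,
         batch_effects = batch_effects, dispersion = dispersion,
         seed = seed),
    class = "SimulationTruth")
  list(dataset = expression_dataset(counts, ann, scale = "raw_counts"),
       truth = truth)
}

#' Simulate a background (microenvironment) dataset
#'
#' Generates a single-group count matrix over the same genes as a simulated
#' signal dataset, in which a chosen fraction of each group's planted
#' markers is also highly expressed ("ubiquitous" in the background) while
#' the remaining markers stay low. An SNR filter run against this
#' background should remove exactly the ubiquitous markers.
#'
#' @param truth `SimulationTruth` from [generate_counts()].
#' @param overlap_fraction fraction of each group's markers made
#'   background-high (per-group counts rounded down).
#' @param n_samples background samples.
#' @param high_lfc log2 boost applied to ubiquitous genes in the
#'   background; non-ubiquitous markers are suppressed by the same amount.
#' @param dispersion negative-binomial dispersion.
#' @param seed integer seed.
#' @return list with `dataset` (an [expression_dataset()], group
#'   `"background"`) and `ubiquitous_genes` (character vector).
#' @export
generate_background <- function(truth, overlap_fraction, n_samples = 20,
                                high_lfc = 3, dispersion = 0.1, seed = 1) {
  stopifnot(inherits(truth, "SimulationTruth"),
            overlap_fraction >= 0, overlap_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  genes <- names(truth$base_means)
  samples <- sprintf("BG%03d", seq_len(n_samples))
  mu <- matrix(truth$base_means, nrow = length(genes), ncol = n_samples,
               dimnames = list(genes, samples))

  ubiquitous <- character(0)
  for (g in names(truth$markers)) {
    mk <- truth$markers[[g]]
    n_ubi <- floor(overlap_fraction * length(mk))
    ubi <- mk[seq_len(n_ubi)]
    low <- setdiff(mk, ubi)
    mu[ubi, ] <- mu[ubi, ] * 2^high_lfc
    mu[low, ] <- mu[low, ] / 2^high_lfc
    ubiquitous <- c(ubiquitous, ubi)
  }

  counts <- matrix(stats::rnbinom(length(genes) * n_samples,
                                  mu = mu, size = 1 / dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
  ann <- data.frame(Sample = samples, Group = "background",
                    stringsAsFactors = FALSE)
  list(dataset = expression_dataset(counts, ann, scale = "raw_counts"),
       ubiquitous_genes = ubiquitous)
}
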