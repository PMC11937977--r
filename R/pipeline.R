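#' Validate and normalize a run configuration
#'
#' Accepts a list (or a path to a YAML/JSON file) of settings, fills in
#' defaults, and rejects unknown or inconsistent keys. Defaults: score
#' threshold 0.05, logFC threshold 0, K = 1000 permutations, rank statistic
#' `p_value`, aggregation `union`, SNR threshold 1, marker direction `up`.
#'
#' @param config list of settings or a file path.
#' @return normalized list of class `RunConfig`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))

  defaults <- list(
    target_group = NULL,
    rank_statistic = "p_value",
    score_threshold = 0.05,
    lfc_threshold = 0,
    n_permutations = 1000L,
    seed = 1L,
    keep_top = NULL,
    keep_group = NULL,
    aggregation = "union",
    snr_threshold = 1,
    direction = "up",
    min_count = 10,
    min_total = 15,
    min_mean = 1.0,
    expr_floor = 1.0,
    de_alpha = 0.05,
    smooth_scores = FALSE
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])

  if (!cfg$rank_statistic %in% c("p_value", "adj_p_value", "logFC")) {
    stop("rank_statistic must be p_value, adj_p_value, or logFC")
  }
  if (cfg$score_threshold <= 0 || cfg$score_threshold > 1) {
    stop("score_threshold must be in (0, 1]")
  }
  if (cfg$lfc_threshold < 0) stop("lfc_threshold must be non-negative")
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  if (!cfg$aggregation %in% c("RRA", "union", "intersect")) {
    stop("aggregation must be RRA, union, or intersect")
  }
  if (cfg$snr_threshold < 0) stop("snr_threshold must be non-negative")
  if (cfg$de_alpha <= 0 || cfg$de_alpha > 1) stop("de_alpha must be in (0, 1]")
  if (!cfg$direction %in% c("up", "any")) stop("direction must be up or any")
  if (!is.null(cfg$keep_top) && is.null(cfg$keep_group)) {
    stop("keep_top requires keep_group")
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Run the full marker-screening workflow
#'
#' End-to-end pipeline over one or more datasets: pairwise DE of the target
#' group against every other group, rank-product permutation scoring,
#' selection at the score threshold (with optional keep_top rescue), a
#' common-DEG eligibility gate (markers must be significant at `de_alpha`
#' and, by default, up-regulated toward the target in every comparison),
#' constraint to the marker pool, aggregation across datasets, and SNR
#' refinement against a background dataset.
#'
#' @param datasets an `ExpressionDataset` or list of them (named; names
#'   are used in aggregation provenance).
#' @param config a `RunConfig` from [validate_config()] (or a raw list);
#'   `target_group` is required.
#' @param pool optional `GeneSetCollection` marker pool: the selection is
#'   intersected with it, and its genes are protected from SNR removal.
#' @param background optional `ExpressionDataset` of microenvironment
#'   expression for SNR filtering.
#' @param out_dir optional output directory; writes `signature.tsv`,
#'   `snr.tsv` (when a background is given) and `manifest.json`.
#' @param keep_intermediates also write per-comparison DE tables and
#'   per-dataset score tables under `out_dir`.
#' @param quiet suppress stage progress messages (written to stderr).
#' @return list with `signature` (a `Signature`), `snr_table` (or `NULL`),
#'   `manifest` (config echo, per-stage gene counts, versions).
#' @export
run_workflow <- function(datasets, config, pool = NULL, background = NULL,
                         out_dir = NULL, keep_intermediates = FALSE,
                         quiet = FALSE) {
  if (inherits(datasets, "ExpressionDataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  if (!inherits(config, "RunConfig")) config <- validate_config(config)
  if (is.null(config$target_group)) stop("config$target_group is required")
  say <- function(...) if (!quiet) message("[sigscreen] ", sprintf(...))

  stage_counts <- list()
  per_dataset <- list()
  de_tables <- list()

  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    say("dataset %s: DE of %s vs %d other group(s)", nm, config$target_group,
        length(unique(ds$annotations$Group)) - 1L)
    de <- run_pairwise_de(ds, config$target_group,
                          lfc_threshold = config$lfc_threshold,
                          min_count = config$min_count,
                          min_total = config$min_total,
                          min_mean = config$min_mean,
                          expr_floor = config$expr_floor)
    de_tables[[nm]] <- de
    ranks <- rank_genes(de, statistic = config$rank_statistic)
    stage_counts[[paste0(nm, ".post_filter")]] <- nrow(ranks)
    say("dataset %s: %d genes in the common universe; %d permutations",
        nm, nrow(ranks), config$n_permutations)
    rp <- permutation_score(ranks, K = config$n_permutations,
                            seed = config$seed + match(nm, names(datasets)) - 1L,
                            smooth = config$smooth_scores)
    sig <- select_genes(rp, score_threshold = config$score_threshold,
                        keep_top = config$keep_top,
                        keep_group = config$keep_group)
    # eligibility gate: a marker must be a DEG common to all comparisons —
    # significant at de_alpha (and up-regulated toward the target when
    # direction = "up") in every list. keep_top rescues bypass the gate.
    if (nrow(sig)) {
      eligible <- Reduce(`&`, lapply(de, function(res) {
        ok <- res$adj_p_value < config$de_alpha
        if (config$direction == "up") ok <- ok & res$logFC > 0
        stats::setNames(ok, res$gene)[sig$gene]
      }))
      sig <- sig[eligible | sig$selected_by == "keep_top", , drop = FALSE]
      class(sig) <- c("Signature", "data.frame")
    }
    say("dataset %s: %d gene(s) selected", nm, nrow(sig))
    per_dataset[[nm]] <- sig
  }
  stage_counts$post_rp <- length(unique(unlist(lapply(per_dataset, `[[`, "gene"))))

  signature <- if (length(per_dataset) > 1L) {
    say("aggregating %d dataset signatures by %s", length(per_dataset),
        config$aggregation)
    aggregate_signatures(per_dataset, method = config$aggregation)
  } else {
    per_dataset[[1L]]
  }

  signature <- constrain_to_pool(signature, pool)
  stage_counts$post_pool <- nrow(signature)
  if (!is.null(pool)) say("%d gene(s) after marker-pool constraint", nrow(signature))

  snr_table <- NULL
  if (!is.null(background)) {
    say("SNR refinement against %d background sample(s)",
        length(background$samples))
    signal_pct <- do.call(cbind, lapply(datasets, function(ds) {
      pct <- percentile_transform(ds)
      pct[, ds$annotations$Group == config$target_group, drop = FALSE]
    }))
    bg_pct <- percentile_transform(background)
    snr_table <- compute_snr(signal_pct, bg_pct)
    signature <- filter_by_snr(signature, snr_table,
                               threshold = config$snr_threshold, pool = pool)
    say("%d gene(s) after SNR filtering", nrow(signature))
  }
  stage_counts$post_snr <- nrow(signature)
  if (!nrow(signature)) warning("empty signature")

  manifest <- list(
    package = "sigscreen",
    version = as.character(utils::packageVersion("sigscreen")),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    datasets = names(datasets),
    stage_counts = stage_counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signature(signature, file.path(out_dir, "signature.tsv"),
                    snr_table = snr_table)
    if (!is.null(snr_table)) {
      write_snr_table(snr_table, file.path(out_dir, "snr.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (keep_intermediates) {
      for (nm in names(de_tables)) {
        for (cmp in names(de_tables[[nm]])) {
          utils::write.table(de_tables[[nm]][[cmp]],
                             file.path(out_dir, sprintf("de_%s_%s.tsv", nm, cmp)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        utils::write.table(as.data.frame(per_dataset[[nm]]),
                           file.path(out_dir, sprintf("scores_%s.tsv", nm)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  list(signature = signature, snr_table = snr_table, manifest = manifest)
}
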