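make_ann <- function(groups, batches = NULL) {
  ann <- data.frame(Group = groups,
                    row.names = sprintf("s%d", seq_along(groups)),
                    stringsAsFactors = FALSE)
  if (!is.null(batches)) ann$Batch <- batches
  ann
}

test_that("design matrix uses group-means coding with appended batch terms", {
  d <- build_design(make_ann(c("A", "A", "B", "B", "C", "C")))
  expect_equal(dim(d), c(6L, 3L))
  expect_equal(unname(colSums(d)), c(2, 2, 2))
  expect_equal(rowSums(d[, 1:3]), setNames(rep(1, 6), rownames(d)))

  db <- build_design(make_ann(c("A", "A", "B", "B", "C", "C"),
                              c("1", "1", "1", "2", "2", "2")))
  expect_equal(dim(db), c(6L, 4L))
  expect_equal(attr(db, "n_groups"), 3L)

  expect_error(build_design(make_ann(c("A", "A", "B", "B"),
                                     c("1", "1", "2", "2"))),
               "confounded")
  expect_error(build_design(make_ann(rep("A", 4))), "two groups")
})

test_that("count filtering matches a direct evaluation of the rule", {
  withr::local_seed(5)
  counts <- matrix(rnbinom(20 * 6, mu = 30, size = 10), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("s%d", 1:6)))
  counts[1, ] <- 0                      # all-zero gene must go
  counts[2, ] <- 1000                   # uniformly high gene must stay
  counts[3, ] <- c(0, 1, 0, 1, 0, 1)    # sparse low gene
  groups <- c("A", "A", "B", "B", "B", "B")  # smallest group size 2
  ds <- expression_dataset(counts, make_ann(groups), scale = "raw_counts")

  keep <- filter_low_expression(ds, min_count = 10, min_total = 15)
  expect_false(keep[["g01"]])
  expect_true(keep[["g02"]])
  expect_equal(unname(keep),
               unname(oracle_filter_rule(counts, groups,
                                         min_count = 10, min_total = 15)))
})

test_that("TMM factors are unity for identical or depth-scaled columns", {
  m <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_equal(unname(tmm_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30, 40), b = 2 * c(10, 20, 30, 40))
  rownames(m2) <- paste0("g", 1:4)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))

  zero <- m; zero[, 2] <- 0
  expect_error(tmm_factors(zero), "zero total")
})

test_that("TMM matches the independent trimmed weighted M-mean oracle", {
  withr::local_seed(31)
  for (i in 1:5) {
    counts <- matrix(rnbinom(200 * 3, mu = 100, size = 5), nrow = 200,
                     dimnames = list(sprintf("g%03d", 1:200), c("a", "b", "c")))
    up <- sample(200, 20)
    counts[up, 3] <- counts[up, 3] * 8
    f <- tmm_factors(counts)
    expect_equal(unname(f), unname(oracle_tmm(counts)), tolerance = 1e-10)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  }
})

test_that("precision weights are positive and track the mean-variance trend", {
  withr::local_seed(17)
  counts <- matrix(rnbinom(300 * 8, mu = rep(2^runif(300, 2, 10), 8),
                           size = 10),
                   nrow = 300, dimnames = list(sprintf("g%03d", 1:300),
                                               sprintf("s%d", 1:8)))
  design <- build_design(make_ann(rep(c("A", "B"), each = 4)))
  v <- precision_weights(counts, design, tmm_factors(counts))

  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))

  # identical count rows sit at the same mean-variance position
  counts2 <- counts
  counts2[2, ] <- counts2[1, ]
  v2 <- precision_weights(counts2, design)
  expect_equal(v2$weights[1, ], v2$weights[2, ])

  # higher-mean genes get higher average weights (monotone trend direction)
  mw <- rowMeans(v$weights)
  mc <- rowMeans(counts)
  top <- mc >= stats::median(mc)
  expect_gt(mean(mw[top]), mean(mw[!top]))
})

test_that("a zero fold-change threshold reduces to the moderated t-test", {
  withr::local_seed(23)
  y <- matrix(rnorm(60 * 9, mean = 6), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%d", 1:9)))
  design <- build_design(make_ann(rep(c("A", "B", "C"), each = 3)))
  res <- fit_and_test(y, design, contrast = c("A", "B"), lfc_threshold = 0)

  fit <- limma::lmFit(y, design)
  cvec <- c(1, -1, 0)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cvec))
  expect_equal(res$p_value, as.numeric(eb$p.value), tolerance = 1e-12)
  expect_equal(res$logFC, as.numeric(eb$coefficients), tolerance = 1e-12)
  expect_true(all(res$adj_p_value >= res$p_value))
})

test_that("disabling moderation reproduces per-gene weighted t-tests", {
  withr::local_seed(29)
  sim <- generate_counts(n_groups = 3, n_per_group = 4, n_genes = 80,
                         n_markers_per_group = 5, lfc = 1.5, seed = 29)
  ds <- sim$dataset
  design <- build_design(ds$annotations)
  keep <- filter_low_expression(ds)
  v <- precision_weights(ds$values[keep, ], design,
                         tmm_factors(ds$values[keep, ]))

  res <- fit_and_test(v, design, contrast = c("G1", "G2"), prior_df = 0)
  cvec <- c(1, -1, 0)
  oracle <- oracle_weighted_t(v$E, design, v$weights, cvec)
  expect_equal(res$p_value, unname(oracle[, "p"]), tolerance = 1e-8)
  expect_equal(res$logFC, unname(oracle[, "logFC"]), tolerance = 1e-8)

  # and with a positive threshold the shifted-null tails combine the same way
  res_thr <- fit_and_test(v, design, contrast = c("G1", "G2"),
                          prior_df = 0, lfc_threshold = 1)
  oracle_thr <- oracle_weighted_t(v$E, design, v$weights, cvec, lfc = 1)
  expect_equal(res_thr$p_value, unname(oracle_thr[, "p"]), tolerance = 1e-8)
})

test_that("a gene with identical group means is null under any threshold", {
  withr::local_seed(3)
  y <- matrix(rnorm(40 * 6, mean = 5), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  # gene 1: equal group means (same values per position in both groups)
  y[1, ] <- c(4, 5, 6, 4, 5, 6)
  design <- build_design(make_ann(rep(c("A", "B"), each = 3)))
  res <- fit_and_test(y, design, contrast = c("A", "B"), lfc_threshold = 1)
  expect_equal(res$logFC[1], 0, tolerance = 1e-12)
  expect_gte(res$p_value[1], 0.5)
})

test_that("p-values ignore how non-contrast groups are labeled", {
  ds <- null_dataset(n_groups = 3, n_per_group = 4, n_genes = 120, seed = 8)
  de1 <- run_pairwise_de(ds, "G1")[["G1-G2"]]

  relabeled <- ds
  relabeled$annotations$Group[relabeled$annotations$Group == "G3"] <- "Z"
  de2 <- run_pairwise_de(relabeled, "G1")[["G1-G2"]]
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-12)
})

test_that("results are invariant to sample order", {
  ds <- null_dataset(n_groups = 3, n_per_group = 4, n_genes = 120, seed = 9)
  perm <- c(5, 1, 12, 3, 7, 2, 9, 11, 4, 10, 6, 8)
  shuffled <- expression_dataset(ds$values[, perm],
                                 ds$annotations[perm, , drop = FALSE],
                                 scale = "raw_counts")
  a <- run_pairwise_de(ds, "G2")
  b <- run_pairwise_de(shuffled, "G2")
  expect_equal(names(a), names(b))
  for (cmp in names(a)) {
    expect_equal(a[[cmp]]$p_value, b[[cmp]]$p_value, tolerance = 1e-10)
  }
})

test_that("one comparison is produced per non-target group", {
  sim <- generate_counts(n_groups = 4, n_per_group = 3, n_genes = 150,
                         n_markers_per_group = 10, lfc = 2, seed = 14)
  de <- run_pairwise_de(sim$dataset, "G2")
  expect_length(de, 3L)
  expect_setequal(names(de), c("G2-G1", "G2-G3", "G2-G4"))

  two <- generate_counts(n_groups = 2, n_per_group = 4, n_genes = 100,
                         n_markers_per_group = 5, lfc = 2, seed = 15)
  expect_length(run_pairwise_de(two$dataset, "G1"), 1L)

  expect_error(run_pairwise_de(sim$dataset, "NK"), "not present")
})

test_that("planted markers dominate the small adjusted p-values everywhere", {
  sim <- generate_counts(n_groups = 3, n_per_group = 6, n_genes = 400,
                         n_markers_per_group = 30, lfc = 2, seed = 21)
  de <- run_pairwise_de(sim$dataset, "G1")
  markers <- sim$truth$markers$G1
  for (cmp in names(de)) {
    res <- de[[cmp]]
    # both target-up and other-group-down genes carry small p-values;
    # restrict to the up-regulated side before taking the top block
    up <- res[res$logFC > 0, ]
    top <- up$gene[order(up$adj_p_value)][seq_along(markers)]
    expect_gte(mean(markers %in% top), 0.95)
  }
})

test_that("log-expression input takes the trend route end to end", {
  sim <- generate_counts(n_groups = 3, n_per_group = 4, n_genes = 200,
                         n_markers_per_group = 15, lfc = 2, seed = 33)
  logcpm <- edgeR::cpm(sim$dataset$values, log = TRUE, prior.count = 0.5)
  ds <- expression_dataset(logcpm, sim$dataset$annotations,
                           scale = "log_expression")
  de <- run_pairwise_de(ds, "G1", min_mean = 0.5, expr_floor = 0.5)
  expect_length(de, 2L)
  markers <- intersect(sim$truth$markers$G1, de[[1]]$gene)
  expect_gt(length(markers), 10)
  for (cmp in names(de)) {
    res <- de[[cmp]]
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    expect_gte(mean(res$adj_p_value[match(markers, res$gene)] < 0.05), 0.9)
  }
})
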