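fake_de <- function(genes, stats, comparison = "T-O") {
  res <- data.frame(gene = genes, logFC = stats$logFC %||% 1,
                    t = 0, p_value = stats$p %||% 0.5,
                    adj_p_value = stats$p %||% 0.5,
                    mean_expression = 5, stringsAsFactors = FALSE)
  attr(res, "comparison") <- comparison
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ranking follows the statistic, with |logFC| descending", {
  genes <- c("a", "b", "c")
  de <- list(cmp1 = fake_de(genes, list(p = c(0.01, 0.2, 0.05))))
  expect_equal(unname(rank_genes(de, "p_value")[, 1]), c(1, 3, 2))

  de_lfc <- list(cmp1 = fake_de(genes, list(logFC = c(2, -3, 1))))
  expect_equal(unname(rank_genes(de_lfc, "logFC")[, 1]), c(2, 1, 3))

  de_tie <- list(cmp1 = fake_de(genes, list(p = c(0.01, 0.01, 0.5))))
  expect_equal(unname(rank_genes(de_tie, "p_value")[, 1]), c(1.5, 1.5, 3))
})

test_that("ranks are taken on the intersection of result tables", {
  de <- list(
    c1 = fake_de(c("a", "b", "c"), list(p = c(0.1, 0.2, 0.3))),
    c2 = fake_de(c("b", "c", "d"), list(p = c(0.05, 0.5, 0.01))))
  r <- rank_genes(de, "p_value")
  expect_setequal(rownames(r), c("b", "c"))

  disjoint <- list(
    c1 = fake_de("a", list(p = 0.1)),
    c2 = fake_de("b", list(p = 0.1)))
  expect_error(rank_genes(disjoint), "common")
})

test_that("the rank product is the sum of natural-log ranks", {
  r <- matrix(c(1, 2, 1, 3), nrow = 2,
              dimnames = list(c("a", "b"), c("c1", "c2")))
  rp <- compute_rp(r)
  expect_equal(unname(rp["a"]), 0)            # rank 1 everywhere
  expect_equal(unname(rp["b"]), log(6))       # ln 2 + ln 3

  single <- matrix(c(3, 1), ncol = 1, dimnames = list(c("a", "b"), "c1"))
  expect_equal(unname(compute_rp(single)), c(log(3), 0))
})

test_that("exhaustive scores on the 2x2 instance are 0 and 0.75", {
  r <- matrix(c(1, 2, 1, 2), nrow = 2,
              dimnames = list(c("A", "B"), c("c1", "c2")))
  res <- permutation_score(r, exhaustive = TRUE)
  expect_equal(res$score[res$gene == "A"], 0)
  expect_equal(res$score[res$gene == "B"], 0.75)
})

test_that("exhaustive scores match the enumeration oracle on small instances", {
  withr::local_seed(41)
  for (G in 2:4) {
    for (C in 1:3) {
      ranks <- vapply(seq_len(C), function(j) sample(G), numeric(G))
      rownames(ranks) <- paste0("g", seq_len(G))
      res <- permutation_score(ranks, exhaustive = TRUE)
      oracle <- oracle_exhaustive_scores(ranks)
      expect_equal(setNames(res$score, res$gene), oracle, info = paste(G, C))
    }
  }
})

test_that("single-comparison exhaustive score of rank r is (r-1)/G", {
  G <- 5
  ranks <- matrix(seq_len(G), ncol = 1,
                  dimnames = list(paste0("g", 1:G), "c1"))
  res <- permutation_score(ranks, exhaustive = TRUE)
  expect_equal(res$score, (seq_len(G) - 1) / G)
})

test_that("sampled scores are deterministic in the seed and honor rank 1", {
  withr::local_seed(2)
  ranks <- vapply(1:3, function(j) sample(30), numeric(30))
  rownames(ranks) <- paste0("g", 1:30)
  ranks[7, ] <- 0.5  # displace then rebuild so gene 7 is rank 1 everywhere
  ranks <- apply(ranks, 2, rank)
  rownames(ranks) <- paste0("g", 1:30)

  a <- permutation_score(ranks, K = 200, seed = 99)
  b <- permutation_score(ranks, K = 200, seed = 99)
  expect_identical(a$score, b$score)
  expect_equal(a$score[7], 0)

  c <- permutation_score(ranks, K = 200, seed = 100)
  expect_false(identical(a$score, c$score))
})

test_that("null scores are uniform and monotone in the rank product", {
  withr::local_seed(12)
  G <- 500
  ranks <- vapply(1:3, function(j) sample(G), numeric(G))
  rownames(ranks) <- sprintf("g%03d", 1:G)
  res <- permutation_score(ranks, K = 1000, seed = 5)

  ks <- suppressWarnings(stats::ks.test(res$score, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
  expect_gte(mean(res$score < 0.05), 0.03)
  expect_lte(mean(res$score < 0.05), 0.07)

  # monotone calibration: sampled scores track the rank-product ordering
  expect_gt(stats::cor(res$rank_product, res$score, method = "spearman"),
            0.99)

  # and under exhaustive enumeration (shared exact null) it is exact
  small <- vapply(1:2, function(j) sample(4), numeric(4))
  rownames(small) <- paste0("g", 1:4)
  ex <- permutation_score(small, exhaustive = TRUE)
  ord <- order(ex$rank_product)
  expect_true(all(diff(ex$score[ord]) >= 0))
})

test_that("the smoothed estimator avoids exact zeros", {
  r <- matrix(c(1, 2, 1, 2), nrow = 2,
              dimnames = list(c("A", "B"), c("c1", "c2")))
  res <- permutation_score(r, K = 50, seed = 1, smooth = TRUE)
  expect_true(all(res$score > 0))
})

test_that("selection applies the score threshold with keep_top rescue", {
  ranks <- matrix(c(1, 2, 3, 2, 3, 1), nrow = 3,
                  dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  rp <- permutation_score(ranks, K = 100, seed = 4)
  rp$score <- c(0.01, 0.20, 0.30)  # fix scores for the contract check

  sig <- select_genes(rp, score_threshold = 0.05)
  expect_equal(sig$gene, "A")
  expect_equal(sig$selected_by, "rp")

  # gene C is rank 1 in comparison c2 but scores 0.30: rescued by keep_top
  sig2 <- select_genes(rp, score_threshold = 0.05,
                       keep_top = 1, keep_group = "c2")
  expect_setequal(sig2$gene, c("A", "C"))
  expect_equal(sig2$selected_by[sig2$gene == "C"], "keep_top")

  all_in <- select_genes(rp, score_threshold = 1.0)
  expect_setequal(all_in$gene, c("A", "B", "C"))

  expect_error(select_genes(rp, keep_top = 1, keep_group = "nope"),
               "unknown comparison")
  expect_error(select_genes(rp, keep_top = 1), "keep_group")
})
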