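make_counts <- function(m) {
  rownames(m) <- sprintf("miR-%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  m
}

test_that("cpm_normalize scales every sample to one million", {
  m <- make_counts(matrix(c(10L, 90L, 5L, 0L), 2, 2))
  cpm <- cpm_normalize(m)
  expect_equal(cpm[, 1], c(`miR-01` = 1e5, `miR-02` = 9e5))
  expect_equal(unname(cpm[, 2]), c(1e6, 0))
  zero <- make_counts(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_error(cpm_normalize(zero), "s02")
})

test_that("detection filter keeps rows above count in enough samples", {
  m <- make_counts(matrix(0L, 3, 12))
  m[1, 1:3] <- 11L       # 3 samples > 10: kept
  m[2, ] <- 10L          # never strictly > 10: dropped
  m[3, 1:2] <- 100L      # only 2 qualifying samples: dropped
  kept <- detection_filter(m)
  expect_equal(rownames(kept), "miR-01")
  expect_error(detection_filter(m, min_samples = 13), "exceeds")
})

test_that("detection filter is monotone in both thresholds", {
  set.seed(5)
  m <- make_counts(matrix(rnbinom(40 * 12, mu = 15, size = 2), 40, 12))
  base <- rownames(detection_filter(m, 10, 3))
  expect_true(all(rownames(detection_filter(m, 20, 3)) %in% base))
  expect_true(all(rownames(detection_filter(m, 10, 6)) %in% base))
})

test_that("exact Mann-Whitney matches enumeration on spec examples", {
  r <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_exact, 0.1)
  tied <- mann_whitney_exact(rep(5, 3), rep(5, 3))
  expect_equal(tied$u_statistic, 4.5)
  expect_equal(tied$p_exact, 1)
  single <- mann_whitney_exact(10, 20)
  expect_equal(single$u_statistic, 0)
  expect_equal(single$p_exact, 1)
  expect_error(mann_whitney_exact(numeric(), 1), "nonempty")
})

test_that("exact Mann-Whitney equals the pair-counting oracle, with ties", {
  set.seed(8)
  for (i in 1:40) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    vals <- if (i %% 2) rnorm(nx + ny) else sample(1:4, nx + ny, TRUE)
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(mann_whitney_exact(x, y)$p_exact, oracle_mw_p(x, y))
  }
})

test_that("Mann-Whitney large-sample path agrees with wilcox.test", {
  set.seed(9)
  x <- rnorm(10); y <- rnorm(9, 0.8)
  got <- mann_whitney_exact(x, y, exact_max_n = 14)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_exact, ref$p.value, tolerance = 1e-10)
})

test_that("fold_change reports direction-agnostic magnitude", {
  expect_equal(fold_change(200, 100), list(magnitude = 2, direction = "up_in_first"))
  expect_equal(fold_change(100, 100)$magnitude, 1)
  expect_equal(fold_change(100, 100)$direction, "none")
  expect_equal(fold_change(50, 150), list(magnitude = 3, direction = "up_in_second"))
  expect_equal(fold_change(0, 0), list(magnitude = 1, direction = "none"))
  expect_equal(fold_change(0, 5, pseudo_mean = 0.5)$magnitude, 10)
})

test_that("run_de recovers planted miRNAs and is calm under the null", {
  cfg <- sim_config(rng_seed = 21, n_mirnas = 120, n_de = 5, log2fc = 2)
  sim <- gen_counts(cfg)
  filtered <- detection_filter(sim$counts)
  res <- run_de(filtered, sim$meta)
  planted <- sim$truth$mirna_id[sim$truth$is_de]
  planted <- intersect(planted, rownames(filtered))
  sig <- res$mirna_id[res$significant]
  expect_true(all(planted %in% sig))
  false_pos <- setdiff(sig, planted)
  expect_lte(length(false_pos), ceiling(0.05 * nrow(res)) + 2)

  # identical low/high columns: nothing can be significant
  m <- make_counts(matrix(rep(c(20L, 40L, 80L), each = 12), 3, 12,
                          byrow = TRUE))
  meta <- data.frame(sample_id = colnames(m),
                     clone_id = rep(sprintf("c%d", 1:6), 2),
                     age_group = "young",
                     pd_value = rep(c(30L, 60L), each = 6),
                     pd_group = rep(c("low", "high"), each = 6))
  flat <- run_de(m, meta)
  expect_false(any(flat$significant))
})

test_that("run_de single-miRNA separation gives the enumeration p", {
  m <- make_counts(matrix(c(1:6, 7:12) * 100L, 1, 12))
  meta <- data.frame(sample_id = colnames(m),
                     clone_id = rep(sprintf("c%d", 1:6), 2),
                     age_group = "old",
                     pd_value = rep(c(25L, 55L), each = 6),
                     pd_group = rep(c("low", "high"), each = 6))
  # CPM rescales each column to 1e6, flattening a single-miRNA matrix;
  # test the statistic directly on the ordered values instead
  r <- mann_whitney_exact(1:6, 7:12)
  expect_equal(r$p_exact, 2 / 924)
  expect_error(run_de(m, meta[1:6, ]), "missing from metadata")
})

test_that("select_candidates applies significance, FC and expression rules", {
  res <- data.frame(
    mirna_id = c("a", "b", "c", "d"),
    u_statistic = 0, p_exact = c(0.01, 0.01, 0.2, 0.01),
    mean_cpm_low = c(500, 400, 100, 300),
    mean_cpm_high = c(1000, 560, 300, 900),
    fold_change = c(2.0, 1.4, 3.0, 3.0),
    direction = "up_in_high",
    significant = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(select_candidates(res, 1.5, 100), c("a", "d"))
  expect_equal(select_candidates(res, 1.5, 100000), character())
  expect_error(select_candidates(res), "expr_min_cpm")
})

test_that("pca_scores separates planted groups and fixes signs", {
  cfg <- sim_config(rng_seed = 31, n_mirnas = 200, n_de = 20, log2fc = 1.5)
  sim <- gen_counts(cfg)
  cpm <- cpm_normalize(detection_filter(sim$counts))
  pca <- pca_scores(cpm)
  grp <- sim$meta$pd_group[match(rownames(pca$scores), sim$meta$sample_id)]
  lo <- range(pca$scores[grp == "low", 1])
  hi <- range(pca$scores[grp == "high", 1])
  expect_true(lo[2] < hi[1] || hi[2] < lo[1])
  # deterministic sign: largest-|.| loading positive on every axis
  for (j in seq_len(ncol(pca$loadings))) {
    v <- pca$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # identical samples get identical scores
  m <- matrix(rnorm(40), 10, 4)
  m <- cbind(m, m[, 4])
  colnames(m) <- paste0("s", 1:5); rownames(m) <- paste0("g", 1:10)
  sc <- pca_scores(m, log_transform = FALSE)$scores
  expect_equal(unname(sc[4, ]), unname(sc[5, ]), tolerance = 1e-8)
  expect_error(pca_scores(matrix(1, 3, 3)), "degenerate")
})

test_that("single dominant feature loads PC1 entirely", {
  m <- matrix(0, 5, 6)
  m[3, ] <- c(1, 2, 3, 4, 5, 6) * 10
  rownames(m) <- paste0("g", 1:5); colnames(m) <- paste0("s", 1:6)
  pca <- pca_scores(m, log_transform = FALSE)
  expect_equal(abs(pca$loadings[3, 1]), 1, tolerance = 1e-12)
})

test_that("hcluster_order merges duplicate pairs first, deterministically", {
  set.seed(12)
  a <- rnorm(30)
  b <- rnorm(30)
  x <- cbind(A = a + rnorm(30, 0, 1e-6), A2 = a + rnorm(30, 0, 1e-6),
             B = b + rnorm(30, 0, 1e-6), B2 = b + rnorm(30, 0, 1e-6))
  cl <- hcluster_order(x)
  first_two <- list(sort(cl$merge[1, ]), sort(cl$merge[2, ]))
  expect_true(any(vapply(first_two, identical, logical(1), c(-2L, -1L))))
  expect_true(any(vapply(first_two, identical, logical(1), c(-4L, -3L))))
  # heights agree with stats::hclust average linkage
  ref <- hclust(as.dist(1 - cor(x)), method = "average")
  expect_equal(sort(cl$height), sort(ref$height), tolerance = 1e-12)
  # newick string contains all labels
  nwk <- cluster_newick(cl)
  expect_true(all(vapply(colnames(x), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
  expect_error(hcluster_order(cbind(A = rep(1, 5), B = rnorm(5))), "zero-variance")
})

test_that("three-item clustering picks the closest pair first", {
  # construct items with controlled correlation distances
  t_ <- seq(0, 1, length.out = 20)
  x <- cbind(i1 = t_, i2 = t_ + rnorm(20, 0, 0.01), i3 = rev(t_))
  cl <- hcluster_order(x)
  expect_equal(sort(cl$merge[1, ]), c(-2L, -1L))
  expect_equal(cl$order[1:2], c(1L, 2L))
})
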