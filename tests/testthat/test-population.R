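make_feature_df <- function(mat, groups = rep("g", nrow(mat))) {
  df <- as.data.frame(mat)
  names(df) <- c("frequency_hz", "frequency_mode_hz", "cv", "cv2",
                 "pause_percent", "rhythmicity_index")[seq_len(ncol(mat))]
  df$cell_id <- sprintf("c%03d", seq_len(nrow(mat)))
  df$group_label <- groups
  df
}

test_that("population assembly z-scores each feature across cells", {
  set.seed(5)
  df <- make_feature_df(matrix(rnorm(60, mean = 10, sd = 3), 10, 6))
  pop <- assemble_population(df)
  expect_equal(unname(colMeans(pop$z)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(pop$z, 2, sd)), rep(1, 6), tolerance = 1e-9)
  # two cells: symmetric +/- 1/sqrt(2) about zero
  df2 <- make_feature_df(matrix(rep(c(1, 3), each = 1, times = 6), 2, 6))
  z2 <- assemble_population(df2)$z
  expect_equal(unname(z2[1, ]), rep(-sqrt(0.5), 6))
  expect_equal(unname(z2[2, ]), rep(sqrt(0.5), 6))
  # z-scoring idempotence
  dfz <- df; dfz[1:6] <- as.data.frame(pop$z)
  expect_equal(assemble_population(dfz)$z, pop$z, tolerance = 1e-9)
  # constant column: zeroed with a warning
  dfc <- df; dfc$cv <- 1
  expect_warning(popc <- assemble_population(dfc), "constant")
  expect_true(all(popc$z[, "cv"] == 0))
  expect_error(assemble_population(df[1, ]),
               class = "purkinjetrain_validation_error")
  # shape contract at the population scale used in the full analysis
  big <- make_feature_df(matrix(rnorm(149 * 6), 149, 6))
  expect_equal(dim(assemble_population(big)$z), c(149L, 6L))
})

test_that("clusterogram separates distinct phenotypes and is order-invariant", {
  young <- cohort_features("young_control", 20, seed = 101)
  old <- cohort_features("old_control", 20, seed = 102)
  df <- rbind(young, old)
  pop <- assemble_population(df)
  cg <- clusterogram(pop)
  cut2 <- cutree(cg$hclust, k = 2)
  expect_gte(adjusted_rand_index(cut2, df$group_label), 0.9)

  # permuting the input rows leaves the 2-cluster partition invariant
  set.seed(9)
  perm <- sample(nrow(df))
  pop_p <- assemble_population(df[perm, ])
  cut2_p <- cutree(clusterogram(pop_p)$hclust, k = 2)
  expect_equal(adjusted_rand_index(cut2_p[order(perm)], cut2), 1)

  # duplicated cells merge at height zero
  dup <- make_feature_df(matrix(rnorm(36), 6, 6))
  dup[2, 1:6] <- dup[1, 1:6]
  hc <- clusterogram(assemble_population(dup))$hclust
  expect_equal(min(hc$height), 0)
  # 2 identical cells: every column is constant (warned) and the tree is
  # flagged degenerate
  pop2 <- suppressWarnings(assemble_population(dup[1:2, ]))
  expect_warning(clusterogram(pop2), "degenerate")
})

test_that("tSNE embedding is seeded, validated and separates phenotypes", {
  young <- cohort_features("young_control", 20, seed = 101)
  old <- cohort_features("old_control", 20, seed = 102)
  pop <- assemble_population(rbind(young, old))
  e1 <- tsne_pseudotimeline(pop, perplexity = 10, seed = 42)
  e2 <- tsne_pseudotimeline(pop, perplexity = 10, seed = 42)
  expect_identical(e1$coordinates, e2$coordinates)  # bitwise determinism
  expect_equal(e1$seed, 42L)
  expect_error(tsne_pseudotimeline(pop, perplexity = 40, seed = 1),
               class = "purkinjetrain_validation_error")
  # inter-group versus intra-group distances in the embedding
  ratios <- vapply(1:5, function(s) {
    em <- tsne_pseudotimeline(pop, perplexity = 10, seed = s)$coordinates
    d <- as.matrix(dist(em))
    same <- outer(pop$group_labels, pop$group_labels, "==")
    diag(same) <- NA
    mean(d[!same & !is.na(same)]) / mean(d[same & !is.na(same)])
  }, 0)
  expect_gt(median(ratios), 1.5)
})

test_that("group linkage clusters group means in PCA space", {
  set.seed(13)
  centers <- rbind(young1 = c(50, 55, 0.7, 0.7, 0.01, 0),
                   young2 = c(55, 60, 0.8, 0.7, 0.02, 0),
                   old1 = c(110, 150, 4.0, 0.35, 0.28, 0.1),
                   old2 = c(105, 145, 4.3, 0.33, 0.30, 0.1),
                   mut1 = c(52, 57, 0.75, 0.72, 0.015, 0),
                   mut2 = c(53, 58, 0.72, 0.71, 0.012, 0))
  df <- make_feature_df(centers, groups = rownames(centers))
  gl <- group_linkage(df)
  expect_equal(length(gl$hclust$order), 6L)  # one leaf per group
  cut2 <- cutree(gl$hclust, k = 2)
  expect_equal(cut2[["mut1"]], cut2[["young1"]])
  expect_equal(cut2[["mut2"]], cut2[["young2"]])
  expect_false(cut2[["mut1"]] == cut2[["old1"]])
  # identical group means merge first
  dfi <- df; dfi[2, 1:6] <- dfi[1, 1:6]
  hci <- group_linkage(dfi)$hclust
  expect_equal(hci$merge[1, ], c(-1L, -2L))
  expect_equal(hci$height[1], 0)
  expect_error(group_linkage(df[1:2, ]),
               class = "purkinjetrain_validation_error")
})

test_that("compare_groups runs ANOVA + Tukey-Kramer with small-group handling", {
  set.seed(3)
  df <- data.frame(group_label = rep(c("a", "b", "c"), each = 10),
                   cv = c(rnorm(10, 1), rnorm(10, 1), rnorm(10, 4)))
  cmp <- compare_groups(df, "cv")
  expect_lt(cmp$p, 0.001)
  expect_equal(nrow(cmp$tukey), 3L)  # all pairs
  expect_true(all(cmp$tukey$p_adj[grepl("c", cmp$tukey$comparison)] < 0.01))
  # identical data in every group: F ~ 0, all pairwise p ~ 1
  dfe <- data.frame(group_label = rep(c("a", "b"), each = 6), cv = rep(1:6, 2))
  cmpe <- compare_groups(dfe, "cv")
  expect_lt(cmpe$f, 1e-20)
  expect_gt(min(cmpe$tukey$p_adj), 0.999)
  # a singleton group is excluded with a warning
  dfs <- rbind(df, data.frame(group_label = "d", cv = 1))
  expect_warning(cmps <- compare_groups(dfs, "cv"), "excluding")
  expect_equal(sort(cmps$groups_used), c("a", "b", "c"))
  expect_error(compare_groups(df, "nope"),
               class = "purkinjetrain_validation_error")
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(1)
  a <- sample(1:3, 3000, TRUE); b <- sample(1:3, 3000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})
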