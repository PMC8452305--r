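## Population-level analysis: z-scored clusterogram over cells, tSNE
## pseudo-timeline, PCA + linkage over group means, and per-feature
## one-way ANOVA with Tukey-Kramer post-hoc comparisons.

CLUSTER_FEATURES <- c("frequency_hz", "frequency_mode_hz", "cv", "cv2",
                      "pause_percent", "rhythmicity_index")

#' Assemble the cells-by-features population matrix
#'
#' Collects the six simple-spike firing statistics for every cell and
#' z-scores each feature across cells. Complex-spike/doublet frequencies
#' and the heterogeneity flag are deliberately excluded from the
#' clustering inputs. A feature that is constant across cells has no
#' z-score; its column is set to 0 with a warning.
#'
#' @param features A feature table: one row per cell with at least
#'   `cell_id`, `group_label` and the six feature columns (e.g. rbind-ed
#'   [extract_features()] rows or [read_feature_table()] output).
#' @return An object of class `population_matrix`: `cell_ids`,
#'   `group_labels`, `features` (cells x 6 matrix), `z` (z-scored matrix).
#' @export
assemble_population <- function(features) {
  if (nrow(features) < 2L)
    stop_validation("at least 2 cells are required for population analysis")
  missing_cols <- setdiff(c("cell_id", "group_label", CLUSTER_FEATURES),
                          names(features))
  if (length(missing_cols))
    stop_validation(paste0("feature table is missing columns: ",
                           paste(missing_cols, collapse = ", ")))
  m <- as.matrix(features[CLUSTER_FEATURES])
  if (anyNA(m)) stop_validation("feature matrix contains missing values")
  z <- m
  for (j in seq_len(ncol(m))) {
    s <- stats::sd(m[, j])
    if (s < .Machine$double.eps) {
      warning("feature '", CLUSTER_FEATURES[j],
              "' is constant across cells; z-scores set to 0")
      z[, j] <- 0
    } else {
      z[, j] <- (m[, j] - mean(m[, j])) / s
    }
  }
  rownames(m) <- rownames(z) <- features$cell_id
  structure(list(cell_ids = features$cell_id,
                 group_labels = features$group_label,
                 features = m, z = z),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat("<population_matrix>", nrow(x$z), "cells x", ncol(x$z), "features;",
      length(unique(x$group_labels)), "groups\n")
  invisible(x)
}

#' Hierarchical clusterogram over cells
#'
#' Clusters cells on their z-scored firing features (cells are
#' de-identified during clustering; group labels are only re-attached to
#' the returned leaf order afterwards) and returns the tree together with
#' the heat-matrix reordered by the dendrogram.
#'
#' @param pop A [assemble_population()] result.
#' @param linkage_method Agglomeration method for [stats::hclust()]
#'   (default "average").
#' @param distance Distance measure for [stats::dist()] (default
#'   "euclidean").
#' @return An object of class `clusterogram`: `hclust` (the tree),
#'   `order` (leaf order), `matrix` (z-scored matrix in leaf order),
#'   `leaf_groups` (group labels in leaf order).
#' @export
clusterogram <- function(pop, linkage_method = "average",
                         distance = "euclidean") {
  if (nrow(pop$z) < 3L)
    warning("fewer than 3 cells: the dendrogram is degenerate")
  hc <- stats::hclust(stats::dist(pop$z, method = distance),
                      method = linkage_method)
  structure(list(hclust = hc, order = hc$order,
                 matrix = pop$z[hc$order, , drop = FALSE],
                 leaf_groups = pop$group_labels[hc$order],
                 linkage_method = linkage_method, distance = distance),
            class = "clusterogram")
}

#' Write a dendrogram in Newick format
#'
#' @param tree A `clusterogram`, `group_linkage` result, or bare `hclust`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  hc <- if (inherits(tree, "hclust")) tree else tree$hclust
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' tSNE pseudo-timeline embedding
#'
#' Embeds the z-scored firing features in two dimensions with exact t-SNE
#' on Euclidean distances. The arrangement of cells along the embedding
#' recapitulates the developmental progression of firing phenotypes, hence
#' "pseudo-timeline". The seed is mandatory and recorded: identical seed
#' and inputs give bitwise-identical coordinates.
#'
#' @param pop A [assemble_population()] result.
#' @param perplexity t-SNE perplexity (default 30; must be < number of
#'   cells).
#' @param seed Integer RNG seed for the embedding initialization.
#' @param max_iter Gradient-descent iterations (default 500).
#' @return An object of class `embedding_result`: `coordinates`
#'   (cells x 2, columns `tSNE1`, `tSNE2`), `seed`, `perplexity`,
#'   `group_labels`.
#' @export
tsne_pseudotimeline <- function(pop, perplexity = 30, seed = 1L,
                                max_iter = 500L) {
  n <- nrow(pop$z)
  if (perplexity >= n)
    stop_validation(sprintf("perplexity (%g) must be smaller than the number of cells (%d)",
                            perplexity, n))
  Y <- with_seed(seed, tsne_exact(pop$z, perplexity = perplexity,
                                  max_iter = max_iter))
  colnames(Y) <- c("tSNE1", "tSNE2")
  rownames(Y) <- pop$cell_ids
  structure(list(coordinates = Y, seed = as.integer(seed),
                 perplexity = perplexity,
                 group_labels = pop$group_labels),
            class = "embedding_result")
}

#' Group-mean PCA and hierarchical linkage
#'
#' Averages the six firing features within each (age x genotype) group,
#' z-scores the group-mean table across groups (correlation-scaled PCA;
#' set `scale = FALSE` for covariance PCA), takes the first two principal
#' components, and hierarchically clusters the groups in that 2-D score
#' space.
#'
#' @param pop A [assemble_population()] result (or a data.frame of group
#'   means with a `group_label` column and the six feature columns).
#' @param linkage_method Agglomeration method (default "average").
#' @param scale Use z-scored features for the PCA (default `TRUE`).
#' @return An object of class `group_linkage`: `hclust` (tree over
#'   groups), `pca_scores` (groups x 2), `group_means` (raw means),
#'   `sdev` (PCA standard deviations).
#' @export
group_linkage <- function(pop, linkage_method = "average", scale = TRUE) {
  if (inherits(pop, "population_matrix")) {
    groups <- pop$group_labels
    mts <- stats::aggregate(pop$features, by = list(group_label = groups),
                            FUN = mean)
  } else {
    mts <- as.data.frame(pop)
    if (!"group_label" %in% names(mts))
      stop_validation("group-mean table must contain a group_label column")
    mts <- mts[c("group_label", intersect(CLUSTER_FEATURES, names(mts)))]
  }
  if (nrow(mts) < 3L)
    stop_validation("at least 3 groups are required for group linkage")
  m <- as.matrix(mts[, -1, drop = FALSE])
  rownames(m) <- mts$group_label
  ms <- m
  if (scale) {
    # z-score across groups, guarding features whose group means are
    # constant (no variance to rescale; they carry no information here)
    for (j in seq_len(ncol(ms))) {
      s <- stats::sd(ms[, j])
      ms[, j] <- if (s < .Machine$double.eps) 0 else (ms[, j] - mean(ms[, j])) / s
    }
  }
  pc <- stats::prcomp(ms, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  hc <- stats::hclust(stats::dist(scores), method = linkage_method)
  structure(list(hclust = hc, pca_scores = scores, group_means = m,
                 sdev = pc$sdev, linkage_method = linkage_method),
            class = "group_linkage")
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' Tests one firing feature across groups. [stats::TukeyHSD()] implements
#' the Tukey-Kramer procedure, which supports unequal group sizes. Groups
#' with fewer than 2 cells are excluded with a warning.
#'
#' @param features A feature table (one row per cell) with `group_label`
#'   and the feature column.
#' @param feature_name Name of the feature column to test.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return An object of class `group_comparison`: `feature`, `f`
#'   (ANOVA F), `p` (ANOVA p-value), `tukey` (data.frame with `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`), `alpha`, `groups_used`.
#' @export
compare_groups <- function(features, feature_name, alpha = 0.05) {
  if (!feature_name %in% names(features))
    stop_validation(paste0("no such feature column: ", feature_name))
  g <- as.character(features$group_label)
  y <- features[[feature_name]]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding groups with < 2 cells: ", paste(small, collapse = ", "))
    keep <- !(g %in% small)
    g <- g[keep]; y <- y[keep]
  }
  if (length(unique(g)) < 2L)
    stop_validation("at least 2 groups with >= 2 cells are required")
  d <- data.frame(y = y, g = factor(g))
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  structure(list(feature = feature_name,
                 f = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                    row.names = NULL),
                 alpha = alpha, groups_used = levels(d$g)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F = %.3f, p = %.3g (%d groups)\n",
              x$feature, x$f, x$p, length(x$groups_used)))
  sig <- x$tukey[x$tukey$p_adj < x$alpha, , drop = FALSE]
  cat("  Tukey-Kramer pairs below alpha:", nrow(sig), "of", nrow(x$tukey), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels (same length).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_validation("partitions differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
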