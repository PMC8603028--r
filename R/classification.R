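#' Keep the genotypes with the least missing trait data
#'
#' Genotypes are ranked by their count of complete-case samples (ties by
#' total sample count, then name) and the top `n_keep` are retained.
#'
#' @param table Data frame with a genotype column and trait columns.
#' @param n_keep Number of genotypes to keep.
#' @param traits Trait columns; default all numeric non-metadata columns.
#' @param genotype Genotype column name.
#' @return Filtered table (genotype factor levels dropped).
#' @export
filter_genotypes <- function(table, n_keep, traits = NULL,
                             genotype = "genotype") {
  traits <- numeric_trait_cols(table, traits)
  cc <- stats::complete.cases(table[, traits, drop = FALSE])
  g <- factor(table[[genotype]])
  score <- tapply(cc, g, sum)
  total <- tapply(rep(1L, nrow(table)), g, sum)
  ord <- order(-score, -total, names(score))
  keep <- names(score)[ord][seq_len(min(n_keep, length(score)))]
  out <- table[g %in% keep, , drop = FALSE]
  out[[genotype]] <- droplevels(factor(out[[genotype]]))
  out
}

# PCA + LDA with leave-one-out CV on one genotype subset.
pca_lda_once <- function(x, grouping, variance_target) {
  x <- scale(x)
  x <- x[, apply(x, 2L, function(c) all(is.finite(c))), drop = FALSE]
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= variance_target)[1L]
  k <- max(2L, min(k, nrow(x) - 2L))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  cv <- MASS::lda(scores, grouping = grouping, CV = TRUE)
  acc <- mean(cv$class == grouping)
  fit <- MASS::lda(scores, grouping = grouping)
  imp <- rowSums(abs(pc$rotation[, seq_len(k), drop = FALSE]) %*%
                   abs(fit$scaling))
  list(accuracy = acc, n_components = k, importance = imp)
}

#' PCA-LDA genotype classification over all k-genotype combinations
#'
#' For every combination of `group_size` genotypes: traits are
#' standardized, projected on the minimal number of principal components
#' reaching `variance_target` cumulative variance, and classified by
#' linear discriminant analysis with leave-one-out cross-validation.
#' Per-trait importance is aggregated as |PC loading| x |discriminant
#' weight| summed over retained components and averaged over
#' combinations. Deterministic given the table.
#'
#' @param table Data frame with genotype and trait columns.
#' @param traits Trait columns; default all numeric non-metadata columns.
#' @param genotype Genotype column name.
#' @param group_size Genotypes per combination; default 3.
#' @param variance_target Cumulative variance for PC retention; default 0.90.
#' @param max_genotypes If set, [filter_genotypes()] is applied first.
#' @return List: `per_combination` (data frame: combination, accuracy,
#'   n_components), `mean_accuracy`, `n_combinations`, `importance`
#'   (named, averaged), `median_components`.
#' @export
pca_lda_combinations <- function(table, traits = NULL, genotype = "genotype",
                                 group_size = 3L, variance_target = 0.90,
                                 max_genotypes = NULL) {
  if (!is.null(max_genotypes))
    table <- filter_genotypes(table, max_genotypes, traits, genotype)
  traits <- numeric_trait_cols(table, traits)
  cc <- stats::complete.cases(table[, traits, drop = FALSE])
  table <- table[cc, , drop = FALSE]
  g <- droplevels(factor(table[[genotype]]))
  counts <- table(g)
  usable <- names(counts)[counts >= 2L]
  if (length(usable) < group_size)
    stop("need at least ", group_size, " genotypes with >= 2 samples")
  combos <- utils::combn(sort(usable), group_size, simplify = FALSE)
  imp_sum <- stats::setNames(numeric(length(traits)), traits)
  rows <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    sel <- g %in% combos[[i]]
    x <- as.matrix(table[sel, traits, drop = FALSE])
    r <- pca_lda_once(x, droplevels(g[sel]), variance_target)
    rows[[i]] <- data.frame(combination = paste(combos[[i]], collapse = "+"),
                            accuracy = r$accuracy,
                            n_components = r$n_components)
    imp_sum[names(r$importance)] <- imp_sum[names(r$importance)] + r$importance
  }
  per <- do.call(rbind, rows)
  list(per_combination = per,
       mean_accuracy = mean(per$accuracy),
       n_combinations = nrow(per),
       median_components = stats::median(per$n_components),
       importance = sort(imp_sum / length(combos), decreasing = TRUE))
}

#' Number of k-genotype combinations
#'
#' @param n_genotypes Number of genotypes after filtering.
#' @param group_size Genotypes per subset; default 3.
#' @return `choose(n_genotypes, group_size)`.
#' @export
genotype_combination_count <- function(n_genotypes, group_size = 3L) {
  choose(n_genotypes, group_size)
}

# Repeated k-fold CV accuracy of a random forest at one (mtry, ntree).
rf_cv_accuracy <- function(x, y, mtry, ntree, folds_list) {
  accs <- vapply(folds_list, function(folds) {
    correct <- 0L
    for (k in seq_len(max(folds))) {
      test <- folds == k
      fit <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                        mtry = mtry, ntree = ntree)
      pred <- stats::predict(fit, x[test, , drop = FALSE])
      correct <- correct + sum(pred == y[test])
    }
    correct / length(y)
  }, 0)
  mean(accs)
}

#' Random-forest classification of a binary label with grid search
#'
#' Grid search over `mtry` and `ntree` scored by repeated k-fold
#' cross-validation; the best model is refit on all data with proximity
#' and both permutation and Gini importance, and the proximity matrix is
#' embedded in 2D by nonmetric multidimensional scaling of 1 - proximity.
#' `mtry` values above the feature count are skipped.
#'
#' @param table Data frame with the label column and traits.
#' @param label Column with exactly 2 classes, each with >= 10 samples.
#' @param traits Trait columns; default all numeric non-metadata columns.
#' @param mtry_grid,ntree_grid Search grids; defaults `1:20` and
#'   `c(500, 1000, 2500, 5000)`.
#' @param k_folds,repeats Cross-validation design; defaults 10-fold x 3.
#' @param seed RNG seed controlling folds and forests.
#' @return List: `best` (mtry, ntree), `cv_accuracy`, `grid` (all scored
#'   combinations), `importance` (permutation), `importance_gini`,
#'   `proximity`, `nmds` (`points`, `stress`), `model`.
#' @export
random_forest_binary <- function(table, label, traits = NULL,
                                 mtry_grid = 1:20,
                                 ntree_grid = c(500, 1000, 2500, 5000),
                                 k_folds = 10L, repeats = 3L, seed = 1L) {
  traits <- numeric_trait_cols(table, traits)
  cc <- stats::complete.cases(table[, c(label, traits)])
  table <- table[cc, , drop = FALSE]
  y <- droplevels(factor(table[[label]]))
  if (nlevels(y) != 2L) stop("label must have exactly 2 classes")
  if (min(table(y)) < 10L)
    stop("each class needs >= 10 samples (smallest has ",
         min(table(y)), ")")
  x <- as.matrix(table[, traits, drop = FALSE])
  mtry_grid <- mtry_grid[mtry_grid <= ncol(x)]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds_list <- lapply(seq_len(repeats), function(r)
    sample(rep(seq_len(k_folds), length.out = nrow(x))))
  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i)
    rf_cv_accuracy(x, y, grid$mtry[i], grid$ntree[i], folds_list), 0)
  best <- grid[which.max(grid$accuracy), ]
  final <- randomForest::randomForest(x, y, mtry = best$mtry,
                                      ntree = best$ntree,
                                      proximity = TRUE, importance = TRUE)
  prox <- final$proximity
  d <- stats::as.dist(1 - prox)
  d[d <= 0] <- 1e-6
  nmds <- tryCatch({
    fit <- MASS::isoMDS(d, k = 2, trace = FALSE)
    list(points = fit$points, stress = fit$stress)
  }, error = function(e) list(points = NULL, stress = NA_real_))
  list(best = list(mtry = best$mtry, ntree = best$ntree),
       cv_accuracy = best$accuracy, grid = grid,
       importance = sort(final$importance[, "MeanDecreaseAccuracy"],
                         decreasing = TRUE),
       importance_gini = sort(final$importance[, "MeanDecreaseGini"],
                              decreasing = TRUE),
       proximity = prox, nmds = nmds, model = final)
}
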