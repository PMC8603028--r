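make_clusters <- function(n_geno = 9, per = 10, p = 15, sep = 4, seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("G%02d", seq_len(n_geno)), each = per)
  centers <- matrix(rnorm(n_geno * p, sd = sep), n_geno, p)
  x <- matrix(rnorm(length(g) * p), ncol = p) +
    centers[as.integer(factor(g)), ]
  cbind(data.frame(sample_id = seq_along(g), genotype = g),
        as.data.frame(x))
}

test_that("PCA-LDA separates well-separated genotype clusters", {
  tab <- make_clusters(sep = 5)
  res <- pca_lda_combinations(tab)
  expect_equal(res$n_combinations, choose(9, 3))
  expect_gt(res$mean_accuracy, 0.95)
  expect_true(all(res$per_combination$n_components >= 2))
  # deterministic: same table, same result
  expect_equal(pca_lda_combinations(tab)$mean_accuracy, res$mean_accuracy)
})

test_that("PCA-LDA accuracy collapses to chance under label permutation", {
  tab <- make_clusters(n_geno = 9, per = 14, sep = 4, seed = 2)
  set.seed(10)
  tab$genotype <- sample(tab$genotype)
  res <- pca_lda_combinations(tab)
  expect_lt(abs(res$mean_accuracy - 1 / 3), 0.06)
})

test_that("the genotype combination census matches the closed form", {
  expect_equal(genotype_combination_count(18), 816)
  expect_equal(genotype_combination_count(16), 560)
  expect_equal(genotype_combination_count(5, 2), 10)
})

test_that("genotype filtering keeps those with the least missing data", {
  tab <- make_clusters(n_geno = 6, per = 6)
  tab[tab$genotype == "G02", 3] <- NA          # G02 fully incomplete
  tab[1, 4] <- NA                              # one G01 sample incomplete
  kept <- filter_genotypes(tab, 4)
  expect_false("G02" %in% kept$genotype)
  expect_equal(nlevels(kept$genotype), 4)
})

test_that("random forests separate shifted classes and not permuted ones", {
  set.seed(30)
  n <- 200; p <- 12
  x <- matrix(rnorm(n * p), n, p)
  env <- rep(c("wet", "dry"), each = n / 2)
  x[env == "wet", 1:5] <- x[env == "wet", 1:5] + 3
  tab <- cbind(data.frame(environment = env), as.data.frame(x))
  rf <- random_forest_binary(tab, "environment", mtry_grid = c(3, 6),
                             ntree_grid = 500, seed = 4)
  expect_gt(rf$cv_accuracy, 0.95)
  expect_true(rf$best$mtry %in% c(3, 6))
  expect_true(isSymmetric(rf$proximity))
  expect_true(all(diag(rf$proximity) == 1))
  expect_false(is.na(rf$nmds$stress))

  null <- tab
  set.seed(11); null$environment <- sample(null$environment)
  rf0 <- random_forest_binary(null, "environment", mtry_grid = 4,
                              ntree_grid = 500, seed = 4)
  expect_lt(abs(rf0$cv_accuracy - 0.5), 0.07)
})

test_that("duplicated samples land in the same leaves (proximity ~ 1)", {
  set.seed(12)
  n <- 30; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  tab <- cbind(data.frame(environment = rep(c("a", "b"), each = 15)),
               as.data.frame(x))
  tab2 <- rbind(tab, tab[1, ])                    # duplicate first sample
  rf <- random_forest_binary(tab2, "environment", mtry_grid = 3,
                             ntree_grid = 500, k_folds = 5, repeats = 1,
                             seed = 2)
  expect_gt(rf$proximity[1, nrow(tab2)], 0.9)
})

test_that("mtry values above the feature count are dropped", {
  tab <- make_clusters(n_geno = 2, per = 12, p = 4)
  tab$environment <- rep(c("x", "y"), 12)
  rf <- random_forest_binary(tab, "environment", traits = sprintf("V%d", 1:4),
                             mtry_grid = c(2, 50), ntree_grid = 500,
                             k_folds = 5, repeats = 1, seed = 1)
  expect_true(all(rf$grid$mtry <= 4))
})

test_that("undersized classes are rejected with a clear message", {
  tab <- make_clusters(n_geno = 2, per = 5)
  tab$environment <- rep(c("x", "y"), 5)
  expect_error(random_forest_binary(tab, "environment"), ">= 10 samples")
})
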