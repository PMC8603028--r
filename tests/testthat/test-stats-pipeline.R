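make_trait_table <- function(n = 40, p = 8, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- sprintf("tr%02d", seq_len(p))
  cbind(data.frame(sample_id = sprintf("S%03d", seq_len(n))), x)
}

test_that("PCA outlier flagging finds gross outliers and nothing else", {
  tab <- make_trait_table(40, 8)
  tab[7, -1] <- tab[7, -1] * 100
  flagged <- multivariate_outliers(tab)
  expect_identical(flagged, "S007")

  clean <- make_trait_table(60, 10, seed = 3)
  expect_length(multivariate_outliers(clean), 0)

  # invariant to column reordering
  shuf <- clean[, c(1, sample(2:11))]
  tabs <- clean; tabs[5, -1] <- tabs[5, -1] + 40
  shuf2 <- tabs[, c(1, 1 + sample(10))]
  expect_identical(multivariate_outliers(tabs), multivariate_outliers(shuf2))
})

test_that("Tukey fences exclude points beyond 1.5 IQR and keep constants", {
  x <- c(1:9, 100)
  # Q1 = 3.25, Q3 = 7.75, IQR = 4.5 -> upper fence 14.5 (type-7 quartiles)
  keep <- univariate_outliers(x)
  expect_identical(which(!keep), 10L)

  expect_true(all(univariate_outliers(rep(5, 10))))
  sym <- c(-5, -2, -1, 0, 0, 1, 2, 5)
  expect_true(all(univariate_outliers(sym) == rev(univariate_outliers(-sym))))
})

test_that("per-trait ANOVA with BH control finds injected genotype effects", {
  set.seed(21)
  n_g <- 10; reps <- 6
  g <- factor(rep(sprintf("G%02d", 1:n_g), each = reps))
  env <- factor(rep(c("wet", "dry"), length.out = n_g * reps))
  p <- 30
  x <- matrix(rnorm(length(g) * p), ncol = p)
  affected <- 1:10
  for (j in affected) x[, j] <- x[, j] + 3 * as.integer(g)
  tab <- cbind(data.frame(genotype = g, environment = env),
               as.data.frame(x))
  res <- anova_fdr(tab, factors = c("genotype", "environment"))
  expect_gte(res$counts[["genotype"]], 9)
  expect_lte(res$counts[["genotype"]], 12)
  expect_lte(res$counts[["environment"]], 2)
  # the BH step never creates discoveries that raw p < 0.05 would not
  raw <- res$results
  for (f in unique(raw$factor)) {
    sel <- raw$factor == f
    expect_lte(sum(raw$p_adj[sel] < 0.05, na.rm = TRUE),
               sum(raw$p[sel] < 0.05, na.rm = TRUE))
  }
})

test_that("a trait identical across groups is never significant", {
  g <- factor(rep(c("a", "b", "c"), each = 5))
  tab <- data.frame(genotype = g, flatter = rep(1:5, 3), same = rep(2, 15))
  res <- anova_fdr(tab, factors = "genotype", remove_outliers = FALSE)
  sig <- res$results[!is.na(res$results$p_adj) & res$results$p_adj < 0.05, ]
  expect_equal(nrow(sig), 0)
})

test_that("Mann-Whitney matches the exhaustively enumerated small-sample law", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)    # 2 of C(6,3)=20 rankings are this extreme
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$p, r$p)
  same <- suppressWarnings(mann_whitney(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p, 1)
})

test_that("Spearman correlation ranks are invariant to monotone transforms", {
  set.seed(4)
  tab <- data.frame(anchor = rexp(50))
  tab$mono <- tab$anchor^3 + 5
  tab$noise <- rnorm(50)
  tab$fixed <- 1
  res <- trait_correlations(tab, "anchor")
  expect_equal(res$rho[res$trait == "mono"], 1)
  expect_true(is.na(res$rho[res$trait == "fixed"]))

  # bivariate recovery at rho ~ 0.7
  set.seed(9)
  a <- rnorm(200); b <- 0.7 * a + sqrt(1 - 0.49) * rnorm(200)
  tab2 <- data.frame(anchor = a, b = b)
  rho <- trait_correlations(tab2, "anchor")$rho[1]
  expect_lt(abs(rho - 0.7), 0.1)
})

test_that("regression reports slope, intercept and adjusted R-squared", {
  r <- regression_fit(1:20, 2 * (1:20) + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$adj_r2, 1)

  set.seed(2)
  x <- rnorm(400); y <- rnorm(400)   # independent
  expect_lt(abs(regression_fit(x, y)$adj_r2), 0.03)
  expect_error(regression_fit(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("variance components and H2 follow the entry-mean estimator", {
  expect_equal(broad_sense_h2(structure(list(sigma2_G = 2, sigma2_GxE = 1,
                                             sigma2_res = 1, e = 2, re = 6,
                                             converged = TRUE),
                                        class = "variance_components")), 0.75)
  expect_equal(broad_sense_h2(structure(list(sigma2_G = 3, sigma2_GxE = 0,
                                             sigma2_res = 0, e = 2, re = 6,
                                             converged = TRUE),
                                        class = "variance_components")), 1)
  expect_equal(broad_sense_h2(structure(list(sigma2_G = 0, sigma2_GxE = 1,
                                             sigma2_res = 1, e = 2, re = 6,
                                             converged = TRUE),
                                        class = "variance_components")), 0)

  zero <- simulate_phenotypes(pheno_sim_spec(n_genotypes = 8, seed = 3))
  zero$trait_01 <- 5
  vc <- variance_components(zero, "trait_01")
  expect_equal(vc$sigma2_G, 0)
  expect_equal(vc$e, 2)
  expect_equal(vc$re, 6)

  # H2 is monotone in sigma2_G
  h <- vapply(c(0.5, 1, 2, 4), function(sg)
    broad_sense_h2(structure(list(sigma2_G = sg, sigma2_GxE = 1,
                                  sigma2_res = 1, e = 2, re = 6,
                                  converged = TRUE),
                             class = "variance_components")), 0)
  expect_true(all(diff(h) > 0))
})

test_that("heritability stratifies by time point when asked", {
  tab <- simulate_phenotypes(pheno_sim_spec(n_genotypes = 15, n_traits = 2,
                                            seed = 5))
  tab$time_point <- rep(c("t1", "t2"), length.out = nrow(tab))
  h2 <- heritability_table(tab, by = "time_point")
  expect_setequal(unique(h2$level), c("t1", "t2"))
  expect_equal(nrow(h2), 4)
})
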