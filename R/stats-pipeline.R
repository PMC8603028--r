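numeric_trait_cols <- function(table, traits = NULL) {
  meta_cols <- c("sample_id", "genotype", "environment", "time_point",
                 "experiment", "replicate")
  if (is.null(traits))
    traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                      meta_cols)
  traits
}

#' Flag multivariate outliers by PCA score distance
#'
#' Traits are standardized (zero-variance columns dropped) and projected
#' onto principal components; samples whose score on PC1 or PC2 exceeds
#' `cutoff` standard deviations of that component are flagged — flagged,
#' not dropped, so the caller decides. Complete cases only.
#'
#' @param table Data frame with trait columns (and optional metadata).
#' @param traits Trait column names; defaults to every numeric non-metadata
#'   column.
#' @param cutoff Robust score cutoff in component SDs; default 4.
#' @return Character vector of flagged `sample_id`s (row indices when no
#'   `sample_id` column exists).
#' @export
multivariate_outliers <- function(table, traits = NULL, cutoff = 4) {
  traits <- numeric_trait_cols(table, traits)
  x <- as.matrix(table[, traits, drop = FALSE])
  ids <- if ("sample_id" %in% names(table)) as.character(table$sample_id)
         else as.character(seq_len(nrow(table)))
  cc <- stats::complete.cases(x)
  if (sum(cc) < 3L) stop("need at least 3 complete rows for PCA outliers")
  x <- x[cc, , drop = FALSE]
  keep <- apply(x, 2L, stats::sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  flagged <- rep(FALSE, nrow(x))
  for (j in seq_len(k))
    flagged <- flagged | abs(pc$x[, j]) > cutoff * pc$sdev[j]
  ids[cc][flagged]
}

#' Tukey-fence inclusion mask for one trait
#'
#' Values strictly beyond `Q1 - 1.5 IQR` or `Q3 + 1.5 IQR` are excluded;
#' quartiles use the linear-interpolation convention (type 7). Constant
#' vectors are fully retained (IQR 0). `NA`s are excluded.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @return Logical inclusion mask, same length as `values`.
#' @export
univariate_outliers <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7)
  iqr <- q[2] - q[1]
  ok & values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
}

#' Per-trait ANOVA with Benjamini-Hochberg control
#'
#' For each trait, a linear model on the available design factors is fit
#' and tested with Type-II sums of squares; p-values are adjusted across
#' traits within each factor family (BH), and the number of traits
#' significant at `alpha` is reported per factor. Tukey-fence outliers are
#' removed per trait first (the univariate convention). Traits whose
#' design is aliased or unreplicated are skipped with the reason logged.
#'
#' @param table Data frame with trait and factor columns.
#' @param factors Factor column names to test (each needs >= 2 levels).
#' @param traits Trait columns; default all numeric non-metadata columns.
#' @param alpha Significance level on adjusted p-values; default 0.05.
#' @param remove_outliers Apply [univariate_outliers()] per trait first.
#' @param ss_type `2` (default) or `3`, passed to [car::Anova()].
#' @return List: `results` (trait, factor, F, p, p_adj), `counts` (named,
#'   significant traits per factor), `skipped` (trait -> reason).
#' @export
anova_fdr <- function(table, factors = c("genotype", "environment"),
                      traits = NULL, alpha = 0.05, remove_outliers = TRUE,
                      ss_type = 2) {
  traits <- numeric_trait_cols(table, traits)
  factors <- factors[factors %in% names(table)]
  factors <- factors[vapply(factors, function(f)
    nlevels(factor(table[[f]])) >= 2L, TRUE)]
  if (!length(factors)) stop("no testable factors with >= 2 levels")
  res <- list(); skipped <- character(0)
  for (tr in traits) {
    y <- table[[tr]]
    keep <- !is.na(y)
    if (remove_outliers && sum(keep) >= 4L)
      keep <- keep & {
        m <- rep(FALSE, length(y)); m[which(!is.na(y))] <-
          univariate_outliers(y[!is.na(y)]); m
      }
    dat <- table[keep, c(tr, factors), drop = FALSE]
    names(dat)[1] <- ".y"
    for (f in factors) dat[[f]] <- factor(dat[[f]])
    if (any(vapply(factors, function(f) nlevels(dat[[f]]) < 2L, TRUE)) ||
        nrow(dat) <= length(factors) + 1L) {
      skipped[tr] <- "insufficient_levels_or_rows"
      next
    }
    fml <- stats::as.formula(paste(".y ~", paste(factors, collapse = " + ")))
    tab <- tryCatch({
      fit <- stats::lm(fml, data = dat)
      car::Anova(fit, type = ss_type)
    }, error = function(e) NULL)
    if (is.null(tab)) { skipped[tr] <- "model_failure"; next }
    for (f in factors) {
      if (!f %in% rownames(tab)) next
      res[[length(res) + 1L]] <- data.frame(
        trait = tr, factor = f,
        F = tab[f, "F value"], p = tab[f, "Pr(>F)"])
    }
  }
  results <- do.call(rbind, res)
  results$p_adj <- NA_real_
  for (f in unique(results$factor)) {
    sel <- results$factor == f
    results$p_adj[sel] <- stats::p.adjust(results$p[sel], method = "BH")
  }
  counts <- vapply(factors, function(f)
    sum(results$p_adj[results$factor == f] < alpha, na.rm = TRUE), 0L)
  list(results = results, counts = counts, skipped = skipped)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test (exact for small untied samples, tie-corrected
#' normal approximation otherwise, as in [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `U` (statistic for `group_a`) and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  wt <- stats::wilcox.test(group_a, group_b, alternative = "two.sided")
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlations of every trait against an anchor
#'
#' @param table Data frame of traits.
#' @param anchor Anchor column name (e.g. root pulling force).
#' @param traits Trait columns to correlate; default all numeric
#'   non-metadata columns except the anchor.
#' @param min_pairs Minimum pairwise-complete observations; fewer yields
#'   `NA` for that trait.
#' @return Data frame (trait, rho, n) sorted by decreasing rho; constant
#'   columns carry `NA` rho.
#' @export
trait_correlations <- function(table, anchor, traits = NULL, min_pairs = 3L) {
  stopifnot(anchor %in% names(table))
  traits <- setdiff(numeric_trait_cols(table, traits), anchor)
  a <- table[[anchor]]
  out <- do.call(rbind, lapply(traits, function(tr) {
    y <- table[[tr]]
    ok <- !is.na(a) & !is.na(y)
    rho <- if (sum(ok) < min_pairs || stats::sd(y[ok]) == 0 ||
               stats::sd(a[ok]) == 0) NA_real_
           else stats::cor(a[ok], y[ok], method = "spearman")
    data.frame(trait = tr, rho = rho, n = sum(ok))
  }))
  out[order(-out$rho, na.last = TRUE), ]
}

#' Ordinary least squares fit with adjusted R-squared
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must vary.
#' @return List with `slope`, `intercept`, `adj_r2`, `n`.
#' @export
regression_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need n >= 3")
  if (stats::sd(x[ok]) == 0) stop("x has zero variance")
  fit <- stats::lm(y[ok] ~ x[ok])
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adj_r2 = s$adj.r.squared, n = sum(ok))
}

#' Variance components of a trait by REML
#'
#' Fits the random-effects model `y ~ (1|G) + (1|E) + (1|G:E)` with
#' genotype, environment and their interaction as random intercepts
#' (REML), and records the design constants used by the heritability
#' estimator: `e`, the number of environments, and `re`, the mean
#' replicate count per genotype per environment.
#'
#' @param table Data frame with `genotype`, `environment` and the trait.
#' @param trait Trait column name.
#' @param genotype,environment Factor column names.
#' @return A `variance_components` list: `sigma2_G`, `sigma2_GxE`,
#'   `sigma2_E`, `sigma2_res`, `e`, `re`, `converged`.
#' @export
variance_components <- function(table, trait, genotype = "genotype",
                                environment = "environment") {
  dat <- data.frame(y = table[[trait]],
                    G = factor(table[[genotype]]),
                    E = factor(table[[environment]]))
  dat <- dat[stats::complete.cases(dat), ]
  if (nlevels(droplevels(dat$G)) < 2L) stop("need >= 2 genotypes")
  e <- nlevels(droplevels(dat$E))
  # re is the mean replicate count per genotype pooled over environments
  # (r x e in a balanced design), as the entry-mean H2 denominator expects
  re <- mean(tapply(seq_len(nrow(dat)), droplevels(dat$G), length))
  if (stats::sd(dat$y) == 0) {
    return(structure(list(sigma2_G = 0, sigma2_GxE = 0, sigma2_E = 0,
                          sigma2_res = 0, e = e, re = re, converged = TRUE),
                     class = "variance_components"))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ (1 | G) + (1 | E) + (1 | G:E), data = dat, REML = TRUE))),
    error = function(err) NULL)
  if (is.null(fit)) {
    return(structure(list(sigma2_G = NA_real_, sigma2_GxE = NA_real_,
                          sigma2_E = NA_real_, sigma2_res = NA_real_,
                          e = e, re = re, converged = FALSE),
                     class = "variance_components"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  structure(list(sigma2_G = getv("G"), sigma2_GxE = getv("G:E"),
                 sigma2_E = getv("E"), sigma2_res = getv("Residual"),
                 e = e, re = re, converged = TRUE),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> sG2=%.4g sGxE2=%.4g sE2=%.4g sres2=%.4g (e=%d, re=%.2f)\n",
              x$sigma2_G, x$sigma2_GxE, x$sigma2_E, x$sigma2_res, x$e, x$re))
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxE / e + sigma2_res / re)`, the
#' entry-mean heritability optimized as a predictor of response to
#' selection. In [0, 1] for nonnegative components; `NA` when the
#' denominator is zero or the fit did not converge.
#'
#' @param vc A [variance_components()] result.
#' @return Numeric scalar.
#' @export
broad_sense_h2 <- function(vc) {
  if (!isTRUE(vc$converged)) return(NA_real_)
  denom <- vc$sigma2_G + vc$sigma2_GxE / vc$e + vc$sigma2_res / (vc$re)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  vc$sigma2_G / denom
}

#' Per-trait broad-sense heritability for a whole table
#'
#' Convenience wrapper: [variance_components()] + [broad_sense_h2()] per
#' trait, optionally within levels of a time-point column (the repeated
#' harvest design estimates heritability separately per time point).
#'
#' @param table Data frame with genotype/environment columns.
#' @param traits Trait columns; default all numeric non-metadata columns.
#' @param by Optional column name to stratify by (e.g. `"time_point"`).
#' @inheritParams variance_components
#' @return Data frame (trait, [level,] h2).
#' @export
heritability_table <- function(table, traits = NULL, by = NULL,
                               genotype = "genotype",
                               environment = "environment") {
  traits <- numeric_trait_cols(table, traits)
  strata <- if (is.null(by)) list(`all` = table)
            else split(table, table[[by]])
  do.call(rbind, lapply(names(strata), function(lv) {
    st <- strata[[lv]]
    h2 <- vapply(traits, function(tr)
      broad_sense_h2(variance_components(st, tr, genotype, environment)),
      0)
    d <- data.frame(trait = traits, h2 = h2, row.names = NULL)
    if (!is.null(by)) d <- cbind(level = lv, d)
    d
  }))
}
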