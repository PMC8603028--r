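#' Pipeline configuration
#'
#' Collects every knob of the volume-to-traits pipeline in one record so a
#' run is reproducible from its provenance: input/output paths, threshold
#' settings, component cleanup, skeleton pruning, distribution binning and
#' the top-level seed.
#'
#' @param input_dir Directory of samples: each `<name>.raw` with its
#'   `.meta.yaml` sidecar is one sample.
#' @param output_dir Where the trait table and provenance are written
#'   (`NULL` to skip writing).
#' @param threshold_method,threshold_level See [threshold_volume()].
#' @param min_component_voxels See [clean_mask()].
#' @param n_slabs,n_shells See [vertical_profile()] and [density_s()].
#' @param prune,prune_factor,cluster_radius See [skeletonize()].
#' @param seed Top-level seed (forwarded to any stochastic stage).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            threshold_method = "fixed",
                            threshold_level = 0,
                            min_component_voxels = 10L,
                            n_slabs = 20L, n_shells = 9L,
                            prune = TRUE, prune_factor = 2,
                            cluster_radius = 2, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the volume-to-traits pipeline over a sample directory
#'
#' Each RAW volume is read, thresholded, cleaned, skeletonized and
#' measured; per-sample trait records are concatenated into a trait table
#' in registry column order. A failing sample is quarantined (its error
#' recorded) and the run continues; the run fails only when no sample
#' succeeds. With `output_dir` set, `traits.csv` (with a units header
#' comment) and `provenance.json` are written.
#'
#' @param config A [pipeline_config()].
#' @return List: `table` (trait data frame), `failures` (named character
#'   vector of quarantined samples), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  raws <- sort(list.files(config$input_dir, pattern = "\\.raw$",
                          full.names = TRUE))
  if (!length(raws)) stop("no .raw samples in ", config$input_dir)
  rows <- list(); failures <- character(0)
  for (path in raws) {
    id <- tools::file_path_sans_ext(basename(path))
    rec <- tryCatch({
      vol <- read_raw_volume(path)
      mask <- threshold_volume(vol, config$threshold_method,
                               level = config$threshold_level)
      if (!is.na(mask$provenance$flag)) stop("degenerate segmentation: ",
                                             mask$provenance$flag)
      mask <- clean_mask(mask, config$min_component_voxels)
      extract_traits(mask, sample_id = id, n_slabs = config$n_slabs,
                     n_shells = config$n_shells, prune = config$prune,
                     prune_factor = config$prune_factor,
                     cluster_radius = config$cluster_radius)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) failures[id] <- rec else rows[[id]] <- rec
  }
  if (!length(rows))
    stop("no samples succeeded; first failure: ",
         if (length(failures)) failures[[1]] else "none")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  prov <- list(package_version = as.character(utils::packageVersion("rootcrown")),
               config = unclass(config),
               n_samples = nrow(table), n_failures = length(failures),
               failures = as.list(failures),
               trait_columns = trait_names())
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(table, file.path(config$output_dir, "traits.csv"))
    jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(table = table, failures = failures, provenance = prov)
}

#' Write / read a trait table CSV with a units header
#'
#' The first line is a comment carrying the registry units for each trait
#' column; the rest is plain CSV in registry column order.
#'
#' @param table Trait data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  reg <- trait_registry()
  units <- vapply(names(table), function(nm) {
    i <- match(nm, reg$name)
    if (is.na(i)) "" else reg$units[i]
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(units, collapse = ",")), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Full statistical analysis of a deposited trait table
#'
#' The downstream workflow applied to a phenotype table with the
#' documented schema (trait columns plus `genotype`, `environment` and
#' optionally `time_point`): PCA outlier flagging, per-trait ANOVA with
#' BH control, per-trait broad-sense heritability (per time point when
#' present), trait correlations against an anchor (when given), PCA-LDA
#' genotype classification and random-forest environment classification.
#'
#' @param table Trait data frame (e.g. from [read_trait_table()]).
#' @param anchor Optional anchor trait for the correlation report (e.g.
#'   a root pulling force column).
#' @param max_genotypes Genotype filter size for PCA-LDA (`NULL` keeps all).
#' @param rf_args List of overrides for [random_forest_binary()] (grids,
#'   CV design, seed).
#' @param drop_outliers Remove PCA-flagged samples before the univariate
#'   stages (default `TRUE`).
#' @return List with `outliers`, `anova`, `h2`, `correlations`,
#'   `pca_lda`, `random_forest`.
#' @export
analyze_trait_table <- function(table, anchor = NULL, max_genotypes = NULL,
                                rf_args = list(), drop_outliers = TRUE) {
  out <- list()
  out$outliers <- multivariate_outliers(table)
  if (drop_outliers && length(out$outliers) &&
      "sample_id" %in% names(table))
    table <- table[!table$sample_id %in% out$outliers, , drop = FALSE]
  factors <- intersect(c("genotype", "environment", "time_point"),
                       names(table))
  out$anova <- anova_fdr(table, factors = factors)
  out$h2 <- heritability_table(
    table, by = if ("time_point" %in% names(table)) "time_point" else NULL)
  if (!is.null(anchor))
    out$correlations <- trait_correlations(table, anchor)
  out$pca_lda <- tryCatch(
    pca_lda_combinations(table, max_genotypes = max_genotypes),
    error = function(e) conditionMessage(e))
  if ("environment" %in% names(table))
    out$random_forest <- tryCatch(
      do.call(random_forest_binary,
              c(list(table = table, label = "environment"), rf_args)),
      error = function(e) conditionMessage(e))
  out
}
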