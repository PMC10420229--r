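# End-to-end orchestration: experimental table -> correlation heatmaps
# (all compounds and N-set-filtered) -> surrogate calibrations ->
# clustering / PCA / SVM reports, with a machine-readable run manifest.

#' Default configuration for [run_full_analysis()]
#'
#' @param ... Named overrides of the defaults.
#' @return A named list. Fields: `partition_csv` / `compounds_csv` /
#'   `solvation_csv` / `descriptors_csv` (paths; `NULL` selects the bundled
#'   experimental fixtures, a simulated solvation panel, and the computed
#'   open descriptor panel respectively), `temperature` (K), `min_pairs`
#'   (correlation support), `filter` (also produce the N-set-filtered
#'   correlation matrix), `k` / `n_restarts` (k-means), `n_components`
#'   (PCA), `seed`, `split_fraction` / `n_folds` (SVM protocol),
#'   `residual_sd` (noise of the simulated solvation panel).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    partition_csv = NULL, compounds_csv = NULL, solvation_csv = NULL,
    descriptors_csv = NULL, temperature = 298.15, min_pairs = 3L,
    filter = TRUE, k = 3L, n_restarts = 25L, n_components = 3L,
    seed = 1L, split_fraction = 0.85, n_folds = 10L, residual_sd = 0.5
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_matrix_csv <- function(m, path, first_col = "compound") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- first_col
  write.csv(df, path, row.names = FALSE)
}

#' Run the full partition-coefficient analysis
#'
#' Chains every stage of the workflow: load the compound set and
#' experimental micellar partition table; obtain a computed solvent/water
#' logP matrix (from a solvation CSV, or from a solvation panel simulated
#' around the bundled reference calibrations when none is given); build
#' pairwise correlation matrices with and without the aromatic-N/urea
#' exclusion; fit all micelle-vs-solvent calibrations; and run the
#' descriptor workflow (z-transform, k-means, PCA, per-micelle SVM
#' regression). All numeric outputs are written as CSV into `outdir`
#' together with a JSON manifest echoing the configuration, seeds, row
#' counts, and package version; a rerun with the same configuration
#' reproduces every output byte-identically.
#'
#' @param config Configuration list, see [pipeline_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory results (`compounds`,
#'   `experimental`, `computed`, `correlation`, `correlation_filtered`,
#'   `filter`, `calibrations`, `descriptors`, `clusters`, `profile`, `pca`,
#'   `svm`, `manifest`).
#' @export
run_full_analysis <- function(config = pipeline_config(), outdir) {
  stopifnot(is.list(config), !missing(outdir))
  config <- do.call(pipeline_config, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  compounds <- run_stage("compounds", {
    if (is.null(config$compounds_csv)) experimental_compounds()
    else load_compound_table(config$compounds_csv)
  })
  experimental <- run_stage("partition_table", {
    tab <- if (is.null(config$partition_csv)) experimental_logp_table()
           else load_partition_table(config$partition_csv)
    colnames(tab) <- sub("^logP_", "", colnames(tab))
    missing_cpd <- setdiff(rownames(tab), compounds$name)
    if (length(missing_cpd)) {
      stop("partition table compounds missing from compound table: ",
           paste(missing_cpd, collapse = ", "))
    }
    tab
  })

  computed <- run_stage("solvation", {
    dg <- if (is.null(config$solvation_csv)) {
      ref <- reference_calibrations()
      plant <- ref[!ref$n_set_excluded, c("micelle", "solvent", "slope", "intercept")]
      # one planted solvent column per (micelle, solvent) reference pair
      plant$solvent <- paste0(plant$solvent, "[", plant$micelle, "]")
      filled <- experimental
      filled[is.na(filled)] <- mean(experimental, na.rm = TRUE)
      dg <- simulate_solvation(filled, plant, residual_sd = config$residual_sd,
                               temperature = config$temperature,
                               seed = config$seed)
      # cells unmeasured in the experimental table stay missing downstream
      for (j in seq_len(nrow(plant))) {
        dg[is.na(experimental[, plant$micelle[j]]), plant$solvent[j]] <- NA
      }
      dg
    } else {
      read_solvation_table(config$solvation_csv)
    }
    logp_matrix(dg, temperature = config$temperature)
  })

  correlation <- run_stage("correlation", {
    correlation_matrix(experimental, computed, min_pairs = config$min_pairs)
  })
  filter_res <- NULL; correlation_filtered <- NULL
  if (isTRUE(config$filter)) {
    filter_res <- run_stage("nset_filter", nset_filter(compounds))
    correlation_filtered <- run_stage("correlation_filtered", {
      keep <- intersect(rownames(experimental), filter_res$retained$name)
      correlation_matrix(experimental[keep, , drop = FALSE],
                         computed[keep, , drop = FALSE],
                         min_pairs = config$min_pairs)
    })
  }

  calibrations <- run_stage("calibration",
                            calibration_table(experimental, computed))

  descriptors <- run_stage("descriptors", {
    if (is.null(config$descriptors_csv)) compute_descriptors(compounds)
    else load_partition_table(config$descriptors_csv)
  })
  z <- run_stage("standardize", standardize_descriptors(descriptors))
  clusters <- run_stage("kmeans",
                        kmeans_cluster(z, k = config$k, seed = config$seed,
                                       n_restarts = config$n_restarts))
  profile <- run_stage("cluster_profile", cluster_profile(clusters, z))
  pca <- run_stage("pca", pca_descriptors(z, n_components = config$n_components))
  svm <- run_stage("svm", {
    lapply(setNames(nm = colnames(experimental)), function(mic) {
      y <- experimental[rownames(descriptors), mic]
      svm_regress(descriptors, y, seed = config$seed,
                  split_fraction = config$split_fraction,
                  n_folds = config$n_folds, micelle = mic)
    })
  })

  run_stage("write_outputs", {
    write_matrix_csv(correlation$r, file.path(outdir, "correlation_all.csv"),
                     first_col = "label")
    write_matrix_csv(correlation$n_pairs,
                     file.path(outdir, "correlation_all_npairs.csv"),
                     first_col = "label")
    if (!is.null(correlation_filtered)) {
      write_matrix_csv(correlation_filtered$r,
                       file.path(outdir, "correlation_filtered.csv"),
                       first_col = "label")
      write.csv(data.frame(name = names(filter_res$reasons),
                           excluded = names(filter_res$reasons) %in%
                             filter_res$excluded$name,
                           reason = unname(filter_res$reasons)),
                file.path(outdir, "filter_report.csv"), row.names = FALSE)
    }
    write.csv(calibrations, file.path(outdir, "calibrations.csv"),
              row.names = FALSE)
    write.csv(data.frame(compound = rownames(z),
                         cluster = unname(clusters$labels)),
              file.path(outdir, "clusters.csv"), row.names = FALSE)
    write_matrix_csv(profile$profile, file.path(outdir, "cluster_profile.csv"),
                     first_col = "cluster")
    write.csv(data.frame(component = seq_along(pca$explained_variance_ratio),
                         variance_ratio = pca$explained_variance_ratio),
              file.path(outdir, "pca_variance.csv"), row.names = FALSE)
    write_matrix_csv(pca$loadings, file.path(outdir, "pca_loadings.csv"),
                     first_col = "descriptor")
    write_matrix_csv(pca$scores, file.path(outdir, "pca_scores.csv"),
                     first_col = "compound")
    svm_df <- do.call(rbind, lapply(svm, function(s) data.frame(
      micelle = s$micelle, n_train = s$n_train, n_test = s$n_test,
      cost = s$best_hyperparameters$cost,
      epsilon = s$best_hyperparameters$epsilon,
      gamma = s$best_hyperparameters$gamma, cv_rmse = s$cv_rmse,
      r2_test = s$r2_test, rmse_test = s$rmse_test, mae_test = s$mae_test)))
    write.csv(svm_df, file.path(outdir, "svm_report.csv"), row.names = FALSE)
  })

  manifest <- list(
    package = "micellogp",
    version = as.character(utils::packageVersion("micellogp")),
    config = config[!vapply(config, is.null, logical(1L))],
    n_compounds = nrow(compounds),
    n_partition_rows = nrow(experimental),
    n_descriptors = ncol(descriptors),
    n_excluded = if (is.null(filter_res)) NA_integer_
                 else nrow(filter_res$excluded),
    cluster_sizes = sort(clusters$sizes, decreasing = TRUE),
    outputs = sort(list.files(outdir, pattern = "\\.csv$"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(compounds = compounds, experimental = experimental,
                 computed = computed, correlation = correlation,
                 correlation_filtered = correlation_filtered,
                 filter = filter_res, calibrations = calibrations,
                 descriptors = descriptors, clusters = clusters,
                 profile = profile, pca = pca, svm = svm,
                 manifest = manifest))
}
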