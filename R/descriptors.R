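# Descriptor-space workflow: open descriptor panel, z-transform, k-means
# partitioning, PCA variance decomposition, and SVM regression with grid
# search and cross-validation.

#' Compute an open molecular-descriptor panel
#'
#' Builds a compounds x descriptors matrix from structures using open
#' toolkits (OpenBabel properties plus constitutional counts): molecular
#' weight, Crippen-type logP, molar refractivity, topological polar surface
#' area, hydrogen-bond donor/acceptor counts, heavy-atom and per-element
#' counts, ring and aromatic-ring counts, and functional-group counts. This
#' panel is an open stand-in for commercial descriptor sets; it feeds the
#' same standardization/clustering/PCA/SVM workflow, which accepts any
#' external descriptor CSV equally.
#'
#' @param compounds A `compound_set` data frame (columns `name`, `smiles`).
#' @return Numeric matrix with compound row names.
#' @export
compute_descriptors <- function(compounds) {
  stopifnot(is.data.frame(compounds),
            all(c("name", "smiles") %in% names(compounds)))
  sdf <- parse_compounds(compounds$smiles, compounds$name)
  prop <- ChemmineR::propOB(sdf)
  atoms <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  rings <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  grp <- ChemmineR::groups(sdf, type = "countMA")

  heavy <- rowSums(atoms)
  halogens <- rowSums(atoms[, intersect(c("F", "Cl", "Br", "I"),
                                        colnames(atoms)), drop = FALSE])
  elem <- function(e) if (e %in% colnames(atoms)) atoms[, e] else numeric(nrow(atoms))
  m <- cbind(
    MW = prop$MW, logP_crippen = prop$logP, MR = prop$MR, TPSA = prop$TPSA,
    HBD = prop$HBD, HBA = prop$HBA1,
    n_heavy = heavy, n_C = elem("C"), n_N = elem("N"), n_O = elem("O"),
    n_halogen = halogens,
    pct_N = 100 * elem("N") / heavy, pct_O = 100 * elem("O") / heavy,
    n_rings = rings[, "RINGS"], n_aromatic_rings = rings[, "AROMATIC"],
    grp
  )
  rownames(m) <- compounds$name
  storage.mode(m) <- "double"
  m
}

#' Column-wise z-transform of a descriptor matrix
#'
#' Standardizes every descriptor to mean 0 and unit sample (n-1) standard
#' deviation, so that clustering and PCA are not driven by descriptor
#' units. Zero-variance columns carry no information on a standardized
#' scale and are dropped with a warning.
#'
#' @param dm Numeric matrix (compounds x descriptors).
#' @return Standardized numeric matrix (possibly with fewer columns).
#' @export
standardize_descriptors <- function(dm) {
  stopifnot(is.matrix(dm), is.numeric(dm), nrow(dm) >= 2L)
  if (anyNA(dm)) stop("descriptor matrix contains missing values", call. = FALSE)
  sds <- apply(dm, 2L, sd)
  constant <- sds == 0
  if (all(constant)) {
    stop("degenerate input: all descriptor columns are constant", call. = FALSE)
  }
  if (any(constant)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(dm)[constant], collapse = ", "), call. = FALSE)
    dm <- dm[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  z <- scale(dm, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Partition compounds by k-means in descriptor space
#'
#' Runs k-means (minimizing the total within-cluster sum of squared
#' Euclidean distances) on a standardized descriptor matrix, keeping the
#' best of `n_restarts` seeded random initializations. Results are
#' deterministic given `(dm, k, seed, n_restarts)`.
#'
#' @param dm Standardized descriptor matrix (see
#'   [standardize_descriptors()]).
#' @param k Number of clusters, `1 <= k <= nrow(dm)`.
#' @param seed Integer RNG seed for the restarts.
#' @param n_restarts Number of random initializations.
#' @return An object of class `cluster_result`: list with `labels` (named
#'   integer vector in 1..k), `centroids` (k x p), `within_ss` (total
#'   within-cluster sum of squares), and `sizes`.
#' @export
kmeans_cluster <- function(dm, k, seed, n_restarts = 25L) {
  stopifnot(is.matrix(dm), is.numeric(dm))
  if (k > nrow(dm) || k < 1L) {
    stop("k must satisfy 1 <= k <= number of compounds", call. = FALSE)
  }
  if (k == nrow(dm)) {
    # every point its own centroid
    labels <- setNames(seq_len(nrow(dm)), rownames(dm))
    return(structure(list(labels = labels, centroids = dm, within_ss = 0,
                          sizes = rep(1L, k)),
                     class = "cluster_result"))
  }
  km <- with_seed(seed,
                  kmeans(dm, centers = k, nstart = n_restarts, iter.max = 100L))
  structure(list(labels = km$cluster, centroids = km$centers,
                 within_ss = km$tot.withinss, sizes = km$size),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, sizes = [%s], within-SS = %.3f\n",
              length(x$sizes), paste(x$sizes, collapse = ", "), x$within_ss))
  invisible(x)
}

#' Principal component analysis of a descriptor matrix
#'
#' Eigen-decomposition of the correlation matrix (the input is expected
#' standardized, so covariance PCA on it is correlation PCA on the raw
#' data). Components are ordered by decreasing eigenvalue; the explained
#' variance ratios over all components sum to one.
#'
#' @param dm Standardized descriptor matrix.
#' @param n_components Number of leading components to return,
#'   `<= min(nrow, ncol)`.
#' @return An object of class `pca_result`: `loadings` (p x m, orthonormal),
#'   `scores` (n x m), and `explained_variance_ratio` (all components).
#' @export
pca_descriptors <- function(dm, n_components = 3L) {
  stopifnot(is.matrix(dm), is.numeric(dm))
  if (n_components < 1L || n_components > min(dim(dm))) {
    stop("n_components must lie in [1, min(n, p)]", call. = FALSE)
  }
  p <- prcomp(dm, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  structure(list(
    loadings = p$rotation[, seq_len(n_components), drop = FALSE],
    scores = p$x[, seq_len(n_components), drop = FALSE],
    explained_variance_ratio = ev / sum(ev)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  m <- ncol(x$loadings)
  cat(sprintf("<pca_result> %d components; cumulative variance = %.1f%%\n",
              m, 100 * sum(x$explained_variance_ratio[seq_len(m)])))
  invisible(x)
}

#' Per-cluster descriptor means
#'
#' Averages each (standardized) descriptor within each cluster and reports
#' which cluster attains the maximal and minimal level of every descriptor
#' - the profile that characterizes what drives the partitioning.
#'
#' @param cr A `cluster_result`.
#' @param dm The standardized descriptor matrix the clustering was run on.
#' @return List with `profile` (k x p matrix of within-cluster means),
#'   `argmax`, and `argmin` (named integer vectors: per-descriptor cluster
#'   attaining the extreme mean).
#' @export
cluster_profile <- function(cr, dm) {
  stopifnot(inherits(cr, "cluster_result"), is.matrix(dm),
            length(cr$labels) == nrow(dm))
  sizes <- as.vector(table(factor(cr$labels, seq_along(cr$sizes))))
  profile <- rowsum(dm, cr$labels) / sizes
  list(profile = profile,
       argmax = apply(profile, 2L, which.max),
       argmin = apply(profile, 2L, which.min))
}

#' Hyperparameter grid for SVM regression
#'
#' @param cost,epsilon Grid values for the SVM cost and epsilon-tube.
#' @param gamma_mult Multipliers applied to the data-driven RBF width
#'   `1 / (p * mean column variance)` of the training descriptors.
#' @return Data frame of grid combinations (row order = search order; ties
#'   in cross-validated error resolve to the earliest row).
#' @export
svm_grid <- function(cost = c(0.1, 1, 10, 100),
                     epsilon = c(0.01, 0.1, 0.5),
                     gamma_mult = c(0.1, 1, 10)) {
  expand.grid(cost = cost, epsilon = epsilon, gamma_mult = gamma_mult,
              KEEP.OUT.ATTRS = FALSE)
}

#' SVM regression of micellar logP on descriptors
#'
#' Radial-basis support-vector regression with seeded train/test split and
#' grid-searched hyperparameters. The data are split into a training part
#' (default 85 percent) and a held-out test part by a seeded shuffle;
#' hyperparameters are chosen by `n_folds`-fold cross-validated RMSE on the
#' training part only; the selected model is refit on the full training
#' part and evaluated once on the test part. Descriptors are standardized
#' with training-set statistics.
#'
#' @param dm Numeric descriptor matrix (compounds x descriptors).
#' @param y Response vector of micellar logP values aligned with `dm` rows;
#'   rows with missing `y` are dropped.
#' @param selected Optional character vector of descriptor names to use
#'   (must be a subset of `colnames(dm)`); default all.
#' @param seed Integer seed driving the split and fold assignment.
#' @param split_fraction Fraction of complete rows used for training.
#' @param n_folds Cross-validation folds for the grid search.
#' @param grid Hyperparameter grid, see [svm_grid()].
#' @param micelle Optional label stored in the report.
#' @param test_index Optional explicit test-set row names (overrides the
#'   seeded split; used to verify split-invariance).
#' @return An object of class `svm_report`: selected descriptors, best
#'   hyperparameters, cross-validated RMSE, and test-set `r2_test`
#'   (coefficient of determination, 1 - SS_res/SS_tot; negative when worse
#'   than the mean predictor), `rmse_test`, `mae_test`, `n_train`,
#'   `n_test`, `test_compounds`.
#' @export
svm_regress <- function(dm, y, selected = NULL, seed = 1L,
                        split_fraction = 0.85, n_folds = 10L,
                        grid = svm_grid(), micelle = NA_character_,
                        test_index = NULL) {
  stopifnot(is.matrix(dm), is.numeric(dm), length(y) == nrow(dm),
            split_fraction > 0, split_fraction < 1, n_folds >= 2L)
  if (is.null(rownames(dm))) rownames(dm) <- paste0("row", seq_len(nrow(dm)))
  if (!is.null(selected)) {
    missing_desc <- setdiff(selected, colnames(dm))
    if (length(missing_desc)) {
      stop("unknown descriptor(s): ", paste(missing_desc, collapse = ", "),
           call. = FALSE)
    }
    dm <- dm[, selected, drop = FALSE]
  }
  keep <- !is.na(y) & complete.cases(dm)
  dm <- dm[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(dm)
  if (n < 20L) {
    stop("insufficient data: need >= 20 complete rows, have ", n, call. = FALSE)
  }

  if (is.null(test_index)) {
    n_test <- max(1L, n - floor(split_fraction * n + 1e-9))
    perm <- with_seed(seed, sample.int(n))
    test_rows <- sort(perm[seq_len(n_test)])
  } else {
    test_rows <- which(rownames(dm) %in% test_index)
    if (!length(test_rows) || length(test_rows) >= n) {
      stop("test_index must select a non-empty strict subset of rows",
           call. = FALSE)
    }
  }
  train_rows <- setdiff(seq_len(n), test_rows)
  # canonical (row-name) ordering makes the fit, the fold assignment, and
  # hence all metrics invariant to the row order of the input
  train_rows <- train_rows[order(rownames(dm)[train_rows])]
  test_rows <- test_rows[order(rownames(dm)[test_rows])]

  x_tr <- dm[train_rows, , drop = FALSE]
  sds <- apply(x_tr, 2L, sd)
  usable_col <- sds > 0
  if (!any(usable_col)) stop("all descriptors constant on the training split",
                             call. = FALSE)
  ctr <- colMeans(x_tr[, usable_col, drop = FALSE])
  scl <- sds[usable_col]
  scale_x <- function(m) scale(m[, usable_col, drop = FALSE], ctr, scl)
  x_tr <- scale_x(dm[train_rows, , drop = FALSE])
  x_te <- scale_x(dm[test_rows, , drop = FALSE])
  y_tr <- y[train_rows]; y_te <- y[test_rows]

  gamma0 <- 1 / (ncol(x_tr) * mean(apply(x_tr, 2L, var)))
  # fold assignment on the training rows only, seeded (offset keeps the fold
  # draw distinct from the split draw)
  folds <- with_seed(seed + 1L,
                     sample(rep_len(seq_len(n_folds), length(train_rows))))

  cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    sq_err <- unlist(lapply(seq_len(n_folds), function(f) {
      hold <- folds == f
      if (!any(hold) || all(hold)) return(numeric(0))
      fit <- e1071::svm(x_tr[!hold, , drop = FALSE], y_tr[!hold],
                        type = "eps-regression", kernel = "radial",
                        cost = grid$cost[g], epsilon = grid$epsilon[g],
                        gamma = gamma0 * grid$gamma_mult[g], scale = FALSE)
      (y_tr[hold] - predict(fit, x_tr[hold, , drop = FALSE]))^2
    }))
    sqrt(mean(sq_err))
  }, numeric(1L))
  best <- which.min(cv_rmse)  # ties -> earliest grid row

  fit <- e1071::svm(x_tr, y_tr, type = "eps-regression", kernel = "radial",
                    cost = grid$cost[best], epsilon = grid$epsilon[best],
                    gamma = gamma0 * grid$gamma_mult[best], scale = FALSE)
  pred <- predict(fit, x_te)
  resid <- y_te - pred
  ss_tot <- sum((y_te - mean(y_te))^2)
  structure(list(
    micelle = micelle,
    selected_descriptors = colnames(dm),
    best_hyperparameters = list(cost = grid$cost[best],
                                epsilon = grid$epsilon[best],
                                gamma = gamma0 * grid$gamma_mult[best]),
    cv_rmse = cv_rmse[best],
    r2_test = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
    rmse_test = sqrt(mean(resid^2)),
    mae_test = mean(abs(resid)),
    n_train = length(train_rows), n_test = length(test_rows),
    test_compounds = rownames(dm)[test_rows]
  ), class = "svm_report")
}

#' @export
print.svm_report <- function(x, ...) {
  cat(sprintf(
    "<svm_report>%s n_train = %d, n_test = %d | R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
    if (!is.na(x$micelle)) paste0(" ", x$micelle, ":") else "",
    x$n_train, x$n_test, x$r2_test, x$rmse_test, x$mae_test))
  cat(sprintf("  best: cost = %g, epsilon = %g, gamma = %.4g (CV RMSE = %.3f)\n",
              x$best_hyperparameters$cost, x$best_hyperparameters$epsilon,
              x$best_hyperparameters$gamma, x$cv_rmse))
  invisible(x)
}
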