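# -- multivariate morphometric protocol ---------------------------------------
#
# prepare: 20 haptoral parameters (hook VII excluded), drop columns then
# rows above the missingness threshold, impute residual cells by column
# mean; PCA on z-scored columns; NMDS on the standardized matrix.

#' Prepare a morphometric matrix
#'
#' Builds the specimen-by-parameter matrix for ordination from specimen
#' records: the 20 haptoral parameters (hook pair VII is excluded because of
#' its missing-data load), then drops variables and specimens whose missing
#' fraction exceeds `missing_threshold` (columns first, then rows), and
#' imputes any residual missing cell by the column mean, logging every
#' imputation.
#'
#' @param records Specimen data frame (>= 3 rows).
#' @param missing_threshold Maximum tolerated missing fraction per column /
#'   row; default 0.5.
#' @return A `kg_morpho_matrix`: numeric matrix with attributes
#'   `dropped_rows`, `dropped_cols`, `imputed` (data frame of row, col) and
#'   `groups` (the records' `species_label`).
#' @export
prepare_matrix <- function(records, missing_threshold = 0.5) {
  validate_specimens(records)
  if (nrow(records) < 3) stop("need at least 3 specimens")
  params <- kg_ordination_params()
  m <- as.matrix(records[, params])
  rownames(m) <- records$specimen_id
  groups <- setNames(records$species_label, records$specimen_id)

  col_miss <- colMeans(is.na(m))
  dropped_cols <- colnames(m)[col_miss > missing_threshold]
  m <- m[, setdiff(colnames(m), dropped_cols), drop = FALSE]
  row_miss <- rowMeans(is.na(m))
  dropped_rows <- rownames(m)[row_miss > missing_threshold]
  m <- m[setdiff(rownames(m), dropped_rows), , drop = FALSE]
  if (nrow(m) == 0) stop("all specimens dropped by the missingness filter")

  imputed <- which(is.na(m), arr.ind = TRUE)
  if (nrow(imputed)) {
    cm <- colMeans(m, na.rm = TRUE)
    m[imputed] <- cm[imputed[, "col"]]
  }
  structure(m,
            dropped_rows = dropped_rows, dropped_cols = dropped_cols,
            imputed = data.frame(
              specimen = rownames(m)[imputed[, "row"]],
              param = colnames(m)[imputed[, "col"]],
              stringsAsFactors = FALSE),
            groups = groups[rownames(m)],
            class = c("kg_morpho_matrix", "matrix", "array"))
}

standardize_columns <- function(m) {
  sds <- apply(m, 2, sd)
  keep <- sds > 0
  if (!all(keep))
    warning("zero-variance column(s) dropped: ",
            paste(colnames(m)[!keep], collapse = ", "))
  scale(m[, keep, drop = FALSE])
}

#' Principal component analysis of a morphometric matrix
#'
#' Z-scores every column (mean 0, sd 1) and eigendecomposes; zero-variance
#' columns are dropped with a warning. The sign of each axis is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param m A matrix from [prepare_matrix()] (or any numeric matrix with >=
#'   3 rows, >= 2 columns), optionally already standardized.
#' @param standardize Standardize columns first (default `TRUE`).
#' @return A `kg_ordination` with `method = "pca"`, `scores`,
#'   `explained_variance_pct` (non-increasing, summing to 100 over all
#'   axes), `loadings`, `dropped_rows`/`dropped_cols`, `groups`.
#' @export
run_pca <- function(m, standardize = TRUE) {
  stopifnot(nrow(m) >= 3, ncol(m) >= 2)
  x <- if (standardize) standardize_columns(m) else as.matrix(m)
  fit <- prcomp(x, center = FALSE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading positive on each axis
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2
  structure(list(
    method = "pca",
    scores = fit$x,
    explained_variance_pct = 100 * ev / sum(ev),
    stress = NULL,
    loadings = fit$rotation,
    dropped_rows = attr(m, "dropped_rows"),
    dropped_cols = attr(m, "dropped_cols"),
    groups = attr(m, "groups")
  ), class = "kg_ordination")
}

#' Non-metric multidimensional scaling of a morphometric matrix
#'
#' Runs NMDS (via \code{vegan::metaMDS} / monoMDS) on distances between
#' standardized specimens, with multiple random starts under a fixed seed;
#' the lowest-stress configuration is returned. Euclidean distance on the
#' standardized matrix is the default (morphometric lengths share a unit;
#' community-ecology dissimilarities are available through `distance`).
#'
#' @param m A matrix from [prepare_matrix()].
#' @param k Number of ordination dimensions (`< nrow(m)`).
#' @param seed Integer seed for the random starts.
#' @param distance Distance measure: `"euclidean"` (default, on
#'   standardized columns) or any measure accepted by
#'   \code{vegan::vegdist}.
#' @param standardize Standardize columns first (default `TRUE`).
#' @param trymax Maximum random starts.
#' @return A `kg_ordination` with `method = "nmds"`, `scores`, `stress`,
#'   and fitted variable vectors in `loadings`.
#' @export
run_nmds <- function(m, k = 2, seed = 1L, distance = "euclidean",
                     standardize = TRUE, trymax = 20) {
  if (k >= nrow(m)) stop("k must be smaller than the number of specimens")
  x <- if (standardize) standardize_columns(m) else as.matrix(m)
  d <- if (distance == "euclidean") dist(x) else vegan::vegdist(x, distance)
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  scores <- vegan::scores(fit, display = "sites")
  rownames(scores) <- rownames(x)
  env <- tryCatch(vegan::envfit(fit, as.data.frame(x), permutations = 0),
                  error = function(e) NULL)
  loadings <- if (!is.null(env)) vegan::scores(env, display = "vectors")
              else NULL
  structure(list(
    method = "nmds",
    scores = scores,
    explained_variance_pct = NULL,
    stress = fit$stress,
    loadings = loadings,
    dropped_rows = attr(m, "dropped_rows"),
    dropped_cols = attr(m, "dropped_cols"),
    groups = attr(m, "groups")
  ), class = "kg_ordination")
}

#' @export
print.kg_ordination <- function(x, ...) {
  if (x$method == "pca") {
    cat(sprintf("<kg_ordination> PCA, %d specimens x %d axes\n",
                nrow(x$scores), ncol(x$scores)))
    ev <- x$explained_variance_pct
    cat(sprintf("  axis 1: %.1f%%, axis 2: %.1f%% of variance\n",
                ev[1], if (length(ev) > 1) ev[2] else NA))
  } else {
    cat(sprintf("<kg_ordination> NMDS, %d specimens, k = %d, stress %.4g\n",
                nrow(x$scores), ncol(x$scores), x$stress))
  }
  if (length(x$dropped_rows))
    cat("  dropped specimens: ", paste(x$dropped_rows, collapse = ", "), "\n")
  if (length(x$dropped_cols))
    cat("  dropped variables: ", paste(x$dropped_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.kg_ordination <- function(x, axes = c(1, 2), ...) {
  sc <- x$scores[, axes, drop = FALSE]
  grp <- x$groups
  if (is.null(grp)) grp <- rep("specimen", nrow(sc))
  grp <- factor(grp)
  cols <- hcl.colors(max(3, nlevels(grp)), "Dark 3")[as.integer(grp)]
  lab <- if (x$method == "pca")
    sprintf("PC%d (%.1f%%)", axes, x$explained_variance_pct[axes])
  else sprintf("NMDS%d", axes)
  plot(sc, col = cols, pch = 19, xlab = lab[1], ylab = lab[2], ...)
  legend("topright", legend = levels(grp), cex = 0.7,
         col = hcl.colors(max(3, nlevels(grp)), "Dark 3")[seq_len(nlevels(grp))],
         pch = 19, bty = "n")
  invisible(x)
}

#' Between- versus within-species ordination separation
#'
#' For ordination scores of specimens from two or more groups, estimates the
#' probability that a randomly chosen between-group pair of specimens is
#' further apart in ordination space than a randomly chosen within-group
#' pair.
#'
#' @param ord A `kg_ordination` (or a score matrix) and a grouping vector.
#' @param groups Group labels per specimen (defaults to the ordination's
#'   stored groups).
#' @return Proportion in `[0, 1]`.
#' @export
separation_probability <- function(ord, groups = NULL) {
  sc <- if (inherits(ord, "kg_ordination")) ord$scores else as.matrix(ord)
  if (is.null(groups)) groups <- attr(ord, "groups")
  if (is.null(groups) && inherits(ord, "kg_ordination")) groups <- ord$groups
  stopifnot(length(groups) == nrow(sc))
  d <- as.matrix(dist(sc))
  same <- outer(groups, groups, "==")
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  if (!length(within) || !length(between))
    stop("need both within- and between-group pairs")
  F_within <- ecdf(within)
  mean(F_within(between))
}
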