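#' Principal component analysis of morphometric traits
#'
#' PCA of the trait columns of a specimen table, by default on the
#' correlation matrix (traits are z-scored) since the traits mix millimetre
#' measurements with counts; covariance-matrix PCA is available with
#' `scale = FALSE`. Axes are ordered by decreasing variance and carry a
#' deterministic sign convention: the largest-magnitude loading on each axis
#' is positive. Rows with missing trait values are dropped and logged.
#'
#' @param table Specimen data frame (typically size-corrected).
#' @param scale Logical; `TRUE` (default) for correlation-matrix PCA.
#' @param traits Trait columns to use.
#' @return Object of class `pca_result` with elements `loadings` (trait x
#'   axis), `scores` (specimen x axis), `pct_variance`, `sdev`, `center`,
#'   `scale`, `sites`, `habitats`, `dropped` (row indices removed for
#'   missingness).
#' @export
#' @examples
#' sim <- generate_specimens(sim_config(seed = 1))
#' p <- run_pca(sim$specimens)
#' round(p$pct_variance, 1)
run_pca <- function(table, scale = TRUE, traits = trait_columns(table)) {
  x <- as.matrix(table[, traits, drop = FALSE])
  storage.mode(x) <- "double"
  keep <- stats::complete.cases(x)
  if (!all(keep))
    message(sum(!keep), " specimen(s) with missing trait values dropped")
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 complete specimens")
  sds <- apply(x, 2, stats::sd)
  if (scale && any(sds == 0))
    stop("constant trait column(s) with scale = TRUE: ",
         paste(traits[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  # sign convention: largest-|loading| entry of each axis positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  res <- list(
    loadings = pc$rotation,
    scores = pc$x,
    pct_variance = 100 * pc$sdev^2 / sum(pc$sdev^2),
    sdev = pc$sdev,
    center = pc$center,
    scale = if (scale) pc$scale else NULL,
    scaled = scale,
    sites = as.character(table$site[keep]),
    habitats = if ("habitat" %in% colnames(table))
      as.character(table$habitat[keep]) else NULL,
    dropped = which(!keep)
  )
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of %d specimens x %d traits (%s matrix)\n",
              nrow(x$scores), nrow(x$loadings),
              if (x$scaled) "correlation" else "covariance"))
  pv <- round(x$pct_variance[seq_len(min(5, length(x$pct_variance)))], 1)
  cat("variance explained (%):", paste(pv, collapse = ", "),
      if (length(x$pct_variance) > 5) "...", "\n")
  invisible(x)
}

#' Orient principal axes by habitat contrast
#'
#' Flips the requested axes so that the mean freshwater score exceeds the
#' mean marine score, making divergence directions comparable across runs.
#' A pure reflection: angles and distances are unchanged.
#'
#' @param pca A [run_pca()] result with habitat information.
#' @param axes Axis indices to orient (default PC1).
#' @return The modified `pca_result`.
#' @export
orient_to_habitat <- function(pca, axes = 1) {
  if (is.null(pca$habitats)) stop("pca carries no habitat labels")
  fw <- pca$habitats == "freshwater"
  for (j in axes) {
    if (mean(pca$scores[fw, j]) < mean(pca$scores[!fw, j])) {
      pca$scores[, j] <- -pca$scores[, j]
      pca$loadings[, j] <- -pca$loadings[, j]
    }
  }
  pca
}

#' Per-site centroids in principal-component space
#'
#' Mean score of each site's specimens on the requested axes.
#'
#' @param pca A [run_pca()] result.
#' @param metadata Optional site metadata; if given, every metadata site
#'   must be present in the scores (error otherwise) and the output is
#'   ordered to match.
#' @param axes Axis indices (default all).
#' @return Data frame of class `centroid_set`: `site`, `n`, one column per
#'   axis (`PC1`, `PC2`, ...).
#' @export
site_centroids <- function(pca, metadata = NULL, axes = NULL) {
  if (is.null(axes)) axes <- seq_len(ncol(pca$scores))
  sites <- pca$sites
  ord <- unique(sites)
  if (!is.null(metadata)) {
    miss <- setdiff(metadata$site, sites)
    if (length(miss))
      stop("site(s) absent from scores: ", paste(miss, collapse = ", "))
    ord <- metadata$site
  }
  sc <- pca$scores[, axes, drop = FALSE]
  cen <- matrix(NA_real_, length(ord), ncol(sc),
                dimnames = list(NULL, colnames(sc)))
  for (k in seq_along(ord))
    cen[k, ] <- colMeans(sc[sites == ord[k], , drop = FALSE])
  out <- data.frame(site = ord, n = as.integer(table(sites)[ord]), cen,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("centroid_set", "data.frame")
  out
}

centroid_axes <- function(centroids) {
  setdiff(colnames(centroids), c("site", "n"))
}

centroid_row <- function(centroids, site) {
  i <- match(site, centroids$site)
  if (is.na(i)) stop("site not found in centroids: ", site)
  unlist(centroids[i, centroid_axes(centroids), drop = TRUE])
}

#' Absolute per-axis divergence between a marine and a freshwater site
#'
#' The absolute difference of the two site centroids on one PC axis, the
#' single-axis measure of marine-freshwater morphological divergence.
#'
#' @param centroids A [site_centroids()] result.
#' @param marine,freshwater Site names.
#' @param axis Axis name (`"PC1"`) or index.
#' @return Non-negative scalar, symmetric in site order.
#' @export
axis_divergence <- function(centroids, marine, freshwater, axis = 1) {
  axes <- centroid_axes(centroids)
  ax <- if (is.numeric(axis)) {
    if (axis < 1 || axis > length(axes)) stop("unknown axis index: ", axis)
    axes[axis]
  } else {
    if (!axis %in% axes) stop("unknown axis: ", axis)
    axis
  }
  abs(centroid_row(centroids, freshwater)[ax] -
        centroid_row(centroids, marine)[ax])[[1]]
}

#' Pool all marine sites into a single panmictic reference
#'
#' Recodes every marine specimen as originating from one site
#' (`"panmictic"`), leaving freshwater rows untouched. Used to re-run the
#' divergence and parallelism analyses against a pooled marine reference.
#'
#' @param table Specimen data frame with a `habitat` column.
#' @return The same table with marine site labels replaced.
#' @export
pool_panmictic <- function(table) {
  if (!any(table$habitat == "marine"))
    stop("table contains no marine specimens")
  table$site[table$habitat == "marine"] <- "panmictic"
  table
}
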