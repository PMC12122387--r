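#' Divergence vector between a marine reference and a freshwater site
#'
#' The multivariate vector connecting the marine reference centroid to the
#' freshwater site centroid in PC space. Its Euclidean norm (`length`) is a
#' whole-morphospace measure of divergence magnitude; pairs of vectors
#' sharing a reference are compared with [theta()].
#'
#' @param centroids A [site_centroids()] result.
#' @param marine,freshwater Site names.
#' @param axes Axis names or indices to use; default all axes present in
#'   the centroids (full trait-space rotation).
#' @return Object of class `divergence_vector`: `marine`, `freshwater`,
#'   `axes`, `components` (freshwater minus marine), `length`.
#' @export
#' @examples
#' cen <- structure(data.frame(site = c("m", "f"), n = c(5L, 5L),
#'                             PC1 = c(0, 3), PC2 = c(0, 4),
#'                             check.names = FALSE),
#'                  class = c("centroid_set", "data.frame"))
#' divergence_vector(cen, "m", "f")$length  # 5
divergence_vector <- function(centroids, marine, freshwater, axes = NULL) {
  all_axes <- centroid_axes(centroids)
  if (is.null(axes)) axes <- all_axes
  if (is.numeric(axes)) axes <- all_axes[axes]
  if (anyNA(axes) || !all(axes %in% all_axes))
    stop("requested axes not present in centroids")
  comp <- centroid_row(centroids, freshwater)[axes] -
    centroid_row(centroids, marine)[axes]
  v <- list(marine = marine, freshwater = freshwater, axes = axes,
            components = comp, length = sqrt(sum(comp^2)))
  class(v) <- "divergence_vector"
  v
}

#' @export
print.divergence_vector <- function(x, digits = 4, ...) {
  cat(sprintf("divergence vector %s -> %s over %d axes: L = %s\n",
              x$marine, x$freshwater, length(x$components),
              format(x$length, digits = digits)))
  invisible(x)
}

#' Angle between two divergence vectors sharing a marine reference
#'
#' The trajectory angle theta, in degrees: the arccosine of the cosine
#' similarity of the two vectors' components, numerically clamped to
#' \[-1, 1\]. Theta near 0 indicates parallel divergence of the two
#' freshwater populations from the shared reference; 90 degrees is the null
#' expectation for unrelated directions. A zero-length vector has no
#' direction and is an error rather than a fabricated angle.
#'
#' @param v1,v2 [divergence_vector()] objects with the same marine
#'   reference and axes.
#' @return Angle in degrees in \[0, 180\].
#' @export
theta <- function(v1, v2) {
  if (!identical(v1$marine, v2$marine))
    stop("vectors must share the same marine reference")
  if (!identical(v1$axes, v2$axes))
    stop("vectors computed on different axis sets")
  if (v1$length == 0 || v2$length == 0)
    stop("theta is undefined for a zero-length vector")
  cth <- sum(v1$components * v2$components) / (v1$length * v2$length)
  acos(max(-1, min(1, cth))) * 180 / pi
}

#' All pairwise theta angles for one marine reference
#'
#' Computes [theta()] for every unordered pair of freshwater sites measured
#' against the same marine reference: `choose(k, 2)` records for `k`
#' freshwater sites.
#'
#' @param centroids A [site_centroids()] result.
#' @param marine Marine reference site name.
#' @param freshwater_sites At least two freshwater site names.
#' @param axes Axes passed to [divergence_vector()].
#' @return Data frame of class `theta_set`: `marine`, `freshwater_a`,
#'   `freshwater_b`, `theta_deg`.
#' @export
theta_set <- function(centroids, marine, freshwater_sites, axes = NULL) {
  if (length(freshwater_sites) < 2L)
    stop("need at least 2 freshwater sites")
  vecs <- lapply(freshwater_sites, function(f)
    divergence_vector(centroids, marine, f, axes = axes))
  pairs <- utils::combn(seq_along(freshwater_sites), 2)
  out <- data.frame(
    marine = marine,
    freshwater_a = freshwater_sites[pairs[1, ]],
    freshwater_b = freshwater_sites[pairs[2, ]],
    theta_deg = apply(pairs, 2, function(ij) theta(vecs[[ij[1]]],
                                                   vecs[[ij[2]]])),
    stringsAsFactors = FALSE)
  class(out) <- c("theta_set", "data.frame")
  out
}

#' Theta summaries per marine reference
#'
#' @param thetas A `theta_set` data frame (possibly concatenated over
#'   references).
#' @return Data frame: `marine`, `n_pairs`, `mean_theta`, `min_theta`,
#'   `max_theta`.
#' @export
theta_summary <- function(thetas) {
  refs <- unique(thetas$marine)
  out <- do.call(rbind, lapply(refs, function(r) {
    th <- thetas$theta_deg[thetas$marine == r]
    data.frame(marine = r, n_pairs = length(th), mean_theta = mean(th),
               min_theta = min(th), max_theta = max(th),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Divergence estimates for every marine-freshwater pair
#'
#' Tabulates, for each (marine reference, freshwater site) pair, either the
#' absolute single-axis centroid difference (`metric = "pc_axis_diff"`,
#' default axis PC1) or the multivariate vector length
#' (`metric = "vector_length"` over `axes`).
#'
#' @param centroids A [site_centroids()] result.
#' @param marine_sites,freshwater_sites Site name vectors.
#' @param metric `"pc_axis_diff"` or `"vector_length"`.
#' @param axis Axis for `pc_axis_diff`.
#' @param axes Axis set for `vector_length` (default all).
#' @return Data frame: `freshwater`, `marine`, `metric`, `value`.
#' @export
divergence_estimates <- function(centroids, marine_sites, freshwater_sites,
                                 metric = c("pc_axis_diff", "vector_length"),
                                 axis = 1, axes = NULL) {
  metric <- match.arg(metric)
  grid <- expand.grid(freshwater = freshwater_sites, marine = marine_sites,
                      stringsAsFactors = FALSE)
  grid$metric <- metric
  grid$value <- vapply(seq_len(nrow(grid)), function(i) {
    if (metric == "pc_axis_diff")
      axis_divergence(centroids, grid$marine[i], grid$freshwater[i], axis)
    else
      divergence_vector(centroids, grid$marine[i], grid$freshwater[i],
                        axes = axes)$length
  }, numeric(1))
  grid
}
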