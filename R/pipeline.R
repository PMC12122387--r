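# CSV writer with numerics at 12 significant digits so that re-runs under
# the same seed produce byte-identical files.
write_csv12 <- function(x, path) {
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- formatC(x[[j]], digits = 12,
                                             format = "g")
  }
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

matrix_to_df <- function(m, rowname_col) {
  d <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                  stringsAsFactors = FALSE, check.names = FALSE)
  colnames(d)[1] <- rowname_col
  d
}

# Fork reproducible module seeds from the run seed.
fork_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Configuration of a full pipeline run
#'
#' Collects every setting of [run_pipeline()]: the data source (a
#' [sim_config()] for synthetic data, or CSV paths for real tables), the
#' preprocessing, morphospace, vector and model options, the geographic
#' distance settings, the output directory and the run seed.
#'
#' @param sim A [sim_config()]; ignored when `specimens_csv` is given.
#' @param specimens_csv,metadata_csv,climate_csv Optional input CSV paths
#'   (specimen table; site metadata with `site`, `habitat`, `latitude`,
#'   `longitude`; site-level climate table).
#' @param raster_path Optional ESRI ASCII grid of the water mask (see
#'   [read_ascii_grid()]); when absent an all-water raster covering the
#'   site bounding box is generated.
#' @param allometry_grouping `"per_population"` or `"common"`.
#' @param exempt_plates_globally Passed to [size_correct()].
#' @param levene_center `"median"` or `"mean"`.
#' @param pca_scale Correlation- (`TRUE`) vs covariance-matrix PCA.
#' @param divergence_axis Axis for single-axis divergence (default 1).
#' @param vector_axes Axis indices for multivariate vectors; `NULL` = all.
#' @param percent_normalize Denominator for percent change (`"max"`,
#'   `"min"`, `"mean"`).
#' @param n_perm Permutations for the reference-effect calibration (0 =
#'   analytic F only).
#' @param resolution_km,snap_cells,connectivity Water-raster settings.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer run seed; forked once per stochastic module.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       specimens_csv = NULL, metadata_csv = NULL,
                       climate_csv = NULL, raster_path = NULL,
                       allometry_grouping = c("per_population", "common"),
                       exempt_plates_globally = FALSE,
                       levene_center = c("median", "mean"),
                       pca_scale = TRUE,
                       divergence_axis = 1,
                       vector_axes = NULL,
                       percent_normalize = c("max", "min", "mean"),
                       n_perm = 0,
                       resolution_km = 2, snap_cells = 3, connectivity = 8,
                       out_dir = NULL, seed = 1L) {
  cfg <- list(sim = sim, specimens_csv = specimens_csv,
              metadata_csv = metadata_csv, climate_csv = climate_csv,
              raster_path = raster_path,
              allometry_grouping = match.arg(allometry_grouping),
              exempt_plates_globally = isTRUE(exempt_plates_globally),
              levene_center = match.arg(levene_center),
              pca_scale = isTRUE(pca_scale),
              divergence_axis = divergence_axis,
              vector_axes = vector_axes,
              percent_normalize = match.arg(percent_normalize),
              n_perm = as.integer(n_perm),
              resolution_km = resolution_km, snap_cells = snap_cells,
              connectivity = connectivity,
              out_dir = out_dir, seed = as.integer(seed))
  if (!is.null(specimens_csv) && is.null(metadata_csv))
    stop("metadata_csv is required when specimens_csv is given")
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full divergence/parallelism analysis
#'
#' Executes the whole analysis end-to-end: data simulation (or loading),
#' allometric size correction and variance screening, morphospace PCA with
#' site centroids, per-reference and panmictic divergence estimates
#' (single-axis and vector length), pairwise theta angles, the
#' marine-reference effect tests, percent-change summaries, waterway
#' distances, climate pruning and environmental differences, and the
#' distance-decay mixed models (marine-only models are ordinary
#' regressions). Any stage failure aborts with the stage name. Re-running
#' with an identical configuration reproduces every numeric output.
#'
#' @param config A [run_config()].
#' @return Object of class `refdiv` collecting all stage outputs; see
#'   [summary.refdiv()].
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 7))
#' summary(res)
#' }
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  seeds <- fork_seeds(config$seed, 4L)

  dat <- stage("data", {
    if (!is.null(config$specimens_csv)) {
      specimens <- utils::read.csv(config$specimens_csv,
                                   stringsAsFactors = FALSE,
                                   check.names = FALSE)
      metadata <- utils::read.csv(config$metadata_csv,
                                  stringsAsFactors = FALSE)
      list(specimens = specimens, metadata = metadata, truth = NULL)
    } else {
      sim <- config$sim
      sim$seed <- seeds[1]
      generate_specimens(sim)
    }
  })
  specimens <- dat$specimens
  metadata <- dat$metadata
  marine_sites <- metadata$site[metadata$habitat == "marine"]
  freshwater_sites <- metadata$site[metadata$habitat == "freshwater"]

  pre <- stage("preprocess", {
    fits <- fit_allometry(specimens, grouping = config$allometry_grouping)
    corrected <- size_correct(
      specimens, fits,
      exempt_plates_globally = config$exempt_plates_globally)
    levene <- levene_by_trait(corrected, center = config$levene_center)
    list(fits = fits, corrected = corrected, levene = levene)
  })

  morpho <- stage("morphospace", {
    pca <- run_pca(pre$corrected, scale = config$pca_scale)
    pca <- orient_to_habitat(pca, axes = 1)
    centroids <- site_centroids(pca, metadata = metadata)
    # panmictic analysis reuses the same scores with marine rows relabeled
    pan <- pca
    pan$sites[pan$habitats == "marine"] <- "panmictic"
    pan_centroids <- site_centroids(pan)
    list(pca = pca, centroids = centroids, pan_centroids = pan_centroids)
  })

  vec <- stage("vectors", {
    div_pc1 <- divergence_estimates(morpho$centroids, marine_sites,
                                    freshwater_sites, "pc_axis_diff",
                                    axis = config$divergence_axis)
    div_len <- divergence_estimates(morpho$centroids, marine_sites,
                                    freshwater_sites, "vector_length",
                                    axes = config$vector_axes)
    thetas <- do.call(rbind, lapply(marine_sites, function(m)
      theta_set(morpho$centroids, m, freshwater_sites,
                axes = config$vector_axes)))
    pan_div_pc1 <- divergence_estimates(morpho$pan_centroids, "panmictic",
                                        freshwater_sites, "pc_axis_diff",
                                        axis = config$divergence_axis)
    pan_div_len <- divergence_estimates(morpho$pan_centroids, "panmictic",
                                        freshwater_sites, "vector_length",
                                        axes = config$vector_axes)
    pan_thetas <- theta_set(morpho$pan_centroids, "panmictic",
                            freshwater_sites, axes = config$vector_axes)
    list(div_pc1 = div_pc1, div_len = div_len, thetas = thetas,
         theta_summary = theta_summary(thetas),
         pan_div_pc1 = pan_div_pc1, pan_div_len = pan_div_len,
         pan_thetas = pan_thetas)
  })

  mods <- stage("models", {
    ref_pc1 <- reference_effect_test(vec$div_pc1, n_perm = config$n_perm,
                                     perm_seed = seeds[3])
    ref_len <- reference_effect_test(vec$div_len, n_perm = config$n_perm,
                                     perm_seed = seeds[4])
    th <- vec$thetas
    th_d <- data.frame(freshwater = paste(th$freshwater_a, th$freshwater_b,
                                          sep = " x "),
                       marine = th$marine, value = th$theta_deg,
                       stringsAsFactors = FALSE)
    ref_theta <- reference_effect_test(th_d)
    pct <- percent_change_by_reference(vec$div_pc1,
                                       normalize = config$percent_normalize)
    list(ref_pc1 = ref_pc1, ref_len = ref_len, ref_theta = ref_theta,
         percent_change = pct)
  })

  geo <- stage("geo_env", {
    xy <- lonlat_to_km(metadata)
    rownames(xy) <- metadata$site
    raster <- if (!is.null(config$raster_path)) {
      read_ascii_grid(config$raster_path)
    } else {
      pad <- 4 * config$resolution_km
      rng_x <- range(xy[, "x"]); rng_y <- range(xy[, "y"])
      shape <- c(ceiling(diff(rng_y) / config$resolution_km) + 8L,
                 ceiling(diff(rng_x) / config$resolution_km) + 8L)
      generate_water_raster(shape, resolution_km = config$resolution_km,
                            origin = c(rng_x[1] - pad, rng_y[1] - pad))
    }
    dists <- waterway_distance_matrix(raster, xy,
                                      snap_cells = config$snap_cells,
                                      connectivity = config$connectivity)
    climate <- if (!is.null(config$climate_csv))
      utils::read.csv(config$climate_csv, stringsAsFactors = FALSE)
    else generate_climate(metadata, seed = seeds[2])
    retained <- prune_climate_variables(climate)
    env <- environment_difference(climate, retained, axes = 1:3)
    list(raster = raster, xy = xy, distances_km = dists, climate = climate,
         retained = retained, env = env)
  })

  decay <- stage("distance_decay", {
    d <- vec$div_pc1
    d$distance_km <- geo$distances_km[cbind(d$marine, d$freshwater)]
    ed <- geo$env$differences
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(d$marine, d$freshwater), key(ed$site_a, ed$site_b))
    d$env_dPC1 <- ed$dPC1[m]; d$env_dPC2 <- ed$dPC2[m]
    dist_fit <- fit_lmm(d, "value", "distance_km",
                        random_intercept = "freshwater")
    env_fit <- fit_lmm(d, "value", "env_dPC2",
                       random_intercept = "freshwater")
    # marine-only: pairwise |PC1 difference| among marine sites, plain OLS
    mm <- t(utils::combn(marine_sites, 2))
    pc1 <- stats::setNames(
      centroid_row_all(morpho$centroids, "PC1"), morpho$centroids$site)
    md <- data.frame(site_a = mm[, 1], site_b = mm[, 2],
                     value = abs(pc1[mm[, 1]] - pc1[mm[, 2]]),
                     distance_km = geo$distances_km[mm],
                     stringsAsFactors = FALSE)
    m2 <- match(key(md$site_a, md$site_b), key(ed$site_a, ed$site_b))
    md$env_dPC1 <- ed$dPC1[m2]; md$env_dPC2 <- ed$dPC2[m2]
    marine_dist_fit <- fit_lmm(md, "value", "distance_km")
    marine_env1_fit <- fit_lmm(md, "value", "env_dPC1")
    marine_env2_fit <- fit_lmm(md, "value", "env_dPC2")
    list(pairs = d, marine_pairs = md, dist_fit = dist_fit,
         env_fit = env_fit, marine_dist_fit = marine_dist_fit,
         marine_env1_fit = marine_env1_fit,
         marine_env2_fit = marine_env2_fit)
  })

  res <- list(config = config, seeds = seeds, specimens = specimens,
              metadata = metadata, truth = dat$truth,
              preprocess = pre, morphospace = morpho, vectors = vec,
              models = mods, geo = geo, decay = decay)
  class(res) <- "refdiv"
  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

centroid_row_all <- function(centroids, axis) {
  unlist(centroids[, axis, drop = TRUE])
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_csv12(res$preprocess$corrected, p("corrected_specimens.csv"))
  write_csv12(attr(res$preprocess$corrected, "audit"),
              p("allometry_audit.csv"))
  write_csv12(res$preprocess$levene, p("levene.csv"))
  write_csv12(matrix_to_df(res$morphospace$pca$loadings, "trait"),
              p("pca_loadings.csv"))
  write_csv12(data.frame(axis = seq_along(res$morphospace$pca$pct_variance),
                         pct_variance = res$morphospace$pca$pct_variance),
              p("pca_pct_variance.csv"))
  write_csv12(res$morphospace$centroids, p("centroids.csv"))
  write_csv12(res$morphospace$pan_centroids, p("centroids_panmictic.csv"))
  write_csv12(res$vectors$div_pc1, p("divergence_pc1.csv"))
  write_csv12(res$vectors$div_len, p("divergence_vector_length.csv"))
  write_csv12(res$vectors$thetas, p("theta.csv"))
  write_csv12(res$vectors$theta_summary, p("theta_summary.csv"))
  write_csv12(res$vectors$pan_div_pc1, p("divergence_pc1_panmictic.csv"))
  write_csv12(res$vectors$pan_div_len,
              p("divergence_vector_length_panmictic.csv"))
  write_csv12(res$vectors$pan_thetas, p("theta_panmictic.csv"))
  write_csv12(res$models$percent_change, p("percent_change.csv"))
  write_csv12(matrix_to_df(res$geo$distances_km, "site"),
              p("distances_km.csv"))
  write_csv12(res$geo$climate, p("climate.csv"))
  writeLines(res$geo$retained, p("climate_retained.txt"))
  write_csv12(res$geo$env$differences, p("environment_differences.csv"))
  write_csv12(res$decay$pairs, p("distance_decay_pairs.csv"))
  model_lines <- utils::capture.output({
    cat("== marine reference effect on PC1 divergence ==\n")
    print(res$models$ref_pc1)
    cat("\n== marine reference effect on vector length ==\n")
    print(res$models$ref_len)
    cat("\n== marine reference effect on theta ==\n")
    print(res$models$ref_theta)
    cat("\n== divergence ~ waterway distance ==\n")
    print(res$decay$dist_fit)
    cat("\n== divergence ~ environmental PC2 difference ==\n")
    print(res$decay$env_fit)
    cat("\n== marine-only models ==\n")
    print(res$decay$marine_dist_fit)
    print(res$decay$marine_env1_fit)
    print(res$decay$marine_env2_fit)
  })
  writeLines(model_lines, p("models.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("refdiv")),
    r_version = R.version.string,
    seed = res$config$seed,
    module_seeds = res$seeds,
    settings = res$config[setdiff(names(res$config), "sim")],
    n_specimens = nrow(res$specimens),
    n_sites = nrow(res$metadata))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.refdiv <- function(x, ...) {
  cat(sprintf("refdiv analysis: %d specimens, %d marine + %d freshwater sites\n",
              nrow(x$specimens), sum(x$metadata$habitat == "marine"),
              sum(x$metadata$habitat == "freshwater")))
  cat(sprintf("PC1 explains %.1f%% of trait variance\n",
              x$morphospace$pca$pct_variance[1]))
  cat(sprintf("mean theta %.1f deg (range %.1f-%.1f)\n",
              mean(x$vectors$thetas$theta_deg),
              min(x$vectors$thetas$theta_deg),
              max(x$vectors$thetas$theta_deg)))
  cat("use summary() for reference-effect and distance-decay results\n")
  invisible(x)
}

#' Summarise a pipeline run
#'
#' Prints the headline quantities of the analysis: variance explained by
#' the leading axes, the range of per-reference mean divergence, the
#' percent change under reference substitution, theta summaries, the
#' marine-reference effect tests, and the distance-decay fits.
#'
#' @param object A `refdiv` object.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.refdiv <- function(object, ...) {
  x <- object
  pv <- x$morphospace$pca$pct_variance
  cat("Morphospace PCA: PC1", sprintf("%.1f%%,", pv[1]),
      "PC2", sprintf("%.1f%%,", pv[2]),
      "PC3", sprintf("%.1f%%\n", pv[3]))
  per_ref <- tapply(x$vectors$div_pc1$value, x$vectors$div_pc1$marine, mean)
  cat(sprintf("Per-reference mean PC1 divergence: %.2f-%.2f\n",
              min(per_ref), max(per_ref)))
  pc <- x$models$percent_change$percent_change
  cat(sprintf("Percent change under reference substitution: %.0f%%-%.0f%%\n",
              min(pc, na.rm = TRUE), max(pc, na.rm = TRUE)))
  th <- x$vectors$thetas$theta_deg
  cat(sprintf("Theta: mean %.0f deg (range %.0f-%.0f); per-reference means %.0f-%.0f\n",
              mean(th), min(th), max(th),
              min(x$vectors$theta_summary$mean_theta),
              max(x$vectors$theta_summary$mean_theta)))
  cat(sprintf("Reference effect on PC1 divergence: SS = %.2f, F(%d, %d) = %.2f, p = %s\n",
              x$models$ref_pc1$marine_SS, x$models$ref_pc1$marine_df,
              x$models$ref_pc1$anova$df_den[1], x$models$ref_pc1$marine_F,
              format.pval(x$models$ref_pc1$anova$p[1], digits = 3)))
  cat(sprintf("Reference effect on vector length: SS = %.2f, F = %.2f\n",
              x$models$ref_len$marine_SS, x$models$ref_len$marine_F))
  b <- x$decay$dist_fit$coefficients
  cat(sprintf("Divergence ~ distance: beta = %.3g (SE %.2g), t = %.2f\n",
              b["distance_km", "Estimate"], b["distance_km", "Std. Error"],
              b["distance_km", "t value"]))
  b2 <- x$decay$env_fit$coefficients
  cat(sprintf("Divergence ~ env PC2 difference: beta = %.3g (SE %.2g), t = %.2f\n",
              b2["env_dPC2", "Estimate"], b2["env_dPC2", "Std. Error"],
              b2["env_dPC2", "t value"]))
  invisible(object)
}

#' Plot a pipeline run
#'
#' Two-panel base-graphics display: site centroids in PC1/PC2 morphospace
#' with divergence vectors from one marine reference, and per-reference
#' boxplots of single-axis divergence (including the panmictic reference).
#'
#' @param x A `refdiv` object.
#' @param reference Marine reference to draw vectors from (default first).
#' @param ... Unused.
#' @export
plot.refdiv <- function(x, reference = NULL, ...) {
  cen <- x$morphospace$centroids
  hab <- x$metadata$habitat[match(cen$site, x$metadata$site)]
  if (is.null(reference))
    reference <- x$metadata$site[x$metadata$habitat == "marine"][1]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(cen$PC1, cen$PC2, pch = ifelse(hab == "marine", 19, 17),
                 col = ifelse(hab == "marine", "steelblue", "firebrick"),
                 xlab = "PC1", ylab = "PC2", main = "Site centroids")
  ref <- cen[cen$site == reference, ]
  fw <- cen[hab == "freshwater", ]
  graphics::arrows(ref$PC1, ref$PC2, fw$PC1, fw$PC2, length = 0.08,
                   col = "grey40")
  graphics::legend("topleft", pch = c(19, 17),
                   col = c("steelblue", "firebrick"),
                   legend = c("marine", "freshwater"), bty = "n")
  d <- x$vectors$div_pc1
  dp <- x$vectors$pan_div_pc1
  graphics::boxplot(c(split(d$value, d$marine),
                      list(panmictic = dp$value)),
                    las = 2, ylab = "PC1 divergence",
                    main = "Divergence by marine reference",
                    cex.axis = 0.6)
  invisible(x)
}
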