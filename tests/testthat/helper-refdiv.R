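# Small, fast simulation design used across tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_marine_sites = 4, n_freshwater_sites = 3, n_per_site = 20,
             seed = seed, ...)
}

# One-way ANOVA F computed from first principles (group/residual sums of
# squares), used as the independent oracle for the Levene test.
anova_F_oracle <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  n_g <- tapply(values, groups, length)
  ss_between <- sum(n_g * (means - gm)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ss_between / df1) / (ss_within / df2)
}

# Brute-force shortest water path by exhaustive enumeration of simple paths
# (8-connected, diagonal cost sqrt(2) * cell). Only viable on tiny grids.
brute_force_water_distance <- function(water, from, to, cell_km = 1) {
  nr <- nrow(water); nc <- ncol(water)
  best <- Inf
  visit <- function(r, c, dist, seen) {
    if (dist >= best) return()
    if (r == to[1] && c == to[2]) {
      best <<- min(best, dist)
      return()
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!water[r2, c2] || seen[r2, c2]) next
      seen[r2, c2] <- TRUE
      step <- if (dr != 0 && dc != 0) sqrt(2) * cell_km else cell_km
      visit(r2, c2, dist + step, seen)
      seen[r2, c2] <- FALSE
    }
  }
  seen <- matrix(FALSE, nr, nc)
  seen[from[1], from[2]] <- TRUE
  visit(from[1], from[2], 0, seen)
  best
}

# Centre coordinates (km) of a cell, for feeding waterway_distance.
cell_xy <- function(raster, row, col) {
  nr <- nrow(raster$water)
  c(raster$origin[1] + (col - 0.5) * raster$cell_km,
    raster$origin[2] + (nr - row + 0.5) * raster$cell_km)
}

# Synthetic specimens -> centroid set (the common front half of the
# analysis), used by vector/model tests.
centroids_from_sim <- function(sim, scale = TRUE) {
  fits <- fit_allometry(sim$specimens)
  corr <- size_correct(sim$specimens, fits)
  pca <- orient_to_habitat(run_pca(corr, scale = scale))
  site_centroids(pca, metadata = sim$metadata)
}

# Minimal hand-built centroid set.
make_centroids <- function(sites, coords, n = 5L) {
  coords <- as.matrix(coords)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  out <- data.frame(site = sites, n = n, coords,
                    stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("centroid_set", "data.frame")
  out
}

# Null divergence table: per-lake level plus iid noise, no reference effect.
null_divergence_table <- function(n_refs, n_lakes, sd_lake = 1, sd_noise = 0.3) {
  d <- expand.grid(freshwater = paste0("lake_", seq_len(n_lakes)),
                   marine = paste0("ref_", seq_len(n_refs)),
                   stringsAsFactors = FALSE)
  lake_eff <- stats::rnorm(n_lakes, 0, sd_lake)
  names(lake_eff) <- paste0("lake_", seq_len(n_lakes))
  d$value <- lake_eff[d$freshwater] + stats::rnorm(nrow(d), 0, sd_noise)
  d
}
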