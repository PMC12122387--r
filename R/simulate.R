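#' Configuration for the synthetic morphometric data generator
#'
#' Bundles and validates every parameter of the hierarchical trait model used
#' by [generate_specimens()]. The model is Gaussian with linear allometry:
#' each site draws a site-level mean per trait (marine baseline plus a
#' spatial trend plus among-site jitter; freshwater sites additionally get a
#' shared parallel offset plus a site-specific non-parallel deviation), and
#' each fish draws its trait value around the site mean with an allometric
#' regression on standard length. Count traits are rounded to the nearest
#' non-negative integer so that the configured variances are honoured.
#'
#' @param n_marine_sites,n_freshwater_sites Number of sites per habitat.
#' @param n_per_site Integer vector of per-site sample sizes (recycled), or
#'   `NULL` to use the default study layout (20-60 fish per site for the
#'   10 marine + 6 freshwater design, otherwise 30 per site).
#' @param traits Trait definition table as returned by
#'   [stickleback_traits()]; supplies per-trait means, SDs, offsets and
#'   allometric slopes unless overridden by the arguments below.
#' @param trait_means_marine,trait_means_freshwater Named or positional
#'   per-trait expected values. Freshwater means default to the marine means;
#'   the habitat contrast is carried by `parallel_effect`.
#' @param trait_sds Per-trait within-site SDs: a vector (shared by habitat)
#'   or a 2-row matrix with rows `marine` and `freshwater`.
#' @param allometric_slopes Per-trait slope of trait on standard length
#'   (trait units per mm).
#' @param length_mean_mm,length_sd_mm Standard-length distribution (mm).
#' @param among_site_sd Per-trait SD of the site-level mean jitter.
#' @param parallel_effect Per-trait offset applied identically to every
#'   freshwater site (the shared direction of freshwater divergence).
#' @param nonparallel_sd Per-trait SD of the site-specific deviation of the
#'   freshwater offset; 0 makes all freshwater sites diverge in exactly the
#'   same expected direction.
#' @param freshwater_site_offsets Optional `n_freshwater_sites x n_traits`
#'   matrix of explicit site-specific deviations, overriding the random
#'   `nonparallel_sd` draw (useful for constructing known trajectory
#'   geometries such as mutually orthogonal divergence directions).
#' @param spatial_range_km Range (km) of the exponential spatial
#'   autocorrelation of site-level trait means: the among-site jitter is a
#'   Gaussian field with correlation `exp(-d / spatial_range_km)` between
#'   sites `d` km apart, so nearby sites have similar means and divergence
#'   between a freshwater site and a marine reference tends to grow with
#'   their separation (distance decay). `0` gives independent site jitter.
#' @param seed Integer seed; every draw is reproducible given the seed.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_specimens()], [generate_climate()],
#'   [generate_water_raster()]
#' @export
sim_config <- function(n_marine_sites = 10L,
                       n_freshwater_sites = 6L,
                       n_per_site = NULL,
                       traits = stickleback_traits(),
                       trait_means_marine = traits$marine_mean,
                       trait_means_freshwater = trait_means_marine,
                       trait_sds = rbind(marine = traits$marine_sd,
                                         freshwater = traits$freshwater_sd),
                       allometric_slopes = traits$allometric_slope,
                       length_mean_mm = 50.71,
                       length_sd_mm = 6,
                       among_site_sd = 0.8 * traits$marine_sd,
                       parallel_effect = traits$freshwater_offset,
                       nonparallel_sd = 0.8 * traits$freshwater_sd,
                       freshwater_site_offsets = NULL,
                       spatial_range_km = 120,
                       seed = 1L) {
  n_marine_sites <- as.integer(n_marine_sites)
  n_freshwater_sites <- as.integer(n_freshwater_sites)
  if (n_marine_sites < 1L || n_freshwater_sites < 1L)
    stop("site counts must be >= 1")
  n_traits <- nrow(traits)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_traits)
    if (length(x) != n_traits)
      stop(sprintf("'%s' must have length 1 or %d", what, n_traits))
    as.numeric(x)
  }
  if (is.matrix(trait_sds)) {
    if (!all(c("marine", "freshwater") %in% rownames(trait_sds)))
      stop("matrix 'trait_sds' needs rows 'marine' and 'freshwater'")
    sds <- rbind(marine = expand(trait_sds["marine", ], "trait_sds"),
                 freshwater = expand(trait_sds["freshwater", ], "trait_sds"))
  } else {
    s <- expand(trait_sds, "trait_sds")
    sds <- rbind(marine = s, freshwater = s)
  }
  cfg <- list(
    n_marine_sites = n_marine_sites,
    n_freshwater_sites = n_freshwater_sites,
    n_per_site = n_per_site,
    traits = traits,
    trait_means_marine = expand(trait_means_marine, "trait_means_marine"),
    trait_means_freshwater = expand(trait_means_freshwater,
                                    "trait_means_freshwater"),
    trait_sds = sds,
    allometric_slopes = expand(allometric_slopes, "allometric_slopes"),
    length_mean_mm = as.numeric(length_mean_mm),
    length_sd_mm = as.numeric(length_sd_mm),
    among_site_sd = expand(among_site_sd, "among_site_sd"),
    parallel_effect = expand(parallel_effect, "parallel_effect"),
    nonparallel_sd = expand(nonparallel_sd, "nonparallel_sd"),
    freshwater_site_offsets = freshwater_site_offsets,
    spatial_range_km = as.numeric(spatial_range_km),
    seed = as.integer(seed)
  )
  if (any(cfg$trait_sds < 0) || any(cfg$among_site_sd < 0) ||
      any(cfg$nonparallel_sd < 0) || cfg$length_sd_mm < 0 ||
      cfg$spatial_range_km < 0)
    stop("standard deviations must be >= 0")
  if (cfg$length_mean_mm <= 0) stop("length_mean_mm must be positive")
  if (!is.null(n_per_site)) {
    n_sites <- n_marine_sites + n_freshwater_sites
    n_per_site <- as.integer(n_per_site)
    if (any(n_per_site < 2L)) stop("n_per_site must be >= 2")
    cfg$n_per_site <- rep_len(n_per_site, n_sites)
  }
  if (!is.null(freshwater_site_offsets)) {
    m <- as.matrix(freshwater_site_offsets)
    if (nrow(m) != n_freshwater_sites || ncol(m) != n_traits)
      stop("freshwater_site_offsets must be n_freshwater_sites x n_traits")
    cfg$freshwater_site_offsets <- m
  }
  class(cfg) <- "sim_config"
  cfg
}

# Site table (name, habitat, n, lat, lon) for a config. Uses the default
# study layout when the requested design matches it, otherwise generates
# sites on a coastal-BC-like coordinate box.
sim_sites <- function(config) {
  layout <- default_site_layout()
  if (config$n_marine_sites == 10L && config$n_freshwater_sites == 6L) {
    sites <- layout
  } else {
    nm <- config$n_marine_sites
    nf <- config$n_freshwater_sites
    sites <- data.frame(
      site = c(sprintf("marine_%02d", seq_len(nm)),
               sprintf("freshwater_%02d", seq_len(nf))),
      habitat = c(rep("marine", nm), rep("freshwater", nf)),
      n = 30L,
      latitude = 48.3 + 2.4 * seq(0, 1, length.out = nm + nf),
      longitude = -127.5 + 5 * rep_len(c(0.1, 0.8, 0.4, 0.6, 0.25, 0.9),
                                       nm + nf),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(config$n_per_site)) sites$n <- config$n_per_site
  sites
}

#' Generate a synthetic specimen table with known ground truth
#'
#' Draws a specimen-level morphometric table from the hierarchical Gaussian
#' model described in [sim_config()]. Site means are drawn once per site;
#' fish-level noise is independent. Each fish's trait value is
#' `site mean + allometric_slope * (standard_length - length_mean_mm) +
#' noise`; count traits are rounded to the nearest non-negative integer.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{specimens}{Data frame, one row per fish: `fish_id`, `site`,
#'     `habitat`, `standard_length`, and one column per trait.}
#'   \item{metadata}{Data frame of site metadata: `site`, `habitat`, `n`,
#'     `latitude`, `longitude`.}
#'   \item{truth}{List with the realized `site_means` (site x trait matrix),
#'     `freshwater_offsets` (true divergence direction per freshwater site,
#'     parallel effect plus site deviation), and `expected_theta_deg`
#'     (pairwise angles between the configured freshwater offsets, measured
#'     in marine-SD-standardised trait space).}
#' }
#' @export
#' @examples
#' out <- generate_specimens(sim_config(seed = 42))
#' dim(out$specimens)
generate_specimens <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object")
  sites <- sim_sites(config)
  traits <- config$traits
  n_traits <- nrow(traits)
  set.seed(config$seed)

  # site-level means: among-site jitter is a spatially autocorrelated
  # Gaussian field (exponential kernel), one independent field per trait
  xy <- lonlat_to_km(sites)
  d_km <- as.matrix(stats::dist(xy))
  R <- if (config$spatial_range_km > 0) exp(-d_km / config$spatial_range_km)
       else diag(nrow(sites))
  cR <- chol(R + 1e-10 * diag(nrow(sites)))
  site_dev <- crossprod(cR, matrix(stats::rnorm(nrow(sites) * n_traits),
                                   nrow(sites), n_traits))
  site_dev <- sweep(site_dev, 2, config$among_site_sd, "*")
  site_means <- matrix(NA_real_, nrow(sites), n_traits,
                       dimnames = list(sites$site, traits$trait))
  fw_idx <- which(sites$habitat == "freshwater")
  fw_offsets <- matrix(0, length(fw_idx), n_traits,
                       dimnames = list(sites$site[fw_idx], traits$trait))
  for (i in seq_len(nrow(sites))) {
    base <- if (sites$habitat[i] == "marine") config$trait_means_marine
            else config$trait_means_freshwater
    site_means[i, ] <- base + site_dev[i, ]
  }
  for (k in seq_along(fw_idx)) {
    dev <- if (!is.null(config$freshwater_site_offsets))
      config$freshwater_site_offsets[k, ]
    else stats::rnorm(n_traits, 0, config$nonparallel_sd)
    fw_offsets[k, ] <- config$parallel_effect + dev
    site_means[fw_idx[k], ] <- site_means[fw_idx[k], ] + fw_offsets[k, ]
  }

  # fish-level draws
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    n <- sites$n[i]
    len <- stats::rnorm(n, config$length_mean_mm, config$length_sd_mm)
    sd_i <- config$trait_sds[sites$habitat[i], ]
    vals <- matrix(NA_real_, n, n_traits)
    for (t in seq_len(n_traits)) {
      x <- site_means[i, t] +
        config$allometric_slopes[t] * (len - config$length_mean_mm) +
        stats::rnorm(n, 0, sd_i[t])
      if (traits$type[t] == "count") x <- pmax(0, round(x))
      vals[, t] <- x
    }
    colnames(vals) <- traits$trait
    rows[[i]] <- data.frame(site = sites$site[i], habitat = sites$habitat[i],
                            standard_length = len, vals,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  specimens <- do.call(rbind, rows)
  specimens <- cbind(fish_id = sprintf("fish_%04d", seq_len(nrow(specimens))),
                     specimens)
  rownames(specimens) <- NULL

  # expected pairwise angles between configured offsets, in trait space
  # standardised by marine within-site SD (the scale the morphospace PCA
  # effectively works on)
  std <- sweep(fw_offsets, 2, config$trait_sds["marine", ], "/")
  nf <- nrow(std)
  expected_theta <- matrix(NA_real_, nf, nf,
                           dimnames = list(rownames(std), rownames(std)))
  for (a in seq_len(nf)) for (b in seq_len(nf)) {
    na_ <- sqrt(sum(std[a, ]^2)); nb_ <- sqrt(sum(std[b, ]^2))
    if (na_ > 0 && nb_ > 0) {
      cth <- sum(std[a, ] * std[b, ]) / (na_ * nb_)
      expected_theta[a, b] <- acos(max(-1, min(1, cth))) * 180 / pi
    }
  }
  list(
    specimens = specimens,
    metadata = sites,
    truth = list(site_means = site_means,
                 freshwater_offsets = fw_offsets,
                 expected_theta_deg = expected_theta)
  )
}

# Canonical bioclim variable codes BIO01..BIO19.
bioclim_codes <- function() sprintf("BIO%02d", 1:19)

#' Generate a synthetic site-level bioclimatic table
#'
#' Builds 19 bioclim-style variables per site from three latent factors plus
#' variable-specific noise. Temperature variables (BIO01, BIO05, BIO06,
#' BIO08-BIO11) load on a latitude-driven factor, precipitation variables
#' (BIO12-BIO14, BIO16-BIO19) on a longitude-driven factor, and
#' seasonality/range variables (BIO02-BIO04, BIO07, BIO15) on an independent
#' factor. Within each block the noise is small enough that several pairs
#' exceed |r| = 0.80, so correlation pruning is always triggered.
#'
#' @param metadata Site metadata with columns `site`, `latitude`,
#'   `longitude`.
#' @param seed Integer seed.
#' @return Data frame: `site` plus columns `BIO01`..`BIO19`.
#' @export
generate_climate <- function(metadata, seed = 1L) {
  if (is.null(metadata) || nrow(metadata) == 0L)
    stop("metadata must contain at least one site")
  if (!all(c("site", "latitude", "longitude") %in% colnames(metadata)))
    stop("metadata needs columns site, latitude, longitude")
  set.seed(as.integer(seed))
  n <- nrow(metadata)
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                   else rep(0, length(x))
  f_temp <- z(metadata$latitude) + stats::rnorm(n, 0, 0.3)
  f_prec <- z(metadata$longitude) + stats::rnorm(n, 0, 0.3)
  f_seas <- stats::rnorm(n)

  # per-variable: latent factor, loading, mean level, scale, noise sd
  spec <- list(
    BIO01 = list(f_temp, -1.0, 9.0, 1.2, 0.15),   # annual mean temp, C
    BIO02 = list(f_seas,  1.0, 7.5, 0.8, 0.15),   # mean diurnal range
    BIO03 = list(f_seas,  0.9, 45,  3.0, 0.20),   # isothermality, %
    BIO04 = list(f_seas,  1.0, 480, 40,  0.20),   # temp seasonality
    BIO05 = list(f_temp, -1.0, 22,  1.5, 0.12),   # max temp warmest month
    BIO06 = list(f_temp, -1.0, -1,  1.5, 0.12),   # min temp coldest month
    BIO07 = list(f_seas,  1.0, 23,  1.5, 0.25),   # annual temp range
    BIO08 = list(f_temp, -0.5, 4.0, 1.0, 0.90),   # mean temp wettest qtr
    BIO09 = list(f_temp, -1.0, 15,  1.5, 0.20),   # mean temp driest qtr
    BIO10 = list(f_temp, -1.0, 16,  1.2, 0.12),   # mean temp warmest qtr
    BIO11 = list(f_temp, -1.0, 3.5, 1.2, 0.12),   # mean temp coldest qtr
    BIO12 = list(f_prec, -1.0, 1800, 350, 0.15),  # annual precipitation, mm
    BIO13 = list(f_prec, -1.0, 300, 60,  0.18),   # precip wettest month
    BIO14 = list(f_prec, -1.0, 35,  12,  0.30),   # precip driest month
    BIO15 = list(f_seas, -0.6, 60,  8,   0.90),   # precip seasonality, %
    BIO16 = list(f_prec, -1.0, 820, 160, 0.15),   # precip wettest qtr
    BIO17 = list(f_prec, -1.0, 130, 40,  0.25),   # precip driest qtr
    BIO18 = list(f_prec, -0.9, 160, 45,  0.40),   # precip warmest qtr
    BIO19 = list(f_prec, -1.0, 780, 150, 0.18)    # precip coldest qtr
  )
  out <- data.frame(site = metadata$site, stringsAsFactors = FALSE)
  for (code in bioclim_codes()) {
    s <- spec[[code]]
    out[[code]] <- s[[3]] + s[[4]] * (s[[2]] * s[[1]] +
                                        stats::rnorm(n, 0, s[[5]]))
  }
  out
}

#' Generate a synthetic water/land raster
#'
#' Builds a [water_raster()] grid in a projected km plane. All cells are
#' water unless marked as land.
#'
#' @param shape Integer vector `c(nrow, ncol)` of grid dimensions.
#' @param land Optional land specification: a logical matrix of the same
#'   shape (`TRUE` = land), or a two-column matrix/data frame of (row, col)
#'   indices of land cells.
#' @param resolution_km Cell edge length in km; must be positive.
#' @param origin Coordinates `c(x, y)` in km of the lower-left corner.
#' @return A `water_raster` object.
#' @export
#' @examples
#' r <- generate_water_raster(c(10, 10), resolution_km = 1)
#' sum(r$water)
generate_water_raster <- function(shape, land = NULL, resolution_km = 1,
                                  origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be two positive integers")
  if (resolution_km <= 0) stop("resolution_km must be positive")
  water <- matrix(TRUE, shape[1], shape[2])
  if (!is.null(land)) {
    if (is.matrix(land) && is.logical(land)) {
      if (!all(dim(land) == shape)) stop("logical land mask must match shape")
      water[land] <- FALSE
    } else {
      idx <- as.matrix(land)
      if (ncol(idx) != 2L) stop("land cell list must have two columns")
      if (any(idx[, 1] < 1 | idx[, 1] > shape[1] |
              idx[, 2] < 1 | idx[, 2] > shape[2]))
        stop("land cells fall outside the grid")
      water[idx] <- FALSE
    }
  }
  water_raster(water, cell_km = resolution_km, origin = origin)
}
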