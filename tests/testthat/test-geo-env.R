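test_that("waterway distances on simple channels match (N-1) x cell size", {
  r <- generate_water_raster(c(1, 5), resolution_km = 1)
  a <- cell_xy(r, 1, 1); b <- cell_xy(r, 1, 5)
  expect_equal(waterway_distance(r, a, b), 4)
  expect_equal(waterway_distance(r, a, a), 0)
  expect_equal(waterway_distance(r, b, a), 4)          # symmetric
  r2 <- generate_water_raster(c(1, 5), resolution_km = 2.5)
  expect_equal(waterway_distance(r2, cell_xy(r2, 1, 1), cell_xy(r2, 1, 5)),
               10)
  # diagonal steps cost sqrt(2) x cell
  r3 <- generate_water_raster(c(4, 4), resolution_km = 1)
  expect_equal(waterway_distance(r3, cell_xy(r3, 1, 1), cell_xy(r3, 4, 4)),
               3 * sqrt(2))
})

test_that("shortest paths agree with exhaustive enumeration on small corridors", {
  # L-shaped corridor
  water <- matrix(FALSE, 5, 5)
  water[1, 1:4] <- TRUE; water[1:5, 4] <- TRUE
  r <- water_raster(water, cell_km = 1)
  got <- waterway_distance(r, cell_xy(r, 1, 1), cell_xy(r, 5, 4),
                           snap_cells = 0.6)
  expect_equal(got, brute_force_water_distance(water, c(1, 1), c(5, 4)))
  # random masks: Dijkstra equals brute force wherever connected
  set.seed(12)
  for (i in 1:5) {
    w <- matrix(runif(25) > 0.3, 5, 5)
    w[1, 1] <- TRUE; w[5, 5] <- TRUE
    rr <- water_raster(w, cell_km = 1)
    brute <- brute_force_water_distance(w, c(1, 1), c(5, 5))
    if (is.finite(brute)) {
      expect_equal(waterway_distance(rr, cell_xy(rr, 1, 1),
                                     cell_xy(rr, 5, 5), snap_cells = 0.6),
                   brute)
    } else {
      expect_error(waterway_distance(rr, cell_xy(rr, 1, 1),
                                     cell_xy(rr, 5, 5), snap_cells = 0.6),
                   "disconnected")
    }
  }
})

test_that("waterway distance respects metric properties and lower bounds", {
  set.seed(13)
  w <- matrix(runif(49) > 0.25, 7, 7)
  r <- water_raster(w, cell_km = 1)
  cells <- which(w, arr.ind = TRUE)
  pts <- cells[sample(nrow(cells), 3), ]
  xy <- lapply(1:3, function(i) cell_xy(r, pts[i, 1], pts[i, 2]))
  d <- try(waterway_distance_matrix(r, do.call(rbind, xy),
                                    snap_cells = 0.6), silent = TRUE)
  if (!inherits(d, "try-error")) {
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-10)     # triangle inequality
    # never shorter than the straight line between the snapped cells
    for (i in 1:2) for (j in (i + 1):3) {
      straight <- sqrt(sum((xy[[i]] - xy[[j]])^2))
      expect_gte(d[i, j] + 1e-10, straight)
    }
  }
  # refining the grid never lengthens the path beyond the sqrt(2) bound
  chan <- generate_water_raster(c(2, 10), resolution_km = 1)
  d1 <- waterway_distance(chan, c(0.5, 0.5), c(9.5, 0.5))
  fine <- generate_water_raster(c(4, 20), resolution_km = 0.5)
  d2 <- waterway_distance(fine, c(0.5, 0.5), c(9.5, 0.5))
  expect_lte(d2, sqrt(2) * d1 + 1e-10)
})

test_that("points off the water snap within the documented radius or fail", {
  water <- matrix(TRUE, 4, 4); water[1:2, 1:2] <- FALSE  # land top-left
  r <- water_raster(water, cell_km = 1)
  # a point on land snaps to the nearest water cell (centre (2.5, 3.5))
  expect_equal(waterway_distance(r, c(1.4, 3.5), c(2.5, 3.5)), 0)
  # no water within the snap radius is an error, not a guess
  w2 <- matrix(FALSE, 1, 8); w2[1, 8] <- TRUE
  r2 <- water_raster(w2, cell_km = 1)
  expect_error(waterway_distance(r2, c(0.5, 0.5), c(7.5, 0.5),
                                 snap_cells = 3), "water cell within")
})

test_that("ASCII grid round-trips the raster exactly", {
  set.seed(14)
  r <- generate_water_raster(c(6, 9), land = matrix(runif(54) > 0.7, 6, 9),
                             resolution_km = 2.5, origin = c(-10, 3))
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_identical(r2$water, r$water)
  expect_equal(r2$cell_km, r$cell_km)
  expect_equal(r2$origin, r$origin)
})

test_that("correlation pruning retains by priority and drops by threshold", {
  set.seed(15)
  # exactly orthogonal columns: nothing can be dropped
  q <- qr.Q(qr(matrix(rnorm(12 * 6), 12, 6)))
  cl <- data.frame(site = paste0("s", 1:12), q)
  colnames(cl)[-1] <- c("BIO01", "BIO02", "BIO03", "BIO08", "BIO12", "BIO15")
  keep <- prune_climate_variables(cl)
  expect_setequal(keep, colnames(cl)[-1])
  # an exact duplicate of an earlier-priority variable is dropped
  cl$BIO05 <- cl$BIO01
  keep2 <- prune_climate_variables(cl)
  expect_false("BIO05" %in% keep2)
  expect_true("BIO01" %in% keep2)
  expect_true("BIO05" %in% attr(keep2, "dropped"))
  # constant variables are dropped with a warning
  cl$BIO04 <- 5
  expect_warning(keep3 <- prune_climate_variables(cl), "constant")
  expect_false("BIO04" %in% keep3)
  # row order does not matter
  expect_identical(
    as.character(suppressWarnings(prune_climate_variables(cl[sample(12), ]))),
    as.character(suppressWarnings(prune_climate_variables(cl))))
})

test_that("pruning the synthetic climate retains annual-trend variables first", {
  md <- default_site_layout()
  cl <- generate_climate(md, seed = 19)
  keep <- prune_climate_variables(cl)
  expect_true(all(c("BIO01", "BIO12") %in% keep))      # top priority survive
  expect_true(length(keep) < 19)                       # pruning fired
  r <- abs(cor(as.matrix(cl[, keep])))
  diag(r) <- 0
  expect_lte(max(r), 0.80)                             # retained set is clean
})

test_that("environmental differences derive from climate PC scores", {
  md <- default_site_layout()
  cl <- generate_climate(md, seed = 20)
  keep <- prune_climate_variables(cl)
  env <- environment_difference(cl, keep, axes = 1:2)
  expect_equal(nrow(env$differences), choose(16, 2))
  # identical climates -> zero difference on every axis
  cl2 <- cl; cl2[2, -1] <- cl2[1, -1]
  env2 <- environment_difference(cl2, keep, axes = 1:2,
                                 pairs = cbind(cl2$site[1], cl2$site[2]))
  expect_equal(env2$differences$dPC1, 0, tolerance = 1e-10)
  expect_equal(env2$differences$dPC2, 0, tolerance = 1e-10)
})

test_that("a single differing variable moves pairs in proportion to its loading", {
  set.seed(16)
  n <- 8
  base <- data.frame(site = paste0("s", 1:n),
                     v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n))
  # sites 1 and 2 share v2, v3; differ only in v1
  base$v2[2] <- base$v2[1]; base$v3[2] <- base$v3[1]
  env <- environment_difference(base, c("v1", "v2", "v3"), axes = 1:3)
  d12 <- env$differences[env$differences$site_a == "s1" &
                           env$differences$site_b == "s2", ]
  dz <- abs(base$v1[1] - base$v1[2]) / sd(base$v1)
  for (k in 1:3) {
    expect_equal(d12[[paste0("dPC", k)]],
                 abs(env$pca$loadings["v1", k]) * dz, tolerance = 1e-10)
  }
})
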