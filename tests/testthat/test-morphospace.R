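two_trait_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(site = rep(c("A", "B", "C"), length.out = n),
             habitat = "marine", standard_length = 50,
             t1 = rnorm(n), t2 = rnorm(n) * 2 + 1,
             stringsAsFactors = FALSE)
}

test_that("PCA eigenstructure matches a direct eigendecomposition", {
  tab <- two_trait_table()
  x <- as.matrix(tab[, c("t1", "t2")])
  for (sc in c(TRUE, FALSE)) {
    p <- run_pca(tab, scale = sc)
    ev <- eigen(if (sc) cor(x) else cov(x))$values
    expect_equal(p$sdev^2, ev, tolerance = 1e-12)
    expect_equal(p$pct_variance, 100 * ev / sum(ev), tolerance = 1e-12)
  }
})

test_that("variance on a single trait loads 100% on PC1", {
  tab <- two_trait_table()
  tab$t2 <- 3  # constant
  p <- run_pca(tab, scale = FALSE)
  expect_equal(p$pct_variance[1], 100)
  expect_error(run_pca(tab, scale = TRUE), "t2")
})

test_that("PCA invariants: orthonormal loadings, variance sums to 100, reconstruction", {
  sim <- generate_specimens(small_config(seed = 13))
  p <- run_pca(sim$specimens)
  L <- p$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(p$pct_variance), 100, tolerance = 1e-6)
  x <- as.matrix(sim$specimens[, rownames(L)])
  z <- scale(x, center = p$center, scale = p$scale)
  expect_lt(max(abs(p$scores %*% t(L) - z)), 1e-8)
  # sign convention: dominant loading of every axis is positive
  dom <- apply(L, 2, function(v) v[which.max(abs(v))])
  expect_true(all(dom > 0))
})

test_that("rows with missing traits are dropped and logged", {
  sim <- generate_specimens(small_config(seed = 14))
  sim$specimens$eye_diameter[4] <- NA
  expect_message(p <- run_pca(sim$specimens), "dropped")
  expect_equal(p$dropped, 4L)
  expect_equal(nrow(p$scores), nrow(sim$specimens) - 1)
})

test_that("centroids are per-site means of scores", {
  tab <- two_trait_table()
  p <- run_pca(tab)
  cen <- site_centroids(p)
  for (s in c("A", "B", "C")) {
    manual <- colMeans(p$scores[tab$site == s, , drop = FALSE])
    expect_equal(unlist(cen[cen$site == s, c("PC1", "PC2")]), manual,
                 ignore_attr = TRUE)
  }
  # a single-specimen site's centroid is that specimen's score
  tab1 <- tab; tab1$site[1] <- "solo"
  p1 <- run_pca(tab1)
  cen1 <- site_centroids(p1)
  expect_equal(unlist(cen1[cen1$site == "solo", c("PC1", "PC2")]),
               p1$scores[1, ], ignore_attr = TRUE)
  # permuting rows within sites leaves centroids unchanged (axis signs
  # aligned: with two standardised traits the dominant loading is tied)
  set.seed(1); perm <- order(tab$site, runif(nrow(tab)))
  p2 <- run_pca(tab[perm, ])
  flip <- sign(colSums(p2$loadings * p$loadings))
  cen2 <- site_centroids(p2)
  cen2[, c("PC1", "PC2")] <- sweep(as.matrix(cen2[, c("PC1", "PC2")]),
                                   2, flip, "*")
  expect_equal(cen2[order(cen2$site), ], cen[order(cen$site), ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("metadata sites absent from the scores raise an error", {
  tab <- two_trait_table()
  p <- run_pca(tab)
  md <- data.frame(site = c("A", "B", "C", "ghost"))
  expect_error(site_centroids(p, metadata = md), "ghost")
})

test_that("axis divergence is the absolute centroid difference", {
  cen <- make_centroids(c("m", "f"), rbind(c(-1, 2), c(3, 2)))
  expect_equal(axis_divergence(cen, "m", "f", 1), 4)
  expect_equal(axis_divergence(cen, "f", "m", 1), 4)   # symmetric
  expect_equal(axis_divergence(cen, "m", "f", "PC2"), 0)
  expect_equal(axis_divergence(cen, "m", "m", 1), 0)
  expect_error(axis_divergence(cen, "m", "f", 7), "unknown axis")
  # invariant under global translation of all scores
  cen2 <- cen; cen2$PC1 <- cen2$PC1 + 100
  expect_equal(axis_divergence(cen2, "m", "f", 1),
               axis_divergence(cen, "m", "f", 1))
})

test_that("orienting PC1 to the habitat contrast flips only the sign", {
  sim <- generate_specimens(small_config(seed = 15))
  p <- run_pca(sim$specimens)
  o <- orient_to_habitat(p)
  fw <- o$habitats == "freshwater"
  expect_gt(mean(o$scores[fw, 1]), mean(o$scores[!fw, 1]))
  expect_equal(abs(o$scores[, 1]), abs(p$scores[, 1]))
})

test_that("panmictic pooling relabels marine rows only and preserves centroid identity", {
  sim <- generate_specimens(sim_config(seed = 16))
  pooled <- pool_panmictic(sim$specimens)
  expect_equal(nrow(pooled), nrow(sim$specimens))
  expect_equal(sum(unique(pooled$site[pooled$habitat == "marine"]) ==
                     "panmictic"), 1)
  fresh <- sim$specimens$habitat == "freshwater"
  expect_identical(pooled$site[fresh], sim$specimens$site[fresh])
  expect_error(pool_panmictic(pooled[pooled$habitat == "freshwater", ]),
               "no marine")
  # panmictic centroid equals the sample-size-weighted mean of marine centroids
  p <- run_pca(sim$specimens)
  cen <- site_centroids(p)
  pan <- p
  pan$sites[pan$habitats == "marine"] <- "panmictic"
  pan_cen <- site_centroids(pan)
  marine <- cen$site %in% sim$metadata$site[sim$metadata$habitat == "marine"]
  w <- cen$n[marine] / sum(cen$n[marine])
  manual <- colSums(as.matrix(cen[marine, paste0("PC", 1:10)]) * w)
  expect_equal(unlist(pan_cen[pan_cen$site == "panmictic",
                              paste0("PC", 1:10)]),
               manual, tolerance = 1e-10, ignore_attr = TRUE)
})
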