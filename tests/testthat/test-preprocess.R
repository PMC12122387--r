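toy_table <- function(lengths, trait, site = "A", habitat = "freshwater") {
  data.frame(site = site, habitat = habitat, standard_length = lengths,
             body_depth = trait, stringsAsFactors = FALSE)
}

test_that("allometric slopes match closed-form least squares", {
  # constant trait -> slope 0; exact proportionality -> slope recovered
  tab <- toy_table(c(40, 45, 50, 55, 60), rep(7, 5))
  expect_equal(fit_allometry(tab)$beta, 0)
  tab2 <- toy_table(c(40, 45, 50, 55, 60), 2 * c(40, 45, 50, 55, 60))
  expect_equal(fit_allometry(tab2)$beta, 2)
  set.seed(1)
  x <- c(42, 47.5, 51, 55, 63); y <- c(8.1, 9.0, 8.7, 10.2, 11.0)
  f <- fit_allometry(toy_table(x, y))
  expect_equal(f$beta, cov(x, y) / var(x))
  expect_equal(f$mean_length_mm, mean(x))
  expect_equal(f$n, 5L)
})

test_that("groups with fewer than 3 usable specimens are excluded with a warning", {
  tab <- rbind(toy_table(c(40, 50, 60), c(1, 2, 3), site = "A"),
               toy_table(c(45, 55), c(2, 3), site = "B"))
  expect_warning(f <- fit_allometry(tab), "excluded")
  expect_equal(f$group, "A")
  expect_match(attr(f, "excluded"), "body_depth/B")
})

test_that("size correction applies the centring equation exactly", {
  # slope 0.5 built in exactly: trait = 9 + 0.5 * (L - 50.71)
  L <- c(48.71, 50.71, 52.71)
  tab <- toy_table(L, 9 + 0.5 * (L - 50.71))
  fits <- fit_allometry(tab)
  expect_equal(fits$beta, 0.5)
  corr <- size_correct(tab, fits)
  # chi = 10 at L = 52.71 with beta 0.5 and Lbar 50.71 corrects to 9.0
  expect_equal(corr$body_depth, rep(9, 3))
  # fish at the mean length is unchanged for any slope
  expect_equal(corr$body_depth[2], tab$body_depth[2])
})

test_that("a zero slope leaves traits unchanged", {
  tab <- toy_table(c(40, 50, 60), c(5, 7, 6))
  fits <- fit_allometry(tab)
  fits$beta <- 0
  expect_equal(size_correct(tab, fits)$body_depth, tab$body_depth)
})

test_that("exemption rules: gill rakers never corrected, plates only in freshwater", {
  sim <- generate_specimens(small_config(seed = 5))
  fits <- fit_allometry(sim$specimens)
  corr <- size_correct(sim$specimens, fits)
  marine <- sim$specimens$habitat == "marine"
  expect_equal(corr$gill_rakers, sim$specimens$gill_rakers)
  expect_equal(corr$lateral_plates[marine],
               sim$specimens$lateral_plates[marine])
  expect_false(isTRUE(all.equal(corr$lateral_plates[!marine],
                                sim$specimens$lateral_plates[!marine])))
  # global plate exemption switch
  corr2 <- size_correct(sim$specimens, fits, exempt_plates_globally = TRUE)
  expect_equal(corr2$lateral_plates, sim$specimens$lateral_plates)
  # corrected table keeps the input schema
  expect_identical(dim(corr), dim(sim$specimens))
  expect_identical(colnames(corr), colnames(sim$specimens))
})

test_that("missing fits are a hard error naming the trait/group pair", {
  sim <- generate_specimens(small_config(seed = 5))
  fits <- fit_allometry(sim$specimens)
  fits2 <- fits[!(fits$trait == "body_depth" & fits$group == "marine_02"), ]
  class(fits2) <- class(fits)
  attr(fits2, "grouping") <- attr(fits, "grouping")
  expect_error(size_correct(sim$specimens, fits2),
               "body_depth.*marine_02")
})

test_that("size correction is idempotent: refit slopes vanish after correcting", {
  sim <- generate_specimens(sim_config(seed = 8))
  fits <- fit_allometry(sim$specimens)
  corr <- size_correct(sim$specimens, fits)
  refit <- fit_allometry(corr)
  corrected_pairs <- !(refit$trait %in% "gill_rakers")
  # plates exempt in marine sites only
  marine_sites <- sim$metadata$site[sim$metadata$habitat == "marine"]
  corrected_pairs <- corrected_pairs &
    !(refit$trait == "lateral_plates" & refit$group %in% marine_sites)
  expect_lt(max(abs(refit$beta[corrected_pairs])), 1e-8)
})

test_that("missing trait values propagate without imputation", {
  sim <- generate_specimens(small_config(seed = 6))
  sim$specimens$body_depth[c(3, 17)] <- NA
  fits <- fit_allometry(sim$specimens)
  corr <- size_correct(sim$specimens, fits)
  expect_true(all(is.na(corr$body_depth[c(3, 17)])))
  expect_false(anyNA(corr$body_depth[-c(3, 17)]))
})

test_that("Levene F equals the one-way ANOVA on absolute deviations", {
  vals <- c(1, 2, 3, 4, 2, 4, 6, 8)
  grp <- rep(c("a", "b"), each = 4)
  for (cen in c("mean", "median")) {
    centre <- tapply(vals, grp, if (cen == "mean") mean else median)
    devs <- abs(vals - centre[grp])
    lt <- levene_test(vals, grp, center = cen)
    expect_equal(lt$statistic, anova_F_oracle(devs, grp), tolerance = 1e-12)
    expect_equal(lt$df_num, 1)
    expect_equal(lt$df_den, 6)
  }
  # per-group variances are reported
  lt <- levene_test(vals, grp)
  expect_equal(unname(lt$group_variances),
               c(var(vals[1:4]), var(vals[5:8])))
})

test_that("Levene test: identical groups give F = 0 and location shifts do not matter", {
  vals <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("a", "b"), each = 3)
  expect_equal(levene_test(vals, grp)$statistic, 0)
  shifted <- vals + ifelse(grp == "b", 100, 0)
  expect_equal(levene_test(shifted, grp)$statistic, 0)
  set.seed(2)
  v2 <- rnorm(24); g2 <- rep(c("a", "b", "c"), 8)
  base <- levene_test(v2, g2)
  shift <- levene_test(v2 + (g2 == "b") * 17.3, g2)
  expect_equal(shift$statistic, base$statistic, tolerance = 1e-12)
})

test_that("two-group Levene F equals the squared t statistic on deviations", {
  set.seed(3)
  vals <- c(rnorm(9, sd = 1), rnorm(13, sd = 2.5))
  grp <- rep(c("a", "b"), c(9, 13))
  med <- tapply(vals, grp, median)
  devs <- abs(vals - med[grp])
  tt <- t.test(devs ~ grp, var.equal = TRUE)
  expect_equal(levene_test(vals, grp)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)
})

test_that("Levene preconditions are enforced", {
  expect_error(levene_test(1:5, rep("a", 5)), "2 groups")
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "2 observations")
})

test_that("the habitat variance screen tabulates every trait", {
  sim <- generate_specimens(small_config(seed = 10))
  fits <- fit_allometry(sim$specimens)
  corr <- size_correct(sim$specimens, fits)
  lv <- levene_by_trait(corr)
  expect_equal(lv$trait, stickleback_traits()$trait)
  expect_true(all(lv$F >= 0))
  expect_true(all(lv$p >= 0 & lv$p <= 1))
  expect_true(all(lv$df_num == 1))
})
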