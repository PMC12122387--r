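#' Fit allometric regressions of traits on standard length
#'
#' Ordinary least-squares slope of each (unadjusted) trait on standard
#' length, fitted either separately per population (`grouping =
#' "per_population"`, the default, appropriate when slopes differ
#' significantly among populations) or once over all specimens
#' (`"common"`). The mean standard length attached to every fit is the grand
#' mean over all specimens in the table, since the size-correction equation
#' references a single dataset-wide average.
#'
#' Groups with fewer than 3 usable specimens for a trait are excluded from
#' the output with a warning; they are listed in the `excluded` attribute.
#'
#' @param table Specimen data frame with `site`, `standard_length` and trait
#'   columns.
#' @param traits Character vector of trait columns to fit; defaults to every
#'   trait column.
#' @param grouping `"per_population"` or `"common"`.
#' @return Data frame of class `allometry_fit`: one row per (trait, group)
#'   with columns `trait`, `group`, `beta`, `mean_length_mm`, `n`.
#' @export
fit_allometry <- function(table, traits = trait_columns(table),
                          grouping = c("per_population", "common")) {
  grouping <- match.arg(grouping)
  if (!"standard_length" %in% colnames(table))
    stop("table has no 'standard_length' column")
  missing_traits <- setdiff(traits, colnames(table))
  if (length(missing_traits))
    stop("trait columns not found: ", paste(missing_traits, collapse = ", "))
  lbar <- mean(table$standard_length, na.rm = TRUE)
  if (!is.finite(lbar) || lbar <= 0)
    stop("mean standard length must be positive")
  groups <- if (grouping == "common") rep("common", nrow(table))
            else as.character(table$site)
  out <- list(); excluded <- character(0)
  for (tr in traits) {
    for (g in unique(groups)) {
      sel <- groups == g & !is.na(table[[tr]]) & !is.na(table$standard_length)
      n <- sum(sel)
      if (n < 3L) {
        excluded <- c(excluded, sprintf("%s/%s (n=%d)", tr, g, n))
        next
      }
      x <- table$standard_length[sel]
      y <- table[[tr]][sel]
      vx <- stats::var(x)
      beta <- if (vx == 0) 0 else stats::cov(x, y) / vx
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, group = g, beta = beta, mean_length_mm = lbar, n = n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(excluded))
    warning("groups excluded from allometry fits (< 3 usable specimens): ",
            paste(excluded, collapse = "; "))
  fits <- do.call(rbind, out)
  rownames(fits) <- NULL
  attr(fits, "grouping") <- grouping
  attr(fits, "excluded") <- excluded
  class(fits) <- c("allometry_fit", "data.frame")
  fits
}

#' Allometric size correction of morphometric traits
#'
#' Removes body-size effects from each trait using
#' `corrected = raw - beta * (standard_length - mean_length)`, where `beta`
#' is the trait-on-length regression slope for the specimen's group and
#' `mean_length` is the dataset-wide average standard length stored in the
#' fits. Meristic counts that do not scale with body size are exempted: by
#' default gill raker number everywhere, and lateral plate number in marine
#' fish only (plates in freshwater fish are corrected), with a switch to
#' exempt plates globally.
#'
#' Missing trait values propagate as `NA`; nothing is imputed. The returned
#' table has the same schema as the input, with a correction audit log
#' (trait, group, beta, n, exempted rows) in the `audit` attribute.
#'
#' @param table Specimen data frame.
#' @param fits An [fit_allometry()] result covering every (trait, group)
#'   that needs correcting; a missing fit is a hard error naming the pair.
#' @param exempt_traits Traits never corrected in any habitat.
#' @param exempt_marine_traits Traits left uncorrected in marine fish only.
#' @param exempt_plates_globally If `TRUE`, lateral plates are exempted in
#'   both habitats (moved from `exempt_marine_traits` to `exempt_traits`).
#' @return Corrected specimen table, same dimensions and column order.
#' @export
#' @examples
#' sim <- generate_specimens(sim_config(seed = 1))
#' fits <- fit_allometry(sim$specimens)
#' corr <- size_correct(sim$specimens, fits)
size_correct <- function(table, fits,
                         exempt_traits = "gill_rakers",
                         exempt_marine_traits = "lateral_plates",
                         exempt_plates_globally = FALSE) {
  if (!inherits(fits, "allometry_fit"))
    stop("'fits' must come from fit_allometry()")
  if (exempt_plates_globally) {
    exempt_traits <- union(exempt_traits, exempt_marine_traits)
    exempt_marine_traits <- character(0)
  }
  grouping <- attr(fits, "grouping")
  traits <- intersect(unique(fits$trait), colnames(table))
  traits <- setdiff(traits, exempt_traits)
  out <- table
  lbar <- fits$mean_length_mm[1]
  key <- paste(fits$trait, fits$group, sep = "\r")
  marine_rows <- table$habitat == "marine"
  for (tr in traits) {
    groups <- if (grouping == "common") rep("common", nrow(table))
              else as.character(table$site)
    need <- rep(TRUE, nrow(table))
    if (tr %in% exempt_marine_traits) need <- need & !marine_rows
    for (g in unique(groups[need])) {
      rows <- need & groups == g
      i <- match(paste(tr, g, sep = "\r"), key)
      if (is.na(i))
        stop(sprintf("no allometry fit for trait '%s' in group '%s'", tr, g))
      beta <- fits$beta[i]
      out[rows, tr] <- table[rows, tr] -
        beta * (table$standard_length[rows] - lbar)
    }
  }
  attr(out, "audit") <- data.frame(
    trait = fits$trait, group = fits$group, beta = fits$beta, n = fits$n,
    stringsAsFactors = FALSE)
  attr(out, "mean_length_mm") <- lbar
  out
}

#' Levene/Brown-Forsythe test of variance homogeneity
#'
#' One-way ANOVA F on absolute deviations from each group's centre. The
#' default centre is the group median (Brown-Forsythe), matching the common
#' default in applied work; mean-centring (classical Levene) is available
#' and the choice is recorded in the result.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param center `"median"` (default) or `"mean"`.
#' @return Object of class `levene_result`: `statistic` (F), `df_num`,
#'   `df_den`, `p`, `group_variances`, `center`.
#' @export
#' @examples
#' levene_test(c(1, 2, 3, 2, 4, 6, 8), c("a", "a", "a", "b", "b", "b", "b"))
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  keep <- !is.na(values) & !is.na(groups)
  values <- as.numeric(values[keep])
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations (smallest has ",
         min(sizes), ")")
  fun <- if (center == "median") stats::median else mean
  lt <- car::leveneTest(values, groups, center = fun)
  res <- list(
    statistic = unname(lt[1, "F value"]),
    df_num = unname(lt[1, "Df"]),
    df_den = unname(lt[2, "Df"]),
    p = unname(lt[1, "Pr(>F)"]),
    group_variances = vapply(split(values, groups), stats::var, numeric(1)),
    center = center
  )
  class(res) <- "levene_result"
  res
}

#' @export
print.levene_result <- function(x, digits = 4, ...) {
  cat(sprintf("Levene test (center = %s): F(%d, %d) = %s, p = %s\n",
              x$center, x$df_num, x$df_den,
              format(x$statistic, digits = digits),
              format.pval(x$p, digits = digits)))
  cat("group variances:\n")
  print(round(x$group_variances, digits))
  invisible(x)
}

#' Habitat variance-homogeneity screen over all traits
#'
#' Runs [levene_test()] of marine versus freshwater samples for each trait
#' column, the standard screen for whether within-habitat trait variances
#' differ between habitats.
#'
#' @param table Specimen data frame (typically size-corrected).
#' @param traits Trait columns to test.
#' @inheritParams levene_test
#' @return Data frame: `trait`, `freshwater_variance`, `marine_variance`,
#'   `F`, `df_num`, `df_den`, `p`.
#' @export
levene_by_trait <- function(table, traits = trait_columns(table),
                            center = c("median", "mean")) {
  center <- match.arg(center)
  rows <- lapply(traits, function(tr) {
    lt <- levene_test(table[[tr]], table$habitat, center = center)
    data.frame(trait = tr,
               freshwater_variance = unname(lt$group_variances["freshwater"]),
               marine_variance = unname(lt$group_variances["marine"]),
               F = lt$statistic, df_num = lt$df_num, df_den = lt$df_den,
               p = lt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
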