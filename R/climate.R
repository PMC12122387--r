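#' Default bioclim retention priority
#'
#' Ordering used when pruning correlated bioclim variables: annual-trend and
#' overall-variation variables first (annual mean temperature BIO01, annual
#' precipitation BIO12, diurnal range BIO02, isothermality BIO03,
#' precipitation seasonality BIO15, wettest-quarter temperature BIO08),
#' then the remaining monthly/quarterly codes in ascending order.
#'
#' @return Character vector of the 19 BIO codes in priority order.
#' @export
bioclim_priority <- function() {
  first <- c("BIO01", "BIO12", "BIO02", "BIO03", "BIO15", "BIO08")
  c(first, setdiff(bioclim_codes(), first))
}

#' Greedy correlation pruning of climate variables
#'
#' Walks the variables in priority order; a variable is retained unless its
#' absolute Pearson correlation with an already-retained variable exceeds
#' the threshold. Deterministic, and invariant to the row (site) order of
#' the table. Constant variables, whose correlation is undefined, are
#' dropped with a warning.
#'
#' @param climate Data frame with a `site` column and one column per
#'   climate variable (or a plain numeric matrix/data frame of variables).
#' @param threshold Absolute correlation above which a variable is dropped
#'   (default 0.80).
#' @param priority Variable names in retention order; defaults to
#'   [bioclim_priority()] filtered to the columns present, followed by any
#'   non-bioclim columns.
#' @return Character vector of retained variable names, in priority order,
#'   with the dropped variables in the `dropped` attribute.
#' @export
#' @examples
#' md <- default_site_layout()
#' cl <- generate_climate(md, seed = 7)
#' prune_climate_variables(cl)
prune_climate_variables <- function(climate, threshold = 0.80,
                                    priority = NULL) {
  vars_df <- climate[, setdiff(colnames(climate), "site"), drop = FALSE]
  if (nrow(vars_df) < 2L) stop("need at least 2 sites")
  if (is.null(priority))
    priority <- c(intersect(bioclim_priority(), colnames(vars_df)),
                  setdiff(colnames(vars_df), bioclim_priority()))
  priority <- priority[priority %in% colnames(vars_df)]
  constant <- names(vars_df)[vapply(vars_df, function(x)
    stats::sd(x, na.rm = TRUE) == 0, logical(1))]
  if (length(constant))
    warning("constant variable(s) dropped (correlation undefined): ",
            paste(constant, collapse = ", "))
  priority <- setdiff(priority, constant)
  retained <- character(0); dropped <- constant
  for (v in priority) {
    if (length(retained) == 0L) {
      retained <- v
      next
    }
    r <- abs(stats::cor(vars_df[[v]],
                        vars_df[, retained, drop = FALSE],
                        use = "pairwise.complete.obs"))
    if (any(r > threshold, na.rm = TRUE)) dropped <- c(dropped, v)
    else retained <- c(retained, v)
  }
  attr(retained, "dropped") <- dropped
  attr(retained, "threshold") <- threshold
  retained
}

#' Pairwise environmental differences in climate PC space
#'
#' Runs a correlation-matrix PCA on the retained climate variables (one row
#' per site) and tabulates, for each requested site pair, the absolute
#' difference in site scores on each requested axis — the climate-space
#' analogue of morphological divergence.
#'
#' @param climate Data frame with `site` plus climate variable columns.
#' @param retained Variable names to use (e.g., from
#'   [prune_climate_variables()]); default all non-`site` columns.
#' @param axes Axis indices (default 1:2).
#' @param pairs Optional two-column data frame/matrix of (site_a, site_b)
#'   pairs; default every unordered pair. Pairs with missing climate values
#'   are flagged `NA`.
#' @return List with `pca` (a `pca_result` over sites), and `differences`
#'   (data frame `site_a`, `site_b`, one `dPC<k>` column per axis).
#' @export
environment_difference <- function(climate, retained = NULL, axes = 1:2,
                                   pairs = NULL) {
  vars <- setdiff(colnames(climate), "site")
  if (is.null(retained)) retained <- vars
  miss <- setdiff(retained, vars)
  if (length(miss))
    stop("retained variable(s) absent: ", paste(miss, collapse = ", "))
  tab <- climate[, c("site", retained)]
  colnames(tab)[1] <- "site"
  ok <- stats::complete.cases(tab[, retained, drop = FALSE])
  pca <- run_pca(tab[ok, , drop = FALSE], scale = TRUE, traits = retained)
  scores <- pca$scores
  rownames(scores) <- tab$site[ok]
  if (is.null(pairs)) {
    cmb <- utils::combn(climate$site, 2)
    pairs <- data.frame(site_a = cmb[1, ], site_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(site_a = pairs[, 1], site_b = pairs[, 2],
                        stringsAsFactors = FALSE)
  }
  for (k in axes) {
    col <- paste0("dPC", k)
    a <- scores[match(pairs$site_a, rownames(scores)), k]
    b <- scores[match(pairs$site_b, rownames(scores)), k]
    pairs[[col]] <- abs(a - b)
  }
  list(pca = pca, differences = pairs)
}
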