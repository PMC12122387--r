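# Negative restricted log-likelihood of a random-intercept Gaussian model,
# parametrised by (tau2, sigma2) = (intercept variance, residual variance).
# Dense: intended for the site-level tables this package produces (tens to
# hundreds of rows).
reml_neg_loglik <- function(theta, y, X, group) {
  tau2 <- theta[1]; sigma2 <- theta[2]
  if (sigma2 <= 0 || tau2 < 0) return(Inf)
  Z <- stats::model.matrix(~ 0 + group)
  V <- sigma2 * diag(length(y)) + tau2 * tcrossprod(Z)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  XtViy <- crossprod(X, Vi_y)
  beta <- solve(XtViX, XtViy)
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
           sum(r * Vi_r))
}

# SE of (tau2, sigma2) from the numerical Hessian of the REML criterion at
# the estimates. Returns NAs when the Hessian is not positive definite
# (e.g., variance estimated at the boundary).
reml_varcomp_se <- function(y, X, group, tau2, sigma2) {
  h <- tryCatch(
    stats::optimHess(c(tau2, sigma2), reml_neg_loglik,
                     y = y, X = X, group = group),
    error = function(e) NULL)
  if (is.null(h)) return(c(tau2_se = NA_real_, sigma2_se = NA_real_))
  ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(c(tau2_se = NA_real_, sigma2_se = NA_real_))
  se <- sqrt(diag(solve(h)))
  c(tau2_se = se[1], sigma2_se = se[2])
}

#' Fit a linear (mixed) model with a site-level random intercept
#'
#' Fits `response ~ fixed` by REML with an optional random intercept for a
#' grouping factor (via `lme4`); with `random_intercept = NULL` the fit
#' reduces to ordinary least squares. Reports the coefficient table
#' (estimate, SE, t, p), sequential fixed-effect ANOVA (SS, F, df), and the
#' random-intercept variance with a standard error obtained from the
#' curvature of the restricted likelihood.
#'
#' Denominator degrees of freedom for fixed-effect tests use the classical
#' between-within convention: predictors varying within groups are tested
#' against `n_obs - n_groups - p` residual df, where `p` is the number of
#' non-intercept fixed-effect columns.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms.
#' @param random_intercept Grouping column name, or `NULL` for OLS.
#' @return Object of class `lmm_fit`: `coefficients` (matrix), `anova`
#'   (data frame of term, SS, F, df_num, df_den, p), `random_variance`,
#'   `random_variance_se`, `sigma2`, `n_obs`, `n_groups`, `reml`,
#'   `converged`, `messages`, `model`.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(40), x = rnorm(40),
#'                 g = rep(letters[1:4], each = 10))
#' fit_lmm(d, "y", "x", random_intercept = "g")
fit_lmm <- function(data, response, fixed, random_intercept = NULL) {
  if (!response %in% colnames(data)) stop("response not found: ", response)
  rhs <- paste(fixed, collapse = " + ")
  if (is.null(random_intercept)) {
    fml <- stats::as.formula(paste(response, "~", rhs))
    m <- stats::lm(fml, data = data)
    sm <- summary(m)
    an <- stats::anova(m)
    terms_ <- setdiff(rownames(an), "Residuals")
    res <- list(
      response = response, fixed = fixed, random_intercept = NULL,
      coefficients = sm$coefficients,
      anova = data.frame(
        term = terms_, SS = an[terms_, "Sum Sq"],
        F = an[terms_, "F value"], df_num = an[terms_, "Df"],
        df_den = an["Residuals", "Df"], p = an[terms_, "Pr(>F)"],
        stringsAsFactors = FALSE),
      random_variance = NA_real_, random_variance_se = NA_real_,
      sigma2 = sm$sigma^2, n_obs = stats::nobs(m), n_groups = NA_integer_,
      reml = FALSE, converged = TRUE, messages = character(0), model = m)
    class(res) <- "lmm_fit"
    return(res)
  }
  grp <- data[[random_intercept]]
  if (is.null(grp)) stop("grouping column not found: ", random_intercept)
  n_groups <- length(unique(grp[!is.na(grp)]))
  if (n_groups < 2L)
    stop("random intercept grouping has a single level; use random_intercept = NULL")
  fml <- stats::as.formula(paste0(response, " ~ ", rhs,
                                  " + (1 | ", random_intercept, ")"))
  msgs <- character(0)
  m <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m_) {
      msgs <<- c(msgs, conditionMessage(m_))
      invokeRestart("muffleMessage")
    })
  msgs <- unique(c(msgs, unlist(m@optinfo$conv$lme4$messages)))
  sm <- summary(m)
  an <- stats::anova(m)
  n_obs <- stats::nobs(m)
  p_fixed <- ncol(lme4::getME(m, "X")) - 1L
  df_den <- n_obs - n_groups - p_fixed
  terms_ <- rownames(an)
  anova_tab <- if (length(terms_) == 0L) {
    data.frame(term = character(0), SS = numeric(0), F = numeric(0),
               df_num = integer(0), df_den = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(
      term = terms_, SS = an[, "Sum Sq"], F = an[, "F value"],
      df_num = an[, if ("npar" %in% colnames(an)) "npar" else "Df"],
      df_den = df_den,
      stringsAsFactors = FALSE)
    tab$p <- stats::pf(tab$F, tab$df_num, tab$df_den, lower.tail = FALSE)
    tab
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  tau2 <- vc$vcov[vc$grp == random_intercept]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  mf <- stats::model.frame(m)
  se <- reml_varcomp_se(stats::model.response(mf), lme4::getME(m, "X"),
                        factor(mf[[random_intercept]]), tau2, sigma2)
  coefs <- sm$coefficients
  coefs <- cbind(coefs, p = 2 * stats::pt(abs(coefs[, "t value"]), df_den,
                                          lower.tail = FALSE))
  res <- list(
    response = response, fixed = fixed, random_intercept = random_intercept,
    coefficients = coefs, anova = anova_tab,
    random_variance = tau2, random_variance_se = unname(se["tau2_se"]),
    sigma2 = sigma2, n_obs = n_obs, n_groups = n_groups,
    reml = TRUE, converged = length(msgs) == 0L, messages = msgs, model = m)
  class(res) <- "lmm_fit"
  res
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s ~ %s%s\n", x$response, paste(x$fixed, collapse = " + "),
              if (is.null(x$random_intercept)) "  [OLS]"
              else sprintf(" + (1 | %s)  [REML]", x$random_intercept)))
  stats::printCoefmat(x$coefficients, digits = digits, signif.stars = FALSE)
  if (nrow(x$anova)) {
    cat("fixed-effect ANOVA:\n")
    print(format(x$anova, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$random_intercept))
    cat(sprintf("random intercept (%s) variance: %s (SE %s); residual %s\n",
                x$random_intercept, format(x$random_variance, digits = digits),
                format(x$random_variance_se, digits = digits),
                format(x$sigma2, digits = digits)))
  if (!x$converged)
    cat("NOTE: fit flagged:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

# Fast marine-reference F statistic: sequential two-way ANOVA F for the
# reference term after the freshwater-site term. For a balanced layout this
# equals the mixed-model F for the reference fixed effect. Vectorised over
# columns of `Y` (one permutation replicate per column).
ref_F_stat <- function(Y, marine, freshwater) {
  Y <- as.matrix(Y)
  X1 <- stats::model.matrix(~ factor(freshwater))
  X2 <- stats::model.matrix(~ factor(freshwater) + factor(marine))
  q1 <- qr.Q(qr(X1)); q2 <- qr.Q(qr(X2))
  tot <- colSums(Y^2)
  rss1 <- tot - colSums(crossprod(q1, Y)^2)
  rss2 <- tot - colSums(crossprod(q2, Y)^2)
  df_m <- ncol(X2) - ncol(X1)
  df_e <- nrow(Y) - ncol(X2)
  ((rss1 - rss2) / df_m) / (rss2 / df_e)
}

#' Test whether divergence estimates depend on the marine reference
#'
#' Fits `value ~ marine_reference + (1 | freshwater_site)` to a table of
#' per-pair divergence estimates and reports the marine-reference sum of
#' squares and F (numerator df = number of references minus 1). Optionally
#' calibrates the F statistic by permuting reference labels within each
#' freshwater site, which preserves the site structure under the null of no
#' reference effect.
#'
#' @param divergences Data frame with columns `freshwater`, `marine`,
#'   `value` (see [divergence_estimates()]).
#' @param n_perm Number of within-site permutations for an exact-style p
#'   value; 0 (default) skips the permutation.
#' @param perm_seed Optional seed for the permutation draw.
#' @return An `lmm_fit` with extra fields `marine_SS`, `marine_F`,
#'   `marine_df`, and (when permuted) `p_perm` and `F_perm`.
#' @export
reference_effect_test <- function(divergences, n_perm = 0, perm_seed = NULL) {
  d <- divergences
  refs <- unique(d$marine); lakes <- unique(d$freshwater)
  if (length(refs) < 2L) stop("need at least 2 marine references")
  if (length(lakes) < 2L) stop("need at least 2 freshwater sites")
  full <- expand.grid(freshwater = lakes, marine = refs,
                      stringsAsFactors = FALSE)
  if (nrow(d) < nrow(full))
    message(nrow(full) - nrow(d), " missing reference x site cell(s)")
  d$marine <- factor(d$marine); d$freshwater <- factor(d$freshwater)
  fit <- fit_lmm(d, "value", "marine", random_intercept = "freshwater")
  i <- match("marine", fit$anova$term)
  fit$marine_SS <- fit$anova$SS[i]
  fit$marine_F <- fit$anova$F[i]
  fit$marine_df <- fit$anova$df_num[i]
  if (n_perm > 0) {
    if (!is.null(perm_seed)) set.seed(perm_seed)
    # permuting reference labels within a site == permuting values within it
    blocks <- split(seq_len(nrow(d)), d$freshwater)
    Y <- vapply(seq_len(n_perm), function(b) {
      y <- d$value
      for (ix in blocks) y[ix] <- y[sample(ix)]
      y
    }, numeric(nrow(d)))
    f_obs <- ref_F_stat(d$value, d$marine, d$freshwater)
    f_perm <- ref_F_stat(Y, d$marine, d$freshwater)
    fit$F_perm <- f_perm
    fit$p_perm <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }
  fit
}

#' Percent change in divergence under marine-reference substitution
#'
#' For each freshwater site, the spread of its per-reference divergence
#' estimates expressed as a percentage: `100 * (max - min) / max` by
#' default. Alternative normalisations (by the minimum or the mean) are
#' available and recorded in the result.
#'
#' @param divergences Data frame with `freshwater`, `marine`, `value`.
#' @param normalize `"max"` (default), `"min"`, or `"mean"` denominator.
#' @return Data frame: `freshwater`, `n_references`, `min`, `max`,
#'   `percent_change`; the normalisation is kept in the `normalize`
#'   attribute. A site whose denominator is 0 gets `NA` with a warning.
#' @export
#' @examples
#' d <- data.frame(freshwater = "L", marine = c("a", "b"), value = c(2, 4))
#' percent_change_by_reference(d)$percent_change  # 50
percent_change_by_reference <- function(divergences,
                                        normalize = c("max", "min", "mean")) {
  normalize <- match.arg(normalize)
  lakes <- unique(divergences$freshwater)
  rows <- lapply(lakes, function(l) {
    v <- divergences$value[divergences$freshwater == l]
    if (length(v) < 2L)
      stop("freshwater site '", l, "' has fewer than 2 reference estimates")
    den <- switch(normalize, max = max(v), min = min(v), mean = mean(v))
    pc <- if (den == 0) NA_real_ else 100 * (max(v) - min(v)) / den
    data.frame(freshwater = l, n_references = length(v), min = min(v),
               max = max(v), percent_change = pc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$percent_change))
    warning("percent change undefined (zero denominator) for: ",
            paste(out$freshwater[is.na(out$percent_change)], collapse = ", "))
  attr(out, "normalize") <- normalize
  out
}
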