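# Univariate inference: two-way ANOVA (Type-II sums of squares) with
# Bonferroni adjustment and assumption checks, Spearman rank correlation,
# and the multiplicity procedures used for gene panels and network edges.

#' Two-way ANOVA for nutrient-input and site effects
#'
#' Fits `y ~ input * site` and reports Type-II sums of squares for the two
#' main effects plus the interaction (on balanced designs these coincide
#' with the classical sequential decomposition). F statistics use the
#' residual mean square of the full model. Residual normality (Shapiro-Wilk)
#' and variance homogeneity across cells (Levene) are checked and reported
#' as flags; violations warn but never abort.
#'
#' @param y Numeric response (e.g. one gene's relative abundance).
#' @param input Factor-like nutrient-input flag (>= 2 levels).
#' @param site Factor-like site label (>= 2 levels).
#' @param family_size Bonferroni family size for `p_bonferroni` (number of
#'   features tested in the same panel; must be chosen explicitly by the
#'   caller, default 1 = no adjustment).
#' @return An `anova_result`: data.frame of terms (input, site, input:site,
#'   Residuals) with ss, df, F, p, p_bonferroni, plus attributes `shapiro_p`
#'   and `levene_p`.
#' @export
two_way_anova <- function(y, input, site, family_size = 1L) {
  input <- factor(input)
  site <- factor(site)
  abort_if(nlevels(input) < 2 || nlevels(site) < 2,
           "two_way_anova: both factors need >= 2 levels")
  abort_if(length(y) != length(input) || length(y) != length(site),
           "two_way_anova: length mismatch")
  cells <- table(input, site)
  abort_if(any(cells == 0),
           "two_way_anova: empty cell; interaction not estimable")
  n <- length(y)
  rss <- function(f) sum(stats::resid(stats::lm(f))^2)
  rss_a <- rss(y ~ input)
  rss_b <- rss(y ~ site)
  rss_ab <- rss(y ~ input + site)
  fit_full <- stats::lm(y ~ input * site)
  rss_full <- sum(stats::resid(fit_full)^2)
  df_res <- fit_full$df.residual
  abort_if(df_res < 1, "two_way_anova: zero residual degrees of freedom")

  ss <- c(input = rss_b - rss_ab,          # Type II: input after site
          site = rss_a - rss_ab,           # site after input
          `input:site` = rss_ab - rss_full)
  total_ss <- sum((y - mean(y))^2)
  tol <- 1e-12 * max(1, total_ss)
  ss <- pmax(ss, 0)
  ss[ss < tol] <- 0
  if (rss_full < tol) rss_full <- 0
  df <- c(input = nlevels(input) - 1L,
          site = nlevels(site) - 1L,
          `input:site` = (nlevels(input) - 1L) * (nlevels(site) - 1L))
  ms_res <- rss_full / df_res
  fstat <- if (ms_res > 0) (ss / df) / ms_res else ifelse(ss > 0, Inf, 0)
  p <- stats::pf(fstat, df, df_res, lower.tail = FALSE)
  p[fstat == 0] <- 1
  res <- data.frame(term = c(names(ss), "Residuals"),
                    ss = c(ss, rss_full),
                    df = c(df, df_res),
                    F = c(fstat, NA),
                    p = c(p, NA),
                    # bonferroni over the declared feature family, per term
                    p_bonferroni = c(pmin(1, p * family_size), NA),
                    stringsAsFactors = FALSE, row.names = NULL)
  checks <- assumption_checks(stats::resid(fit_full),
                              interaction(input, site, drop = TRUE))
  if (!is.na(checks$shapiro_p) && checks$shapiro_p < 0.05) {
    warning("two_way_anova: residual normality questionable (Shapiro-Wilk p = ",
            signif(checks$shapiro_p, 3), ")", call. = FALSE)
  }
  if (!is.na(checks$levene_p) && checks$levene_p < 0.05) {
    warning("two_way_anova: variance homogeneity questionable (Levene p = ",
            signif(checks$levene_p, 3), ")", call. = FALSE)
  }
  attr(res, "shapiro_p") <- checks$shapiro_p
  attr(res, "levene_p") <- checks$levene_p
  class(res) <- c("anova_result", "data.frame")
  res
}

#' ANOVA assumption checks: Shapiro-Wilk and Levene
#'
#' @param residuals Model residuals (>= 3 values).
#' @param groups Cell/group assignment for the Levene test (>= 2 groups).
#' @param center Levene centering: `"median"` (Brown-Forsythe, robust
#'   default) or `"mean"` (classical).
#' @return List with `shapiro_p`, `levene_p` and `degenerate` flag
#'   (constant residuals make both tests undefined; both p are NA then).
#' @export
assumption_checks <- function(residuals, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  abort_if(length(residuals) < 3, "assumption_checks: need >= 3 residuals")
  groups <- factor(groups)
  abort_if(nlevels(groups) < 2, "assumption_checks: need >= 2 groups")
  if (stats::sd(residuals) == 0) {
    return(list(shapiro_p = NA_real_, levene_p = NA_real_, degenerate = TRUE))
  }
  shapiro_p <- tryCatch(stats::shapiro.test(residuals)$p.value,
                        error = function(e) NA_real_)
  levene_p <- levene_test(residuals, groups, center = center)$p
  list(shapiro_p = shapiro_p, levene_p = levene_p, degenerate = FALSE)
}

#' Levene test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from each group's center.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param center `"median"` (Brown-Forsythe) or `"mean"` (original Levene).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  cfun <- if (center == "median") stats::median else mean
  ctr <- tapply(values, groups, cfun)
  z <- abs(values - ctr[groups])
  fit <- stats::anova(stats::lm(z ~ groups))
  list(F = fit$`F value`[1L], df1 = fit$Df[1L], df2 = fit$Df[2L],
       p = fit$`Pr(>F)`[1L])
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise; `m` defaults to the length of the vector but
#' can name a larger declared family.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param m Family size.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0) return(numeric(0))
  abort_if(any(pvals < 0 | pvals > 1, na.rm = TRUE),
           "bonferroni: p-values outside [0, 1]")
  pmin(1, pvals * m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values: `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` over
#' the sorted p-values, mapped back to input order.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  abort_if(any(pvals < 0 | pvals > 1, na.rm = TRUE),
           "bh_fdr: p-values outside [0, 1]")
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pvals[o] * m / seq(m, 1)))[ro]
  q
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (ties allowed); the
#' two-sided p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  abort_if(length(x) != length(y), "spearman: length mismatch")
  n <- length(x)
  abort_if(n < 3, "spearman: need n >= 3")
  abort_if(stats::sd(x) == 0 || stats::sd(y) == 0,
           "spearman: constant vector; rho undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Gene-panel ANOVA over a profile matrix
#'
#' Runs [two_way_anova()] per feature row with the feature count as the
#' Bonferroni family, returning a tidy table (feature, term, ss, df, F, p,
#' p_bonferroni, shapiro_p, levene_p).
#'
#' @param profile Feature x sample matrix.
#' @param meta A `sample_metadata` table.
#' @param contrast `"P"` or `"N"` (samples outside the contrast are dropped).
#' @param family_size Bonferroni family; defaults to `nrow(profile)`.
#' @return data.frame, one row per feature x term.
#' @export
panel_anova <- function(profile, meta, contrast = c("P", "N"),
                        family_size = nrow(profile)) {
  contrast <- match.arg(contrast)
  col <- if (contrast == "P") "p_contrast" else "n_contrast"
  keep <- meta$sample_id[!is.na(meta[[col]])]
  keep <- intersect(colnames(profile), keep)
  meta2 <- meta[match(keep, meta$sample_id), ]
  out <- lapply(rownames(profile), function(f) {
    res <- suppressWarnings(
      two_way_anova(profile[f, keep], meta2[[col]], meta2$site,
                    family_size = family_size))
    cbind(feature = f, as.data.frame(res),
          shapiro_p = attr(res, "shapiro_p"),
          levene_p = attr(res, "levene_p"))
  })
  do.call(rbind, out)
}
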