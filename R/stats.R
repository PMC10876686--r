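# Agreement and association statistics: ICC(A,1) (two-way model, single
# measures, absolute agreement), Lin's concordance correlation
# coefficient, Pearson correlation with p-values, and the Mann-Whitney U
# test for two-group comparisons.

#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, single measures, absolute agreement (McGraw-Wong
#' ICC(A,1)): with n subjects (rows) and k raters (columns),
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' from the two-way ANOVA mean squares for rows (subjects), columns
#' (raters) and error. Rows with missing values are dropped listwise.
#'
#' @param table Numeric matrix or data.frame, subjects x raters.
#' @return A list: \code{estimate}, \code{n} (subjects after exclusions),
#'   \code{k} (raters), \code{method}.
#' @export
icc_a1 <- function(table) {
  m <- as.matrix(table)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot <= 0) stop("zero total variance: ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  est <- min(est, 1)   # analytically <= 1; guards float overshoot at MSE ~ 0
  list(estimate = est, n = n, k = k,
       method = "ICC(A,1) two-way, single measures, absolute agreement")
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar{x}-\bar{y})^2}}
#' with population (1/n) variance and covariance denominators, the
#' original Lin definition (the convention matters at small n).
#'
#' @param x,y Paired numeric vectors.
#' @return A list: \code{estimate}, \code{n}, \code{method}.
#' @export
ccc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need paired vectors of length >= 3")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 + sy2 == 0) stop("zero variance in both inputs: CCC undefined")
  list(estimate = 2 * sxy / (sx2 + sy2 + (mx - my)^2), n = n,
       method = "Lin CCC (population denominators)")
}

#' Pearson correlation with two-sided p-value
#'
#' Wraps \code{stats::cor.test}: r with the two-sided p from the
#' t-distribution on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return A list: \code{estimate}, \code{p_value}, \code{n},
#'   \code{method}.
#' @export
pearson_with_p <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = "Pearson (t-test, two-sided)")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups, via
#' \code{stats::wilcox.test}: the exact null distribution is used for
#' small samples without ties, the normal approximation with tie
#' correction otherwise. The reported U is the statistic for
#' \code{group_a}.
#'
#' @param group_a,group_b Numeric vectors.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return A list: \code{u} (statistic for group_a), \code{p_value},
#'   \code{n}, \code{method}.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = length(group_a) + length(group_b) <= 20 &&
                         !any(duplicated(c(group_a, group_b)))))
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n = c(n_a = length(group_a), n_b = length(group_b)),
       method = wt$method)
}

#' Agreement report across AIF variants
#'
#' Mirrors the cohort-level agreement analysis: for each Tofts-model
#' parameter, the ICC(A,1) across the six population-AIF variants
#' (subjects = lesions, raters = variants) and the CCC between the plain
#' population AIF and the individual AIF.
#'
#' @param fits Data.frame with columns \code{lesion}, \code{aif_variant},
#'   and the parameter columns named in \code{params}.
#' @param params Parameters to report; default c("ktrans", "ve").
#' @param pop_variant Variant paired against "individual" in the CCC;
#'   default "pop".
#'
#' @return A data.frame with one row per parameter: \code{icc_population}
#'   (across population variants), \code{ccc_pop_vs_individual},
#'   \code{n_lesions}.
#' @export
parameter_agreement_report <- function(fits, params = c("ktrans", "ve"),
                                       pop_variant = "pop") {
  stopifnot(all(c("lesion", "aif_variant") %in% names(fits)))
  pop_variants <- setdiff(unique(fits$aif_variant), "individual")
  if (length(pop_variants) < 2L && !("individual" %in% fits$aif_variant))
    stop("need at least 2 AIF variants")
  out <- lapply(params, function(p) {
    wide <- stats::reshape(
      fits[, c("lesion", "aif_variant", p)],
      idvar = "lesion", timevar = "aif_variant", direction = "wide")
    rownames(wide) <- wide$lesion
    wide$lesion <- NULL
    names(wide) <- sub(paste0("^", p, "\\."), "", names(wide))
    icc <- if (length(pop_variants) >= 2L)
      icc_a1(wide[, pop_variants, drop = FALSE])$estimate else NA_real_
    cc_est <- if (all(c(pop_variant, "individual") %in% names(wide)))
      ccc(wide[[pop_variant]], wide[["individual"]])$estimate else NA_real_
    data.frame(parameter = p, icc_population = icc,
               ccc_pop_vs_individual = cc_est, n_lesions = nrow(wide))
  })
  do.call(rbind, out)
}
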