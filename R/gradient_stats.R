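# Downstream statistics along richness and regional gradients:
# linear-vs-quadratic model selection by AIC, Cohen's d with conventional
# magnitude labels, and annual climate variation as a mean yearly CV.

#' Fit linear and quadratic models and select by AIC
#'
#' Ordinary least squares fits of `y ~ x` and `y ~ x + x^2`; the model with
#' the lower Gaussian-likelihood AIC is selected. Only AIC differences
#' matter for the selection. When both models fit the data to numerical
#' precision (relative residual sum of squares below 1e-10), the AIC of a
#' near-zero RSS is meaningless and the simpler linear model is selected.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`; `x` non-constant.
#' @return Object of class `aic_fit`: a list with the two `lm` fits
#'   (`linear`, `quadratic`), named vectors `aic` and `r2`, and `selected`
#'   (`"linear"` or `"quadratic"`).
#' @export
fit_best <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("at least 4 complete observations are required")
  if (max(x) == min(x)) stop("x is constant; no gradient to fit")
  d <- data.frame(x = x, y = y)
  fit_lin <- stats::lm(y ~ x, data = d)
  fit_quad <- stats::lm(y ~ x + I(x^2), data = d)
  aic <- c(linear = stats::AIC(fit_lin), quadratic = stats::AIC(fit_quad))
  rss <- c(linear = sum(fit_lin$residuals^2),
           quadratic = sum(fit_quad$residuals^2))
  tss <- sum((y - mean(y))^2)
  selected <- if (tss > 0 && all(rss <= 1e-10 * tss)) "linear"
              else names(aic)[which.min(aic)]
  r2 <- c(linear = summary(fit_lin)$r.squared,
          quadratic = summary(fit_quad)$r.squared)
  structure(list(linear = fit_lin, quadratic = fit_quad, aic = aic,
                 r2 = r2, rss = rss, n = length(x), selected = selected),
            class = "aic_fit")
}

#' @export
print.aic_fit <- function(x, ...) {
  cat("Linear vs quadratic fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  linear:    AIC = %.2f, R2 = %.3f\n",
              x$aic["linear"], x$r2["linear"]))
  cat(sprintf("  quadratic: AIC = %.2f, R2 = %.3f\n",
              x$aic["quadratic"], x$r2["quadratic"]))
  cat("  selected: ", x$selected, "\n", sep = "")
  invisible(x)
}

#' Cohen's d with magnitude label
#'
#' Standardized mean difference `(mean1 - mean2) / s_pooled` with the
#' pooled (n - 1) standard deviation, labelled by the conventional cuts:
#' negligible (|d| < 0.2), small (0.2 <= |d| < 0.5), medium
#' (0.5 <= |d| < 0.8), large (|d| >= 0.8). The sign is preserved, so the
#' direction of a regional contrast is readable from the output.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return Object of class `cohens_d`: list with `d`, `label` (one of
#'   `"negligible"`, `"small"`, `"medium"`, `"large"`), and group sizes.
#' @export
cohens_d <- function(group1, group2) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 observations")
  sp <- sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  d <- (mean(group1) - mean(group2)) / sp
  label <- if (abs(d) < 0.2) "negligible"
           else if (abs(d) < 0.5) "small"
           else if (abs(d) < 0.8) "medium"
           else "large"
  structure(list(d = d, label = label, n1 = n1, n2 = n2),
            class = "cohens_d")
}

#' @export
print.cohens_d <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s; n1 = %d, n2 = %d)\n",
              x$d, x$label, x$n1, x$n2))
  invisible(x)
}

#' Annual climate variation as mean yearly CV
#'
#' For each year, the coefficient of variation (sample sd / mean) of its 12
#' monthly values; the output is the mean of the yearly CVs, summarizing
#' how strongly a site's climate fluctuates within a typical year.
#'
#' @param monthly Matrix with one row per year and 12 monthly columns, or a
#'   numeric vector whose length is a multiple of 12 (consecutive years).
#' @return Mean yearly CV (scalar).
#' @export
climate_cv <- function(monthly) {
  if (is.vector(monthly) && is.numeric(monthly)) {
    if (length(monthly) %% 12L != 0L)
      stop("monthly vector length must be a multiple of 12")
    monthly <- matrix(monthly, ncol = 12L, byrow = TRUE)
  }
  if (!is.matrix(monthly) || ncol(monthly) != 12L)
    stop("monthly must be a years x 12 matrix")
  means <- rowMeans(monthly)
  if (any(means == 0))
    stop("zero yearly mean in year(s): ",
         paste(which(means == 0), collapse = ", "))
  cvs <- apply(monthly, 1L, stats::sd) / means
  mean(cvs)
}
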