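# Storage statistics: Pearson correlation of physicochemical indexes
# against 3D morphological parameters, and the moisture-porosity
# ordinary-least-squares fit with R^2.

#' Pearson product-moment correlation
#'
#' A checked wrapper around the standard product-moment estimate: inputs
#' must be equal-length numeric sequences of at least 3 complete pairs, and
#' a constant input is an error (r is undefined), never a silent 0.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("'x' is constant: correlation undefined")
  if (sd(y) == 0) stop("'y' is constant: correlation undefined")
  r <- cor(x, y)
  max(-1, min(1, r))
}

#' Pairwise Pearson correlation matrix of a feature table
#'
#' Complete-case: rows with any missing value are dropped (and reported).
#' The result is exactly symmetric with a unit diagonal. Unadjusted
#' two-sided p-values are attached as attribute `"p_values"`; no
#' multiple-testing correction is applied.
#'
#' @param table Data.frame of numeric columns (non-numeric columns such as
#'   day labels are ignored with a message).
#' @return A matrix of class `correlation_matrix`.
#' @export
correlation_matrix <- function(table) {
  num <- vapply(table, is.numeric, TRUE)
  if (any(!num))
    message("correlation_matrix: ignoring non-numeric column(s): ",
            paste(names(table)[!num], collapse = ", "))
  tb <- table[, num, drop = FALSE]
  if (anyDuplicated(names(tb))) stop("column names must be unique")
  cc <- stats::complete.cases(tb)
  if (any(!cc))
    message(sprintf("correlation_matrix: dropped %d incomplete row(s)", sum(!cc)))
  tb <- tb[cc, , drop = FALSE]
  if (nrow(tb) < 3L) stop("need at least 3 complete rows")
  const <- vapply(tb, function(v) sd(v) == 0, TRUE)
  if (any(const))
    stop("constant column(s): ", paste(names(tb)[const], collapse = ", "))
  p <- ncol(tb)
  m <- diag(1, p)
  pv <- matrix(NA_real_, p, p)
  dimnames(m) <- dimnames(pv) <- list(names(tb), names(tb))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) {
      ct <- cor.test(tb[[i]], tb[[j]])
      m[i, j] <- m[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  structure(m, class = c("correlation_matrix", "matrix"), p_values = pv,
            n = nrow(tb))
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation matrix (n = %d; p-values unadjusted):\n",
              attr(x, "n")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Ordinary least-squares line with R-squared
#'
#' Simple linear regression of `y` on `x`; for this one-regressor case the
#' coefficient of determination equals the squared Pearson correlation.
#'
#' @param x,y Numeric vectors, at least 3 complete pairs; `x` nonconstant.
#' @return An object of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("'x' is constant: no line can be fitted")
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g + %.4g x, R^2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Assemble a feature table from covariates and morphometry summaries
#'
#' Joins the per-day covariate table to per-day morphometry summaries on
#' the `day` column, producing the table used for the correlation matrix:
#' `hardness_N`, `flexibility_mm`, `moisture_pct` (one chosen region),
#' `volume_mm3`, `area_mm2`, `porosity_pct`, `length_mm`, `width_mm`.
#'
#' @param covariates Data.frame with a `day` column and the covariate
#'   columns of [simulate_storage_covariates()].
#' @param summaries List of `morphometry_summary` objects, one per day (in
#'   day order).
#' @param moisture_region Which region's moisture enters the table:
#'   `"center"` (default), `"crumb"` or `"skin"`.
#' @return A data.frame with one row per day.
#' @export
build_feature_table <- function(covariates, summaries,
                                moisture_region = c("center", "crumb", "skin")) {
  moisture_region <- match.arg(moisture_region)
  if (length(summaries) != nrow(covariates))
    stop("one morphometry summary per covariate row is required")
  mo <- covariates[[paste0("moisture_", moisture_region)]]
  data.frame(
    day = covariates$day,
    hardness_N = covariates$hardness_N,
    flexibility_mm = covariates$flexibility_mm,
    moisture_pct = mo,
    volume_mm3 = vapply(summaries, function(s) s$mean_volume_mm3, 1.0),
    area_mm2 = vapply(summaries, function(s) s$mean_area_mm2, 1.0),
    porosity_pct = vapply(summaries, function(s) s$porosity_pct, 1.0),
    length_mm = vapply(summaries, function(s) s$mean_length_mm, 1.0),
    width_mm = vapply(summaries, function(s) s$mean_width_mm, 1.0))
}

#' Write a correlation matrix as CSV
#' @param m A `correlation_matrix`.
#' @param path Output path (labels x labels).
#' @export
write_correlation_matrix <- function(m, path) {
  df <- data.frame(feature = rownames(m), unclass(m), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
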