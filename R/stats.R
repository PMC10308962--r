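#' Ordinary least squares fit of Zc against Eh7
#'
#' Slope, Pearson correlation, and the 95% margin of error of the slope
#' (t-quantile with N - 2 degrees of freedom times the slope standard
#' error), so results print as m +/- MOE95. Eh7 should be supplied in
#' volts so slopes carry the 1/V unit.
#'
#' @param x Predictor (Eh7 in volts).
#' @param y Response (Zc).
#' @return A `regression_fit`: list with `N`, `m` (slope), `moe95`,
#'   `r` (Pearson), `intercept`.
#' @examples
#' f <- ols_fit(1:10 / 10, 0.3 + 0.1 * (1:10 / 10))
#' c(f$m, f$moe95, f$r)  # 0.1, 0, 1
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for a regression")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # slope SE from the residuals directly (summary.lm warns on exact fits)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sxx)
  moe95 <- stats::qt(0.975, n - 2) * se
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  structure(list(N = n, m = co[["x"]], moe95 = moe95, r = r,
                 intercept = co[["(Intercept)"]]),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("N = %d, m = %.4g +/- %.4g (1/V), r = %.3f\n",
              x$N, x$m, x$moe95, x$r))
  invisible(x)
}

#' Exact one-sided binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, 1/2): the probability of observing k or
#' more positive regression slopes out of n datasets if positive and
#' negative were equally likely.
#'
#' @param n Number of trials (datasets).
#' @param k Number of successes (positive slopes).
#' @return Exact tail probability in (0, 1].
#' @examples
#' binom_tail(12, 10)  # 0.019...
#' @export
binom_tail <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) stop("successes cannot exceed trials")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Paper-style P value formatting
#'
#' Three decimal places at or above 0.001; five decimal places below
#' (0.0000654 prints as "0.00007").
#'
#' @param p Numeric P value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p >= 1e-3, sprintf("%.3f", p), sprintf("%.5f", p))
}

#' Keep regressions whose 95% CI excludes zero
#'
#' A fit is significant when the minimum and maximum of the 95% confidence
#' interval of the slope have the same sign.
#'
#' @param fits data.frame with columns `m` and `moe95` (e.g. from
#'   [dataset_fits()]), or a list of `regression_fit` objects.
#' @return The significant subset with an added `sign` column (+1/-1);
#'   for a list input, a filtered list with a `sign` attribute per fit.
#' @export
significance_filter <- function(fits) {
  if (is.data.frame(fits)) {
    keep <- (fits$m - fits$moe95) > 0 | (fits$m + fits$moe95) < 0
    out <- fits[keep, , drop = FALSE]
    out$sign <- ifelse(out$m > 0, 1L, -1L)
    rownames(out) <- NULL
    return(out)
  }
  keep <- vapply(fits, function(f) (f$m - f$moe95) > 0 ||
                   (f$m + f$moe95) < 0, logical(1))
  lapply(fits[keep], function(f) { attr(f, "sign") <- sign(f$m); f })
}

#' Binomial sign-test tally of regression slopes
#'
#' Groups per-dataset fits by environment and tallies positive vs negative
#' slopes, with an exact one-sided binomial P value per group and a Total
#' row. With `filtered = TRUE` only fits whose 95% CI excludes zero are
#' counted.
#'
#' @param fits data.frame with columns `environment`, `m`, `moe95` (and
#'   any others, e.g. `dataset`, `domain`).
#' @param filtered Count only significant fits?
#' @param environments Optional row order; defaults to order of first
#'   appearance.
#' @return data.frame: `environment`, `N_tot`, `N_pos`, `N_neg`, `P`,
#'   `P_printed` (via [format_pvalue()]), ending with a "Total" row.
#' @export
tally_table <- function(fits, filtered = FALSE, environments = NULL) {
  if (filtered) fits <- significance_filter(fits)
  if (is.null(environments)) environments <- unique(fits$environment)
  rows <- lapply(environments, function(env) {
    sub <- fits[fits$environment == env, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("no fits for environment: ", env, " (omitted)")
      return(NULL)
    }
    tally_row(env, sub$m)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, c(rows, list(tally_row("Total", fits$m))))
  rownames(out) <- NULL
  out
}

tally_row <- function(label, slopes) {
  n_pos <- sum(slopes > 0)
  n_neg <- sum(slopes < 0)
  p <- binom_tail(n_pos + n_neg, n_pos)
  data.frame(environment = label, N_tot = n_pos + n_neg, N_pos = n_pos,
             N_neg = n_neg, P = p, P_printed = format_pvalue(p),
             stringsAsFactors = FALSE)
}

#' Two-sample t-test on group Zc values
#'
#' Pooled-variance (Student) two-sided test, e.g. aerotolerant vs strictly
#' anaerobic genera.
#'
#' @param group_a,group_b Numeric vectors of Zc values (each N >= 2).
#' @return Two-sided P value.
#' @export
group_zc_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b))
    return(1)
  stats::t.test(group_a, group_b, var.equal = TRUE)$p.value
}
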