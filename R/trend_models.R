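#' Centered moving average with truncated endpoints
#'
#' Smooths an annual series with a centred window (before-during-after for
#' the default `window = 3`); endpoints average over the available part of
#' the window so the smoothed series keeps the raw series' length. Missing
#' values are ignored within the window.
#'
#' @param values Numeric vector.
#' @param window Odd window length; `window = 1` is the identity.
#' @return Numeric vector, same length as `values`.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4))  # 1.5 2 3 3.5
moving_average <- function(values, window = 3) {
  window <- check_window(window)
  if (length(values) == 0L) abort("`values` is empty.")
  ma_truncated(as.numeric(values), window)
}

candidate_forms <- c("linear", "exponential", "power", "quadratic")

# AIC comparable across response scales: every form's likelihood is
# evaluated for the response on its original (measured) scale. Identity
# forms use the Gaussian residual likelihood; log-response forms use the
# implied lognormal density, i.e. the Gaussian likelihood of log(y) plus the
# change-of-variables term 2*sum(log y). Weights are normalised to sum to n
# so equal weights reproduce the unweighted values.
original_scale_aic <- function(y, resid_model_scale, w, n_coef, log_scale) {
  n <- length(y)
  wn <- w * n / sum(w)
  rss <- sum(wn * resid_model_scale^2)
  sigma2 <- max(rss / n, .Machine$double.eps)
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1)
  if (log_scale) ll <- ll - sum(wn * log(y))
  -2 * ll + 2 * (n_coef + 1)
}

fit_one_form <- function(form, x, y, w) {
  df <- data.frame(x = x, y = y, w = w)
  fml <- switch(form,
    linear      = y ~ x,
    quadratic   = y ~ x + I(x^2),
    exponential = log(y) ~ x,
    power       = log(y) ~ log(x)
  )
  m <- stats::lm(fml, data = df, weights = w)
  sm <- summary(m)
  fs <- sm$fstatistic
  p_value <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  cf <- stats::coef(m)
  log_scale <- form %in% c("exponential", "power")

  xr <- range(x)
  pred_ends <- as.numeric(stats::predict(m, newdata = data.frame(x = xr)))
  if (log_scale) pred_ends <- exp(pred_ends)
  net_change <- pred_ends[2L] - pred_ends[1L]
  net_change_pct <- 100 * net_change / pred_ends[1L]

  # Fitted first derivative at the first timestep, on the response's own
  # scale sign (the back-transform is monotone, so the sign carries over).
  deriv_first <- switch(form,
    linear      = cf[["x"]],
    quadratic   = cf[["x"]] + 2 * cf[["I(x^2)"]] * xr[1L],
    exponential = cf[["x"]],
    power       = cf[["log(x)"]]
  )

  shapiro_p <- tryCatch(stats::shapiro.test(stats::residuals(m))$p.value,
                        error = function(e) NA_real_)
  dw <- tryCatch(unname(lmtest::dwtest(m)$statistic), error = function(e) NA_real_)

  structure(list(
    form = form, model = m,
    coefficients = tibble(term = names(cf), estimate = unname(cf),
                          std.error = sm$coefficients[, "Std. Error"]),
    r2 = sm$r.squared, p_value = unname(p_value),
    aic = original_scale_aic(y, as.numeric(stats::residuals(m)), w,
                             length(cf), log_scale),
    shapiro_p = shapiro_p, dw = dw, n = length(y),
    net_change = net_change, net_change_pct = net_change_pct,
    deriv_first = unname(deriv_first),
    effect = NA_real_, effect_se = NA_real_,
    selected = FALSE, flags = character()
  ), class = "creel_fit")
}

# Standardised linear slope (z-scored x and y, same weights): the
# cross-variable effect size used by the management classifier.
standardized_effect <- function(x, y, w) {
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  if (!is.finite(sum(zy)) || stats::sd(y) == 0) {
    return(c(effect = 0, se = Inf))
  }
  m <- stats::lm(zy ~ zx, weights = w)
  sm <- summary(m)$coefficients
  c(effect = unname(stats::coef(m)[2L]), se = unname(sm["zx", "Std. Error"]))
}

#' Fit the candidate trend models to one series
#'
#' Fits weighted least-squares regressions of four forms to an annual
#' series: linear (`y ~ x`), quadratic (`y ~ x + x^2`, humped trends),
#' exponential (`log(y) ~ x`) and power (`log(y) ~ log(x)`), the latter two
#' capturing strong early change followed by saturation. `x` is the year
#' index starting at 1. Log-response forms require a strictly positive
#' response and are skipped otherwise. AIC values are made comparable across
#' response scales by evaluating every form's likelihood for the response on
#' its original measured scale (log-response forms via the implied lognormal
#' density, i.e. with the change-of-variables correction). Each fit carries the overall
#' F-test p-value, a Shapiro-Wilk residual-normality p, and the
#' Durbin-Watson statistic.
#'
#' @param y Response values (typically the smoothed annual series).
#' @param weights Per-year confidence weights (total kg for biomass-derived
#'   variables, fish counts for size variables); `NULL` for equal weights.
#' @param x Predictor; defaults to the year index `1..length(y)`.
#' @return A named list of `creel_fit` objects (possibly fewer than four).
#' @export
fit_candidates <- function(y, weights = NULL, x = seq_along(y)) {
  if (is.null(weights)) weights <- rep(1, length(y))
  keep <- is.finite(y) & is.finite(weights) & weights > 0
  x <- x[keep]; y <- y[keep]; w <- weights[keep]
  if (length(y) < 5L) {
    abort("Need at least 5 usable (finite, positively weighted) points.")
  }
  forms <- candidate_forms
  if (any(y <= 0)) {
    inform("Non-positive response values: skipping log-response forms.")
    forms <- c("linear", "quadratic")
  }
  eff <- standardized_effect(x, y, w)
  fits <- lapply(forms, function(f) {
    ft <- fit_one_form(f, x, y, w)
    ft$effect <- eff[["effect"]]
    ft$effect_se <- eff[["se"]]
    ft
  })
  stats::setNames(fits, forms)
}

#' Select the best candidate model
#'
#' Among candidates whose overall F-test is significant at `alpha`, prefers
#' those whose residuals pass the Shapiro-Wilk normality test
#' (`shapiro_p >= alpha`) and picks the minimum AIC there — balancing fit
#' against residual normality. If every significant fit violates normality,
#' the minimum-AIC significant fit is returned flagged
#' `"normality_violated"`. A Durbin-Watson statistic outside `[1, 3]` adds
#' an `"autocorrelated"` flag without vetoing. Returns `NULL` when no fit is
#' significant.
#'
#' @param fits List of `creel_fit` objects from [fit_candidates()].
#' @param alpha Significance level.
#' @return The selected `creel_fit` (with `selected = TRUE`), or `NULL`.
#' @export
select_model <- function(fits, alpha = 0.05) {
  if (length(fits) == 0L) abort("Empty fit list.")
  p <- vapply(fits, function(f) f$p_value %||% NA_real_, numeric(1))
  signif_ok <- !is.na(p) & p < alpha
  if (!any(signif_ok)) return(NULL)
  sig <- fits[signif_ok]
  sh <- vapply(sig, `[[`, numeric(1), "shapiro_p")
  normal_ok <- is.na(sh) | sh >= alpha  # NA: test unavailable, no evidence
  pool <- if (any(normal_ok)) sig[normal_ok] else sig
  aic <- vapply(pool, `[[`, numeric(1), "aic")
  best <- pool[[which.min(aic)]]
  best$selected <- TRUE
  if (!any(normal_ok)) best$flags <- c(best$flags, "normality_violated")
  if (!is.na(best$dw) && (best$dw < 1 || best$dw > 3)) {
    best$flags <- c(best$flags, "autocorrelated")
  }
  best
}

#' Render a fitted model as a compact equation string
#'
#' @param fit A `creel_fit`.
#' @param digits Significant digits per coefficient.
#' @return A string such as `"y = -1.1x + 0.03x^2 + 24.7"`.
#' @export
equation_string <- function(fit, digits = 2) {
  cf <- signif(fit$coefficients$estimate, digits)
  names(cf) <- fit$coefficients$term
  term <- function(v, sym) {
    sprintf("%s %s%s", if (v < 0) "-" else "+", format(abs(v)), sym)
  }
  lead <- function(v, sym) sprintf("%s%s%s", if (v < 0) "-" else "", format(abs(v)), sym)
  switch(fit$form,
    linear = sprintf("y = %s %s", lead(cf[["x"]], "x"),
                     term(cf[["(Intercept)"]], "")),
    quadratic = sprintf("y = %s %s %s", lead(cf[["x"]], "x"),
                        term(cf[["I(x^2)"]], "x^2"), term(cf[["(Intercept)"]], "")),
    exponential = sprintf("log(y) = %s %s", lead(cf[["x"]], "x"),
                          term(cf[["(Intercept)"]], "")),
    power = sprintf("log(y) = %s %s", lead(cf[["log(x)"]], " log(x)"),
                    term(cf[["(Intercept)"]], ""))
  )
}

#' @export
print.creel_fit <- function(x, ...) {
  cat(sprintf("<creel_fit> %s  %s\n", x$form, equation_string(x)))
  cat(sprintf("  R2 = %.3f, p = %.4g, AIC = %.2f, shapiro p = %.3g, DW = %.2f, n = %d\n",
              x$r2, x$p_value, x$aic, x$shapiro_p, x$dw, x$n))
  cat(sprintf("  net change = %.3f (%.1f%%)%s\n", x$net_change, x$net_change_pct,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Tidy a fitted trend model
#'
#' @param x A `creel_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (`term`, `estimate`,
#'   `std.error`); `glance()`: a one-row model summary.
#' @export
#' @importFrom generics tidy
tidy.creel_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.creel_fit
#' @export
#' @importFrom generics glance
glance.creel_fit <- function(x, ...) {
  tibble(form = x$form, r.squared = x$r2, p.value = x$p_value, AIC = x$aic,
         shapiro_p = x$shapiro_p, dw = x$dw, n = x$n,
         net_change = x$net_change, net_change_pct = x$net_change_pct,
         effect = x$effect, effect_se = x$effect_se,
         selected = x$selected,
         flags = paste(x$flags, collapse = ","))
}
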