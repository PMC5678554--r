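#' Fit the exponential expansion-rate model
#'
#' Rosette growth is sub-exponential: the relative expansion rate
#' declines as the plant gets larger. The model captures this with
#' `RER = exp(alpha + beta * area)`, where `alpha` (dimensionless) is the
#' log rate extrapolated to zero area and `beta` (per cm^2, negative in
#' practice) measures how fast the rate decays with size.
#'
#' The model is fitted by nonlinear least squares on the RER scale
#' (Levenberg-Marquardt), which is maximum likelihood under additive
#' Gaussian noise and, unlike a log-linear regression, keeps intervals
#' whose observed RER is zero or negative. An ordinary regression of
#' `log(RER)` on area over the positive RERs seeds the optimizer.
#'
#' @param rers data frame with columns `rer` and `mean_area_cm2` (the
#'   output of [rer()], possibly pooled over plants). Rows with `NA` are
#'   dropped.
#' @param tol optimizer convergence tolerance (`ftol`/`ptol`).
#' @return an object of class `rer_fit`: list with `alpha`, `beta`,
#'   `sigma2` (ML residual variance, RSS/n), `logLik`, `rss`, `n`,
#'   `fitted`, `residuals`, and `converged`.
#' @examples
#' a <- seq(10, 900, length.out = 50)
#' d <- data.frame(mean_area_cm2 = a, rer = exp(-4.55 - 2.127e-3 * a))
#' fit_rer_model(d)[c("alpha", "beta")]
#' @export
fit_rer_model <- function(rers, tol = 1e-10) {
  stopifnot(is.data.frame(rers),
            all(c("rer", "mean_area_cm2") %in% names(rers)))
  d <- rers[stats::complete.cases(rers[, c("rer", "mean_area_cm2")]), ]
  n <- nrow(d)
  if (n < 3L) stop_input("need at least 3 intervals to fit the RER model")
  pos <- d$rer > 0
  start <- if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm(log(rer) ~ mean_area_cm2, data = d[pos, ]))
    list(alpha = unname(cf[1]), beta = unname(cf[2]))
  } else {
    list(alpha = log(max(mean(d$rer), 1e-6)), beta = 0)
  }
  # a vanishing seed slope (flat data) breaks nls's per-parameter
  # scaling; snap it to zero, and retry once from a jittered seed if the
  # optimizer still balks
  if (abs(start$beta) < 1e-12) start$beta <- 0
  try_fit <- function(s) tryCatch(
    minpack.lm::nlsLM(rer ~ exp(alpha + beta * mean_area_cm2),
                      data = d, start = s,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = tol, ptol = tol)),
    error = function(e) e)
  fit <- try_fit(start)
  if (inherits(fit, "error"))
    fit <- try_fit(list(alpha = start$alpha + 0.05,
                        beta = start$beta * 1.1 - 1e-6))
  if (inherits(fit, "error"))
    stop_input("RER model fit failed to converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                 sigma2 = sigma2, logLik = ll, rss = rss, n = n,
                 fitted = stats::fitted(fit), residuals = res,
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "rer_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rer_fit <- function(x, ...) {
  cat(sprintf(
    "<rer_fit> RER = exp(alpha + beta * area)\n  alpha = %.4f  beta = %.4g per cm^2\n  n = %d  sigma^2 = %.3g  logLik = %.2f\n",
    x$alpha, x$beta, x$n, x$sigma2, x$logLik))
  invisible(x)
}

#' Likelihood-ratio comparison of expansion-rate models across treatments
#'
#' Tests whether treatments share one expansion-rate curve. The full
#' model gives every treatment its own `(alpha, beta)`; the reduced model
#' pools all intervals into a single pair. Both use a common Gaussian
#' residual variance, so the statistic is
#' `2 * (logLik_full - logLik_reduced) = n * log(RSS_reduced / RSS_full)`
#' and is referred to a chi-squared distribution with `2 * (T - 1)`
#' degrees of freedom for T treatments. Treatments are additionally
#' grouped by significance letters from all pairwise likelihood-ratio
#' tests at the chosen level: treatments sharing a letter are not
#' significantly different.
#'
#' @param data data frame with columns `treatment`, `rer`,
#'   `mean_area_cm2` (pooled per-interval records of all plants).
#' @param alpha_level significance level for the letter grouping.
#' @return an object of class `rer_lrt`: list with `statistic`, `df`,
#'   `p_value`, `fits` (per-treatment `rer_fit`s), `pooled_fit`,
#'   `letters` (named per-treatment significance letters),
#'   `pairwise_p`, `n`, and `alpha_level`.
#' @export
compare_treatments <- function(data, alpha_level = 0.01) {
  stopifnot(is.data.frame(data),
            all(c("treatment", "rer", "mean_area_cm2") %in% names(data)))
  data <- data[stats::complete.cases(
    data[, c("treatment", "rer", "mean_area_cm2")]), ]
  trts <- unique(as.character(data$treatment))
  if (length(trts) < 2L) stop_input("need at least 2 treatments")
  fits <- lapply(trts, function(tr)
    fit_rer_model(data[data$treatment == tr, ]))
  names(fits) <- trts
  pooled <- fit_rer_model(data)
  n <- sum(vapply(fits, `[[`, 0, "n"))
  rss_full <- sum(vapply(fits, `[[`, 0, "rss"))
  if (rss_full <= 0 || pooled$rss <= 0)
    stop_input("degenerate fit: zero residual sum of squares")
  stat <- n * log(pooled$rss / rss_full)
  df <- 2L * (length(trts) - 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)

  pair_lrt <- function(t1, t2) {
    d12 <- data[data$treatment %in% c(t1, t2), ]
    red <- fit_rer_model(d12)
    rssf <- fits[[t1]]$rss + fits[[t2]]$rss
    n12 <- fits[[t1]]$n + fits[[t2]]$n
    stats::pchisq(n12 * log(red$rss / rssf), df = 2, lower.tail = FALSE)
  }
  pw <- matrix(NA_real_, length(trts), length(trts),
               dimnames = list(trts, trts))
  for (i in seq_along(trts)) for (j in seq_along(trts)) if (i < j)
    pw[i, j] <- pw[j, i] <- pair_lrt(trts[i], trts[j])

  structure(list(statistic = stat, df = df, p_value = p,
                 fits = fits, pooled_fit = pooled,
                 letters = significance_letters(pw, alpha_level),
                 pairwise_p = pw, n = n, alpha_level = alpha_level),
            class = "rer_lrt")
}

# Greedy insert-and-absorb letter assignment: treatments not
# significantly different (p >= alpha_level) may share a letter; each
# treatment receives the letters of all groups it belongs to.
significance_letters <- function(pairwise_p, alpha_level) {
  trts <- rownames(pairwise_p)
  same <- function(a, b) pairwise_p[a, b] >= alpha_level
  groups <- list()
  for (tr in trts) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(vapply(groups[[gi]], same, TRUE, b = tr))) {
        groups[[gi]] <- c(groups[[gi]], tr)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- tr
  }
  # drop groups wholly contained in another
  keep <- vapply(seq_along(groups), function(i)
    !any(vapply(seq_along(groups), function(j)
      i != j && all(groups[[i]] %in% groups[[j]]), TRUE)), TRUE)
  groups <- groups[keep]
  out <- vapply(trts, function(tr)
    paste(letters[which(vapply(groups, function(g) tr %in% g, TRUE))],
          collapse = ""), "")
  out
}

#' @export
print.rer_lrt <- function(x, ...) {
  cat(sprintf(
    "<rer_lrt> %d treatments, n = %d intervals\n  LRT = %.3f on %d df, p = %.4g\n",
    length(x$fits), x$n, x$statistic, x$df, x$p_value))
  for (tr in names(x$fits))
    cat(sprintf("  %-14s alpha = %7.3f  beta = %10.4g  [%s]\n",
                tr, x$fits[[tr]]$alpha, x$fits[[tr]]$beta, x$letters[[tr]]))
  invisible(x)
}
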