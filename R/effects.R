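#' Hedges g for paired differences
#'
#' Bias-corrected standardized mean difference for a within-subject contrast:
#' `g = (mean(d) / sd(d)) * J(n - 1)` with the small-sample correction
#' `J(nu) = 1 - 3 / (4 nu - 1)`. The 95% confidence interval is obtained by
#' inverting the noncentral t distribution of the one-sample t statistic
#' (`ci_method = "noncentral_t"`, default), or by a seeded percentile
#' bootstrap.
#'
#' @param differences Per-subject difference scores (length >= 2, nonzero
#'   variance).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"noncentral_t"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap.
#' @return An `effect_size`: `g`, `ci_low`, `ci_high`, `n`, `conf_level`,
#'   `ci_method`.
#' @export
#' @examples
#' hedges_g(c(0.8, 1.1, 0.7, 1.4, 0.9, 1.2))
hedges_g <- function(differences, conf_level = 0.95,
                     ci_method = c("noncentral_t", "bootstrap"),
                     n_boot = 10000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 2L) stop("at least 2 differences are required", call. = FALSE)
  if (anyNA(d) || !all(is.finite(d))) stop("non-finite differences", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("zero variance: Hedges g is undefined", call. = FALSE)
  nu <- n - 1L
  J <- 1 - 3 / (4 * nu - 1)
  g <- mean(d) / s * J

  if (ci_method == "noncentral_t") {
    tstat <- mean(d) / (s / sqrt(n))
    lo_p <- (1 + conf_level) / 2
    hi_p <- (1 - conf_level) / 2
    ncp_bound <- function(target_p) {
      # pt() emits a known precision warning deep in the noncentral tail
      f <- function(ncp) suppressWarnings(stats::pt(tstat, df = nu, ncp = ncp)) - target_p
      span <- abs(tstat) + 20
      stats::uniroot(f, lower = tstat - span, upper = tstat + span,
                     extendInt = "downX", tol = 1e-9)$root
    }
    ci <- sort(c(ncp_bound(lo_p), ncp_bound(hi_p)) / sqrt(n) * J)
  } else {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        db <- d[sample.int(n, n, replace = TRUE)]
        sb <- stats::sd(db)
        if (sb == 0) return(NA_real_)
        mean(db) / sb * J
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boot, c((1 - conf_level) / 2, (1 + conf_level) / 2),
                                 na.rm = TRUE))
  }
  structure(list(
    g = g, ci_low = ci[1], ci_high = ci[2],
    n = n, conf_level = conf_level, ci_method = ci_method
  ), class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> g = %.3f [%.3f, %.3f] (n = %d, %d%% CI, %s)\n",
              x$g, x$ci_low, x$ci_high, x$n, round(100 * x$conf_level), x$ci_method))
  invisible(x)
}
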