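#' JZS Bayes factor for a one-sample / paired t statistic
#'
#' Default Bayes factor `BF10` comparing the alternative with a Cauchy prior
#' of scale `r_scale` on the standardized effect size against the point null,
#' for a one-sample (equivalently, paired) design summarized by its t
#' statistic. The marginal likelihood under the alternative is the
#' Jeffreys-Zellner-Siow integral over the variance-scale mixing parameter
#' `g` (inverse-gamma(1/2, r^2/2) mixing, i.e. the Cauchy prior written as a
#' scale mixture of normals):
#'
#' `BF10 = [ integral_0^Inf (1 + N g)^(-1/2) (1 + t^2 / ((1 + N g) nu))^(-(nu+1)/2)
#'          (2 pi)^(-1/2) r g^(-3/2) exp(-r^2 / (2 g)) dg ]
#'          / (1 + t^2 / nu)^(-(nu+1)/2)`
#'
#' with `N = n`, `nu = n - 1`. Evaluated by adaptive quadrature in log space
#' on the substitution `g = exp(u)`; an integration failure raises an error.
#'
#' @param t Observed t statistic.
#' @param n Sample size (number of pairs), >= 2.
#' @param r_scale Cauchy prior scale (default 0.707, i.e. sqrt(2)/2).
#' @return A `bayes_result`: `bf10`, `r_scale`, `n`, `t`.
#' @export
#' @examples
#' jzs_bf10(t = 2.5, n = 21)
jzs_bf10 <- function(t, n, r_scale = 0.707) {
  stopifnot_scalar_number(t, "t")
  stopifnot_scalar_number(n, "n", positive = TRUE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  stopifnot_scalar_number(r_scale, "r_scale", positive = TRUE)
  nu <- n - 1

  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # log integrand on g = exp(u), including the Jacobian g
  log_f <- function(u) {
    g <- exp(u)
    q <- 1 + n * g * r_scale^2
    val <- -0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (q * nu)) -
      0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) + u
    val[!is.finite(val)] <- -Inf       # overflowed g: integrand vanishes there
    val
  }
  # centre the integrand to avoid under/overflow at large |t|
  u_grid <- seq(-12, 12, length.out = 200)
  shift <- max(log_f(u_grid))
  if (!is.finite(shift)) stop("JZS integrand is not finite", call. = FALSE)
  int <- tryCatch(
    stats::integrate(function(u) exp(log_f(u) - shift), lower = -Inf, upper = Inf,
                     rel.tol = 1e-10, abs.tol = 0),
    error = function(e) stop("JZS quadrature failed: ", conditionMessage(e), call. = FALSE)
  )
  if (int$message != "OK" && int$message != "") {
    stop("JZS quadrature failed: ", int$message, call. = FALSE)
  }
  bf10 <- exp(log(int$value) + shift - log_null)
  if (!is.finite(bf10) || bf10 <= 0) stop("JZS Bayes factor is not finite and positive", call. = FALSE)
  structure(list(bf10 = bf10, r_scale = r_scale, n = n, t = t), class = "bayes_result")
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("<bayes_result> BF10 = %.4g (t = %.3f, n = %d, r = %g)\n",
              x$bf10, x$t, x$n, x$r_scale))
  invisible(x)
}

#' Classify a Bayes factor into evidence categories
#'
#' `BF10 < 1/3` is moderate evidence for the null, `BF10 > 3` moderate
#' evidence for the alternative, anything in between (including the exact
#' boundaries) is inconclusive.
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character vector in `{"supports_null", "inconclusive",
#'   "supports_alternative"}`.
#' @export
classify_evidence <- function(bf10) {
  if (any(!is.finite(bf10)) || any(bf10 <= 0)) stop("bf10 must be positive and finite", call. = FALSE)
  ifelse(bf10 < 1 / 3, "supports_null",
         ifelse(bf10 > 3, "supports_alternative", "inconclusive"))
}

#' Tabulate Bayes factor evidence by region of interest
#'
#' Per-ROI counts (and integer-rounded percentages) of nodes with moderate
#' evidence for the null (`BF10 < 1/3`) and for the alternative (`BF10 > 3`).
#'
#' @param bf_per_node Named numeric vector of BF10 values (names = node ids).
#' @param roi_membership Named character vector mapping every node id to an
#'   ROI label.
#' @return Data frame of class `evidence_table` with columns `roi`,
#'   `n_vertices`, `n_bf_below_third`, `pct_below_third`, `n_bf_above_three`,
#'   `pct_above_three`.
#' @export
tabulate_evidence <- function(bf_per_node, roi_membership) {
  if (is.null(names(bf_per_node)) || is.null(names(roi_membership))) {
    stop("both inputs must be named by node id", call. = FALSE)
  }
  missing_roi <- setdiff(names(bf_per_node), names(roi_membership))
  if (length(missing_roi)) {
    stop("node(s) missing from roi_membership: ",
         paste(utils::head(missing_roi, 5), collapse = ","), call. = FALSE)
  }
  cls <- classify_evidence(bf_per_node)
  roi <- unname(roi_membership[names(bf_per_node)])
  rois <- unique(unname(roi_membership))
  rows <- lapply(rois, function(rr) {
    in_roi <- roi == rr
    nv <- sum(in_roi)
    nb <- sum(in_roi & cls == "supports_null")
    na_ <- sum(in_roi & cls == "supports_alternative")
    data.frame(
      roi = rr, n_vertices = nv,
      n_bf_below_third = nb,
      pct_below_third = if (nv > 0) as.integer(round(100 * nb / nv)) else 0L,
      n_bf_above_three = na_,
      pct_above_three = if (nv > 0) as.integer(round(100 * na_ / nv)) else 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evidence_table", "data.frame")
  out
}
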