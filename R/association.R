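#' Loess curve of outcome against a predictor
#'
#' Locally weighted least squares (tricube weights, degree-1 local fits by
#' default) evaluated on an even grid spanning the observed predictor
#' range; the standard nonparametric view of the entropy-outcome relation.
#'
#' @param x,y paired observations, `n >= 10`.
#' @param span fraction of the data in each local fit, in (0, 1\].
#' @param degree local polynomial degree (1 = moving least squares lines).
#' @param n_grid number of evaluation points.
#' @return data frame of class `smooth_curve` with columns `x`, `fitted`.
#' @export
loess_curve <- function(x, y, span = 0.75, degree = 1L, n_grid = 100L) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 10L) stop("need at least 10 observations")
  if (!is.finite(span) || span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (length(unique(x)) == 1L) stop("x is degenerate (all values equal)")
  fit <- loess(y ~ x, span = span, degree = degree, family = "gaussian",
               surface = "direct")
  grid <- seq(min(x), max(x), length.out = n_grid)
  out <- data.frame(x = grid, fitted = predict(fit, newdata = data.frame(x = grid)))
  class(out) <- c("smooth_curve", "data.frame")
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  out
}

.wald_summary <- function(fit, term, knots = NULL) {
  cf <- coef(summary(fit))
  ci <- confint(fit, term, level = 0.95)
  structure(list(beta_entropy = unname(cf[term, "Estimate"]),
                 ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]),
                 p_value = unname(cf[term, "Pr(>|t|)"]),
                 r_squared = summary(fit)$r.squared,
                 knots = knots,
                 model = fit),
            class = "association_fit")
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf("entropy coefficient: beta = %.1f (95%% CI %.1f to %.1f), p = %.3g, R2 = %.2f\n",
              x$beta_entropy, x$ci_low, x$ci_high, x$p_value, x$r_squared))
  if (!is.null(x$knots))
    cat("adjusted for mean illness score, RCS knots at",
        paste(signif(x$knots, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Univariate regression of the outcome composite on entropy
#'
#' Ordinary least squares with a Wald-style 95% confidence interval
#' (t quantiles, homoskedastic errors).
#'
#' @param composite numeric outcome (composite rank sum).
#' @param entropy numeric predictor (nats).
#' @return an `association_fit`: `beta_entropy`, `ci_low`, `ci_high`,
#'   `p_value`, `r_squared`, and the underlying `lm`.
#' @export
fit_univariate <- function(composite, entropy) {
  if (length(composite) != length(entropy)) stop("inputs must be paired")
  if (any(!is.finite(composite)) || any(!is.finite(entropy)))
    stop("inputs must be finite")
  if (length(composite) < 3L) stop("need at least 3 observations")
  fit <- lm(composite ~ entropy)
  .wald_summary(fit, "entropy")
}

#' Restricted cubic spline basis with three knots
#'
#' Natural cubic spline constrained to be linear beyond the boundary
#' knots. For knots k1 < k2 < k3 the two design columns are x itself and
#'
#' `[(x-k1)+^3 - (x-k2)+^3 (k3-k1)/(k3-k2) + (x-k3)+^3 (k2-k1)/(k3-k2)] / (k3-k1)^2`
#'
#' which vanishes for x <= k1 and is linear for x >= k3.
#'
#' @param x numeric vector.
#' @param knots three strictly increasing values.
#' @return n x 2 matrix with columns `lin`, `nonlin`.
#' @export
rcs_basis <- function(x, knots) {
  knots <- as.numeric(knots)
  if (length(knots) != 3L || any(!is.finite(knots)) ||
      is.unsorted(knots, strictly = TRUE))
    stop("knots must be three strictly increasing values")
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  pos3 <- function(u) pmax(u, 0)^3
  nonlin <- (pos3(x - k1) -
               pos3(x - k2) * (k3 - k1) / (k3 - k2) +
               pos3(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(lin = x, nonlin = nonlin)
}

#' Entropy-outcome regression adjusted for mean illness score
#'
#' Least squares of the composite on entropy plus a 3-knot restricted
#' cubic spline in the mean illness score. Knots default to the 0.10,
#' 0.50, 0.90 quantiles of the adjuster. A constant adjuster degenerates
#' gracefully to the univariate model; any other rank deficiency is an
#' error naming the aliased columns.
#'
#' @param composite,entropy,mean_score paired numeric vectors.
#' @param knots optional three knot values; computed from `mean_score`
#'   when `NULL`.
#' @return an `association_fit` with the knots recorded.
#' @export
fit_adjusted <- function(composite, entropy, mean_score, knots = NULL) {
  n <- length(composite)
  if (length(entropy) != n || length(mean_score) != n)
    stop("inputs must be paired")
  if (any(!is.finite(c(composite, entropy, mean_score))))
    stop("inputs must be finite")
  if (is.null(knots)) {
    knots <- unname(quantile(mean_score, c(0.10, 0.50, 0.90), type = 7))
    if (is.unsorted(knots, strictly = TRUE)) {
      # adjuster too concentrated for a spline: fall back to univariate
      out <- fit_univariate(composite, entropy)
      out$knots <- NULL
      return(out)
    }
  }
  B <- rcs_basis(mean_score, knots)
  X <- cbind(entropy = entropy, score_lin = B[, "lin"],
             score_nonlin = B[, "nonlin"])
  d <- as.data.frame(X)
  d$composite <- composite
  fit <- lm(composite ~ entropy + score_lin + score_nonlin, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear design; aliased terms: ", paste(bad, collapse = ", "))
  }
  .wald_summary(fit, "entropy", knots = knots)
}
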