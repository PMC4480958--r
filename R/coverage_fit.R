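#' Fit a power-law decay to a donors-vs-mutations curve
#'
#' Models the fraction of donors y recovered by a fraction of somatic
#' mutations x as `y = A * x^b`, fitted by ordinary least squares on
#' (log x, log y). The two-parameter power law is an interpretation: it is
#' the minimal monotone family able to express both fast-saturating
#' regimes (a tiny mutation fraction covering nearly all donors) and slow
#' ones (most mutations needed); the underlying data do not prescribe a
#' functional form. Points with x = 0 or y = 0 are excluded from the log
#' fit (but see [mutation_fraction_at_coverage()], which still uses them
#' for interpolation); their number is recorded.
#'
#' @param points data.frame with columns `mutation_fraction` and
#'   `donor_fraction`, e.g. from [donors_vs_mutations()].
#' @param min_points minimum usable (positive) points; default 4. Fewer
#'   points refuse the fit with an error naming the scope.
#' @param scope label used in messages and the result.
#' @return A `coverage_fit`: list with `scope`, `model`, `amplitude` (A),
#'   `exponent` (b), `n_points`, `n_dropped`, and `rss` (residual sum of
#'   squares in log-log space).
#' @export
fit_coverage_model <- function(points, min_points = 4L, scope = "catalog") {
  points <- as.data.table(points)
  stopifnot(all(c("mutation_fraction", "donor_fraction") %in% names(points)))
  use <- points$mutation_fraction > 0 & points$donor_fraction > 0
  n_use <- sum(use)
  if (n_use < min_points) {
    stop(sprintf(
      "fit refused for scope '%s': %d usable point(s) < minimum of %d",
      scope, n_use, min_points))
  }
  lx <- log(points$mutation_fraction[use])
  ly <- log(points$donor_fraction[use])
  fit <- lm(ly ~ lx)
  structure(list(scope = scope, model = "power-law",
                 amplitude = unname(exp(coef(fit)[1L])),
                 exponent = unname(coef(fit)[2L]),
                 n_points = n_use, n_dropped = sum(!use),
                 rss = sum(fit$residuals^2)),
            class = "coverage_fit")
}

#' @export
print.coverage_fit <- function(x, ...) {
  cat(sprintf(
    "<coverage_fit> scope %s: donor_fraction = %.4g * mutation_fraction^%.4g (n = %d, log-log RSS = %.3g)\n",
    x$scope, x$amplitude, x$exponent, x$n_points, x$rss))
  invisible(x)
}

#' Mutation fraction needed to cover a target fraction of donors
#'
#' Estimates the fraction of somatic mutations whose carriers include the
#' target fraction of donors (default 95%). Observed data win over the
#' model: when the target donor fraction is bracketed by observed points
#' the estimate is a monotone linear interpolation in mutation fraction
#' (method `"interpolated"`); otherwise the fitted power law is inverted,
#' `x = (target / A)^(1/b)` (method `"extrapolated"`), clamped to (0, 1].
#' Donor fractions are made non-decreasing in mutation fraction by a
#' running maximum before interpolating, so numerically flat or jittered
#' curves behave monotonically.
#'
#' @inheritParams fit_coverage_model
#' @param fit optional `coverage_fit` used when the target is not
#'   bracketed; if absent in that situation the estimate is refused.
#' @param target_donor_fraction target in (0, 1); default 0.95.
#' @return list with `mutation_fraction` and `method`
#'   (`"interpolated"` or `"extrapolated"`).
#' @export
mutation_fraction_at_coverage <- function(points, fit = NULL,
                                          target_donor_fraction = 0.95) {
  stopifnot(target_donor_fraction > 0, target_donor_fraction < 1)
  points <- as.data.table(points)[order(mutation_fraction)]
  x <- points$mutation_fraction
  y <- cummax(points$donor_fraction)
  target <- target_donor_fraction
  if (length(x) > 0L && target >= y[1L] && target <= y[length(y)]) {
    i <- which(y >= target)[1L]
    xt <- if (y[i] == target || i == 1L) {
      x[i]
    } else {
      x[i - 1L] + (x[i] - x[i - 1L]) * (target - y[i - 1L]) / (y[i] - y[i - 1L])
    }
    return(list(mutation_fraction = min(max(xt, 0), 1),
                method = "interpolated"))
  }
  if (is.null(fit)) {
    stop("target donor fraction ", target,
         " not bracketed by observed points and no fit supplied")
  }
  stopifnot(inherits(fit, "coverage_fit"))
  if (fit$exponent <= 0) {
    if (fit$amplitude >= target) {
      # flat or decreasing fitted curve already above the target everywhere
      return(list(mutation_fraction = .Machine$double.eps,
                  method = "extrapolated"))
    }
    stop("target donor fraction ", target,
         " unreachable under the fitted model for scope '", fit$scope, "'")
  }
  xt <- (target / fit$amplitude)^(1 / fit$exponent)
  list(mutation_fraction = min(max(xt, .Machine$double.xmin), 1),
       method = "extrapolated")
}
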