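#' Linear-quadratic cell survival
#'
#' The standard radiobiological dose-response S = exp(-alpha*D - beta*D^2),
#' with alpha the linear and beta the quadratic killing component. Negative
#' coefficients are permitted: fitted values for some cell line / assay
#' combinations are negative.
#'
#' @param dose dose vector in Gy.
#' @param alpha linear coefficient, 1/Gy.
#' @param beta quadratic coefficient, 1/Gy^2.
#' @return surviving fractions.
#' @export
lq_survival <- function(dose, alpha, beta) {
  exp(-alpha * dose - beta * dose^2)
}

#' Surviving fraction from colony counts
#'
#' SF = (colonies / cells plated) irradiated over (colonies / cells plated)
#' untreated, the clonogenic (colony formation assay) definition.
#'
#' @param colonies_t,plated_t colonies counted and cells plated, treated arm.
#' @param colonies_0,plated_0 colonies counted and cells plated, untreated arm.
#' @return surviving fraction(s).
#' @examples
#' surviving_fraction(50, 500, 100, 250)  # 0.25
#' @export
surviving_fraction <- function(colonies_t, plated_t, colonies_0, plated_0) {
  if (any(plated_t <= 0) || any(plated_0 <= 0)) {
    stop("plated cell numbers must be > 0")
  }
  if (any(colonies_0 <= 0)) {
    stop("untreated colony count must be > 0 (plating efficiency undefined)")
  }
  (colonies_t / plated_t) / (colonies_0 / plated_0)
}

#' Surviving fraction from well counts
#'
#' Cell-count analogue of the clonogenic surviving fraction: the mean count
#' of treated wells relative to the mean count of untreated wells.
#'
#' @param treated,untreated numeric vectors of per-well counts (>= 1 well each).
#' @return surviving fraction.
#' @export
sf_from_counts <- function(treated, untreated) {
  if (!length(treated) || !length(untreated)) {
    stop("need at least one well per arm")
  }
  m0 <- mean(untreated)
  if (m0 == 0) stop("mean untreated count is zero; surviving fraction undefined")
  mean(treated) / m0
}

#' Fit the linear-quadratic dose-response model
#'
#' Least-squares fit of -ln(S) on D and D^2 with no intercept, which forces
#' S(0) = 1 and has a closed-form solution admitting negative coefficients.
#' Replicate surviving fractions at the same dose enter as individual
#' points. R^2 is reported on the -ln(S) scale, where the model is linear.
#' A nonlinear least-squares option on the natural S scale is available.
#'
#' @param dose dose vector, Gy; at least 3 distinct doses required.
#' @param sf surviving fractions, all > 0 (the log transform must exist).
#' @param method "loglinear" (default) or "nls" (Levenberg-Marquardt
#'   nonlinear least squares on the natural S scale).
#' @return object of class `lq_fit`: alpha, beta, se_alpha, se_beta,
#'   r_squared, sf2, n, method.
#' @examples
#' d <- 0:8
#' fit_lq(d, lq_survival(d, 0.22, 0.05))
#' @export
fit_lq <- function(dose, sf, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(dose) != length(sf)) stop("dose and sf lengths differ")
  if (any(sf <= 0)) stop("all surviving fractions must be > 0 for LQ fitting")
  if (length(unique(dose)) < 3L) stop("need at least 3 distinct doses")
  y <- -log(sf)
  d2 <- dose^2
  X <- cbind(dose = dose, d2 = d2)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  alpha <- unname(cf["dose"]); beta <- unname(cf["d2"])
  # closed-form coefficient covariance; avoids summary.lm's perfect-fit
  # warning on noiseless curves, where the residual variance is ~0
  dof <- length(y) - 2L
  s2 <- if (dof > 0) sum(fit$residuals^2) / dof else NA_real_
  covb <- s2 * chol2inv(qr.R(fit$qr))
  se_alpha <- sqrt(covb[1, 1]); se_beta <- sqrt(covb[2, 2])
  if (method == "nls") {
    nfit <- minpack.lm::nlsLM(sf ~ exp(-a * dose - b * d2),
                              start = list(a = alpha, b = beta),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    ncf <- summary(nfit)$coefficients
    alpha <- ncf["a", "Estimate"]; beta <- ncf["b", "Estimate"]
    se_alpha <- ncf["a", "Std. Error"]; se_beta <- ncf["b", "Std. Error"]
  }
  resid <- y - (alpha * dose + beta * d2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else NA_real_
  out <- list(alpha = alpha, beta = beta,
              se_alpha = se_alpha, se_beta = se_beta,
              r_squared = r2, sf2 = exp(-2 * alpha - 4 * beta),
              n = length(dose), method = method)
  class(out) <- "lq_fit"
  out
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("Linear-quadratic fit (%s, n = %d points)\n", x$method, x$n))
  cat(sprintf("  alpha = %.4f +/- %.4f 1/Gy\n", x$alpha, x$se_alpha))
  cat(sprintf("  beta  = %.4f +/- %.4f 1/Gy^2\n", x$beta, x$se_beta))
  cat(sprintf("  R^2 (on -ln S) = %s\n",
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  cat(sprintf("  SF2 = %.3f\n", x$sf2))
  invisible(x)
}

#' Predicted surviving fraction from a fitted LQ model
#'
#' @param fit an `lq_fit` object (or any list with alpha and beta).
#' @param dose dose vector, Gy.
#' @return predicted surviving fractions; 1 at dose 0 by construction.
#' @export
predict_sf <- function(fit, dose) {
  lq_survival(dose, fit$alpha, fit$beta)
}

#' Compare surviving fractions measured by two assays
#'
#' Ordinary least-squares regression of assay B on assay A over
#' dose-matched surviving fraction pairs, with R^2; the cross-assay
#' agreement summary used to benchmark a high-throughput readout against
#' the clonogenic gold standard.
#'
#' @param sf_a,sf_b paired surviving fractions (>= 3 pairs).
#' @return list with slope, intercept, r_squared, n.
#' @export
compare_assays <- function(sf_a, sf_b) {
  if (length(sf_a) != length(sf_b)) stop("paired vectors must match in length")
  if (length(sf_a) < 3L) stop("need at least 3 paired surviving fractions")
  if (stats::var(sf_a) == 0) stop("zero variance in reference assay values")
  fit <- stats::lm(sf_b ~ sf_a)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(sf_a, sf_b)^2,
       n = length(sf_a))
}
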