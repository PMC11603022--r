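#' Single-component 3D diffusion correlation model
#'
#' `G(tau) = G0 * (1 + tau/tauD)^-1 * (1 + tau/(kappa^2 tauD))^-1/2`,
#' the free-diffusion correlation function of one species through a 3D
#' Gaussian volume of aspect ratio kappa.
#'
#' @param tau Lag times (s).
#' @param G0 Zero-lag amplitude.
#' @param tauD Diffusion time (s).
#' @param kappa Axial/lateral aspect ratio of the observation volume.
#' @export
diffusion_model <- function(tau, G0, tauD, kappa) {
  G0 / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
}

#' Fit a diffusion model to a correlation curve
#'
#' Weighted least-squares fit of the one-component (or, for a mixture of
#' bound and free sensor, two-component) 3D diffusion model to one
#' channel of a correlation curve. Weights are taken from the per-lag
#' standard errors when the curve was computed with segmentation. The
#' fitted amplitude `G0` is the extrapolated zero-lag value used by the
#' readout; it is never read off the (shot-noise dominated) first lag
#' point.
#'
#' @param curve A `"correlation_curve"`.
#' @param channel `"GG"`, `"GR"` or `"Gcc"`.
#' @param kappa Aspect ratio of the observation volume (fixed, not
#'   fitted).
#' @param components 1 or 2. The two-component model is
#'   `G0 (f S(tau; tauD1) + (1 - f) S(tau; tauD2))` with shape `S` as in
#'   [diffusion_model()].
#' @param start Optional named list of start values.
#' @return An object of class `"fcs_fit"` with `print`, `summary`,
#'   `coef`, `predict` and `residuals` methods. Coefficients: `G0`,
#'   `tauD` (1 component) or `G0`, `f`, `tauD1`, `tauD2` (2 components);
#'   standard errors in `$se`.
#' @export
fit_diffusion <- function(curve, channel = c("GR", "GG", "Gcc"),
                          kappa = 5, components = 1, start = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(curve, "correlation_curve"))
  tau <- curve$lag_s
  g <- curve[[channel]]
  if (length(tau) < 10) stop("need at least 10 lag points")
  se_col <- paste0("se_", channel)
  w <- if (se_col %in% names(curve) && all(curve[[se_col]] > 0))
    1 / curve[[se_col]]^2 else rep(1, length(tau))

  g0_init <- max(mean(g[seq_len(min(3, length(g)))]), 1e-6)
  half_idx <- which(g < g0_init / 2)
  tauD_init <- if (length(half_idx)) tau[half_idx[1]] else stats::median(tau)
  dat <- data.frame(tau = tau, g = g)

  if (components == 1) {
    st <- list(G0 = g0_init, tauD = tauD_init)
    if (!is.null(start)) st[names(start)] <- start
    fit <- try(minpack.lm::nlsLM(
      g ~ G0 / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD))),
      data = dat, start = st, weights = w,
      lower = c(G0 = 0, tauD = tau[1] / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else if (components == 2) {
    st <- list(G0 = g0_init, f = 0.5, tauD1 = tauD_init / 10,
               tauD2 = tauD_init * 2)
    if (!is.null(start)) st[names(start)] <- start
    shape <- function(tau, tauD)
      1 / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
    fit <- try(minpack.lm::nlsLM(
      g ~ G0 * (f * shape(tau, tauD1) + (1 - f) * shape(tau, tauD2)),
      data = dat, start = st, weights = w,
      lower = c(G0 = 0, f = 0, tauD1 = tau[1] / 10, tauD2 = tau[1] / 10),
      upper = c(G0 = Inf, f = 1, tauD1 = Inf, tauD2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
  } else stop("components must be 1 or 2")

  if (inherits(fit, "try-error"))
    stop("diffusion fit did not converge (start: ",
         paste(names(st), signif(unlist(st), 3), sep = " = ", collapse = ", "),
         "); residual spread ", signif(stats::sd(g), 3))

  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  structure(list(coefficients = est, se = se, channel = channel,
                 kappa = kappa, components = components,
                 fitted = stats::fitted(fit), residuals = stats::resid(fit),
                 tau = tau, g = g, nls = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS diffusion fit (", x$components, "-component, channel ",
      x$channel, ")\n", sep = "")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) object$coefficients

#' @export
summary.fcs_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  cat("FCS diffusion fit, channel", object$channel, "\n")
  print(signif(tab, 5))
  invisible(tab)
}

#' @export
predict.fcs_fit <- function(object, tau = NULL, ...) {
  if (is.null(tau)) return(object$fitted)
  cf <- as.list(object$coefficients)
  if (object$components == 1)
    return(diffusion_model(tau, cf$G0, cf$tauD, object$kappa))
  cf$G0 * (cf$f * diffusion_model(tau, 1, cf$tauD1, object$kappa) +
           (1 - cf$f) * diffusion_model(tau, 1, cf$tauD2, object$kappa))
}

#' @export
residuals.fcs_fit <- function(object, ...) object$residuals

#' Zero-lag amplitude ratio Gcc(0)/GR(0)
#'
#' Fits single-component diffusion models to the cross-correlation and
#' the red autocorrelation and returns the ratio of the fitted zero-lag
#' amplitudes. Normalizing the cross-correlation amplitude by the red
#' one cancels the labeled-vesicle concentration (and labeling
#' inaccuracies); in the ideal uniformly-labeled dilute limit the ratio
#' equals the fraction of green particles (sensors) co-diffusing with
#' red particles (LUVs).
#'
#' With Poisson-distributed tracer dyes the dye-number dispersion
#' inflates GR(0) by (1 + 1/mu) (mu = mean dyes per vesicle), biasing
#' the raw ratio to `f_bound * mu/(1+mu)`; `brightness_correction`
#' multiplies it back. The rate estimators use only ratios of readouts,
#' so they are insensitive to this choice.
#'
#' @param curve A segmented `"correlation_curve"` (see
#'   [correlate_multitau()]).
#' @param kappa Aspect ratio for the fits.
#' @param brightness_correction Multiplicative amplitude correction
#'   (1 = none; `1 + 1/mu` to undo Poisson dye-loading dispersion).
#' @param average_directions Average the forward (green -> red) and
#'   reverse cross-correlations before fitting; they estimate the same
#'   quantity on a stationary trace, so averaging lowers the estimator
#'   variance.
#' @return List: `ratio`, plus the two `fcs_fit` objects.
#' @export
readout_ratio <- function(curve, kappa = 5, brightness_correction = 1,
                          average_directions = TRUE) {
  if (all(is.na(curve$GR)) || max(abs(curve$GR), na.rm = TRUE) < 1e-12)
    stop("GR(0) <= 0: no red species detected")
  fit_r <- fit_diffusion(curve, "GR", kappa = kappa)
  g0_r <- coef(fit_r)[["G0"]]
  if (g0_r <= 0) stop("GR(0) <= 0: no red species detected")
  if (average_directions && "Gcc_rev" %in% names(curve) &&
      all(is.finite(curve$Gcc_rev)))
    curve$Gcc <- (curve$Gcc + curve$Gcc_rev) / 2
  fit_cc <- fit_diffusion(curve, "Gcc", kappa = kappa,
                          start = list(tauD = coef(fit_r)[["tauD"]]))
  ratio <- coef(fit_cc)[["G0"]] / g0_r * brightness_correction
  list(ratio = max(ratio, 0), fit_cc = fit_cc, fit_r = fit_r)
}
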