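#' Biosensor binding model
#'
#' A 1:1 equilibrium binding model for a fluorescent lipid biosensor:
#' one sensor molecule occupies one accessible cargo lipid. The model is
#' solved exactly (quadratic root of S + L <-> SL), not in the dilute
#' approximation, so depletion of either partner is handled.
#'
#' The default dissociation constants are calibration choices of this
#' package, not measured affinities: they are set so that at 50 uM total
#' lipid, 1 mol% cargo falls in the responsive range of the sensor while
#' 3-4 mol% saturates it, which is what makes the extraction and release
#' assay regimes work.
#'
#' @param sensor `"C2Lact"` (PS reader) or `"SidC"` (PI4P reader).
#' @param kd_nM Dissociation constant; defaults 50 nM (C2Lact) and
#'   40 nM (SidC).
#' @param sensor_nM Total sensor concentration.
#' @param sites_per_cargo Binding sites contributed per accessible cargo
#'   lipid (default 1; monovalent reader).
#' @return An object of class `"sensor_model"`.
#' @export
sensor_model <- function(sensor = c("C2Lact", "SidC"), kd_nM = NULL,
                         sensor_nM = NULL, sites_per_cargo = 1) {
  sensor <- match.arg(sensor)
  if (is.null(kd_nM)) kd_nM <- c(C2Lact = 50, SidC = 40)[[sensor]]
  if (is.null(sensor_nM)) sensor_nM <- c(C2Lact = 50, SidC = 100)[[sensor]]
  stopifnot(kd_nM > 0, sensor_nM >= 0, sites_per_cargo > 0)
  structure(list(sensor = sensor, sensed_cargo = sensed_cargo(sensor),
                 kd_nM = kd_nM, sensor_nM = sensor_nM,
                 sites_per_cargo = sites_per_cargo),
            class = "sensor_model")
}

# exact bound complex concentration for S + L <-> SL (all nM)
bound_complex <- function(S, L, kd) {
  if (S <= 0 || L <= 0) return(0)
  b <- S + L + kd
  (b - sqrt(b * b - 4 * S * L)) / 2
}

#' Fraction of sensor bound at a given accessible cargo concentration
#'
#' @param accessible_cargo_nM Accessible cargo (= binding site source)
#'   concentration in nM; may be a vector.
#' @param model A [sensor_model()].
#' @return Bound sensor fraction in `[0, 1]`.
#' @examples
#' m <- sensor_model("C2Lact", kd_nM = 10, sensor_nM = 50)
#' bound_sensor_fraction(250, m)   # ~0.953: 47.65 of 50 nM bound
#' @export
bound_sensor_fraction <- function(accessible_cargo_nM, model) {
  stopifnot(inherits(model, "sensor_model"))
  if (any(accessible_cargo_nM < 0)) stop("cargo concentration must be >= 0")
  if (model$sensor_nM == 0) return(rep(0, length(accessible_cargo_nM)))
  L <- accessible_cargo_nM * model$sites_per_cargo
  vapply(L, function(l)
    bound_complex(model$sensor_nM, l, model$kd_nM) / model$sensor_nM,
    numeric(1))
}

#' Predicted calibration curve of the FCCS readout
#'
#' Maps a grid of cargo mol percents in a LUV template to the predicted
#' readout Gcc(0)/GR(0), which in the ideal dilute limit equals the
#' bound sensor fraction. This reproduces the saturating calibration
#' curves that define the extraction (responsive) and release
#' (saturated) regimes.
#'
#' @param model A [sensor_model()].
#' @param mol_percent_grid Nonnegative cargo mol percents.
#' @param luv_template A [luv_population()] supplying the total lipid
#'   concentration and accessible fraction.
#' @return Data frame with columns `mol_percent`, `accessible_nM`,
#'   `readout`; class `"calibration_curve"`.
#' @export
calibration_curve <- function(model, mol_percent_grid, luv_template) {
  stopifnot(inherits(model, "sensor_model"),
            inherits(luv_template, "luv_population"))
  if (any(mol_percent_grid < 0)) stop("mol percents must be >= 0")
  acc <- luv_template$accessible_fraction * (mol_percent_grid / 100) *
    luv_template$total_lipid_nM
  out <- data.frame(mol_percent = mol_percent_grid,
                    accessible_nM = acc,
                    readout = bound_sensor_fraction(acc, model))
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' @export
plot.calibration_curve <- function(x, ...) {
  plot(x$mol_percent, x$readout, type = "b", pch = 16,
       xlab = "cargo (mol%)", ylab = "predicted Gcc(0)/GR(0)", ...)
  invisible(x)
}
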