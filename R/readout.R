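#' Readout series
#'
#' A time series of the FCCS readout Gcc(0)/GR(0) relative to protein
#' addition at t = 0. The point at `time_min = 0` with
#' `phase = "baseline"` is the pre-addition value that the rate
#' estimators normalise by.
#'
#' @param time_min Times in minutes.
#' @param readout Gcc(0)/GR(0) values (>= 0).
#' @param se Optional per-point standard errors.
#' @param phase Optional character vector (`"baseline"`/`"assay"`).
#' @return Data frame of class `"readout_series"`.
#' @export
readout_series <- function(time_min, readout, se = NA_real_, phase = NULL) {
  if (any(readout < -1e-12, na.rm = TRUE)) stop("readout values must be >= 0")
  if (is.null(phase)) phase <- ifelse(time_min == 0, "baseline", "assay")
  out <- data.frame(time_min = time_min, readout = pmax(readout, 0),
                    se = se, phase = phase)
  class(out) <- c("readout_series", "data.frame")
  out
}

#' @export
plot.readout_series <- function(x, ...) {
  plot(x$time_min, x$readout, type = "b", pch = 16,
       xlab = "time after protein addition (min)",
       ylab = "Gcc(0)/GR(0)", ylim = c(0, max(x$readout) * 1.05), ...)
  if (any(is.finite(x$se)))
    arrows(x$time_min, x$readout - x$se, x$time_min, x$readout + x$se,
           angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Ideal readout series from a kinetic trajectory
#'
#' Maps the kinetic state through the exact sensor isotherm to the
#' predicted Gcc(0)/GR(0): the fraction of biosensor bound to the
#' labeled donor vesicles. The baseline point is the isotherm of the
#' initial cargo pools before any transporter acts.
#'
#' For a labeled-transporter binding assay (scenario with
#' `sensor_nM = 0`), the readout is instead the fraction of transporter
#' adsorbed to the labeled membrane, which is what the cross-correlation
#' amplitude of such an experiment reports.
#'
#' @param traj A [simulate_kinetics()] trajectory.
#' @return A [readout_series()].
#' @export
readout_from_trajectory <- function(traj) {
  net <- attr(traj, "network")
  if (net$sensor$sensor_nM <= 0) {
    occ <- protein_occupancy(traj)
    return(readout_series(occ$time_min, occ$on_A))
  }
  r <- vapply(seq_len(nrow(traj)), function(i) {
    state <- unlist(traj[i, -1])
    part <- sensor_partition(state, net)
    L <- sum(part$ligand_on)
    if (L <= 0) return(0)
    part$bound_on[["A"]] / net$sensor$sensor_nM
  }, numeric(1))
  # baseline: isotherm of the untouched pools
  part0 <- sensor_partition(net$state0, net)
  baseline <- if (sum(part0$ligand_on) > 0)
    part0$bound_on[["A"]] / net$sensor$sensor_nM else 0
  if (traj$time_min[1] == 0) r[1] <- baseline
  readout_series(traj$time_min, r)
}
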