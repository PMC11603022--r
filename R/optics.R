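#' Confocal optics configuration
#'
#' Idealized two-channel confocal detection: a 3D Gaussian observation
#' volume with lateral 1/e^2 radius `w0_um` and axial elongation
#' `kappa`, perfectly separated green/red channels (pulsed interleaved
#' excitation is idealized as zero bleed-through), Poisson photon
#' statistics, and a periodic cubic simulation box. All values are
#' synthetic defaults of this package; the published assays report the
#' hardware, not the calibrated volume.
#'
#' @param w0_um Lateral 1/e^2 radius (um).
#' @param kappa Axial/lateral aspect ratio.
#' @param brightness_g,brightness_r Counts/s per fluorophore at the
#'   focus center.
#' @param bin_width_s Photon binning time (s).
#' @param box_um Side of the periodic cube (um); must be at least
#'   10 * w0 so the volume is dilute in the box.
#' @return An object of class `"optics_config"`.
#' @export
optics_config <- function(w0_um = 0.25, kappa = 5,
                          brightness_g = 3e4, brightness_r = 3e4,
                          bin_width_s = 1e-5, box_um = 3) {
  stopifnot(w0_um > 0, kappa > 0, brightness_g > 0, brightness_r > 0,
            bin_width_s > 0)
  if (box_um < 10 * w0_um)
    stop("box must be at least 10 * w0 (", 10 * w0_um, " um)")
  structure(list(w0_um = w0_um, kappa = kappa,
                 brightness_g = brightness_g, brightness_r = brightness_r,
                 bin_width_s = bin_width_s, box_um = box_um),
            class = "optics_config")
}

#' Effective observation volume
#'
#' The FCS effective volume `V_eff = (integral W)^2 / integral W^2` of
#' the 3D Gaussian profile `W`, in femtoliters. With
#' `box_corrected = TRUE` the integrals run over the periodic box
#' actually simulated (the axial tail of the profile is truncated by a
#' finite box, which raises the amplitude slightly); otherwise the
#' infinite-volume value `pi^(3/2) w0^2 z0` is returned.
#'
#' @param optics An [optics_config()].
#' @param box_corrected Account for the finite box.
#' @return Volume in fL (um^3).
#' @export
effective_volume <- function(optics, box_corrected = TRUE) {
  w0 <- optics$w0_um
  z0 <- optics$kappa * w0
  if (!box_corrected) return(pi^1.5 * w0^2 * z0)
  h <- optics$box_um / 2
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  # 1D integrals of exp(-2 x^2 / s^2) and its square over [-h, h]
  i1 <- function(s) s * sqrt(pi / 2) * erf(h * sqrt(2) / s)
  i2 <- function(s) s * sqrt(pi) / 2 * erf(2 * h / s)
  num <- (i1(w0)^2 * i1(z0))^2
  den <- i2(w0)^2 * i2(z0)
  num / den
}

#' Expected particles in the effective volume
#'
#' @param conc_nM Particle concentration in nM.
#' @param optics An [optics_config()].
#' @param box_corrected See [effective_volume()].
#' @return Expected particle number N_eff; for a single uniformly
#'   bright species the fitted correlation amplitude is G(0) = 1/N_eff.
#' @export
n_effective <- function(conc_nM, optics, box_corrected = TRUE) {
  avogadro <- 6.02214076e23
  conc_nM * 1e-9 * avogadro * effective_volume(optics, box_corrected) * 1e-15
}

# molecules expected in the simulation box for a concentration in nM
molecules_in_box <- function(conc_nM, box_um) {
  avogadro <- 6.02214076e23
  conc_nM * 1e-9 * avogadro * box_um^3 * 1e-15
}
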