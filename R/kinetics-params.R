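#' Kinetic parameters of the transporter cycle
#'
#' Rate constants for the mass-action model of the transport cycle:
#' membrane adsorption/desorption of the transporter in each load state,
#' cargo extraction, cargo release, direct exchange at the membrane, and
#' the coefficients of the charge/fluidity modulation. Units: nM and
#' minutes; bimolecular constants in 1/(nM min).
#'
#' The default set is calibrated (see `scripts/calibrate-defaults.R` in
#' the source repository) against three printed kinetic anchors of the
#' assay system: PS extraction from the donor vesicles completes within
#' one minute, PI4P extraction takes about ten minutes, and 20 mol% PS
#' in competitor vesicles suppresses PI4P extraction by the same factor
#' as 1 mol% PI4P suppresses PS extraction. All values are overridable.
#'
#' @param k_on Adsorption rate constant of the transporter to a
#'   membrane, per nM of accessible lipid, 1/(nM min).
#' @param k_off Desorption rate, 1/min.
#' @param k_ext Named vector, extraction rate constants of the
#'   membrane-adsorbed empty transporter, in 1/min per unit cargo mole
#'   fraction of the accessible leaflet: `c(PS = ..., PI4P = ...)`. PS
#'   extraction is much faster than PI4P extraction (the PI4P headgroup
#'   binds deeper and loads slower).
#' @param k_rel Named vector, baseline release rates (1/min) of the
#'   loaded, membrane-adsorbed transporter into that membrane; modulated
#'   by [charge_fluidity_multiplier()].
#' @param k_exch Rate constant of the direct cargo swap at the membrane
#'   (pocket PS exchanged for a membrane PI4P), in 1/min per unit
#'   membrane-PI4P mole fraction; the reverse swap runs at
#'   `k_exch / K_comp`.
#' @param K_comp PI4P:PS affinity ratio of the binding pocket (> 1:
#'   PI4P is the stronger binder).
#' @param charge_coeff Linear coefficient of the membrane charge density
#'   in the release multiplier for the PS-loaded transporter.
#' @param ext_charge_coeff Charged lipids stabilise PS in the bilayer
#'   and damp its (re-)extraction: the PS extraction rate from a
#'   membrane of charge density Q is multiplied by
#'   `1 / (1 + ext_charge_coeff * Q)`.
#' @param fluidity_scores Ordinal tail-class fluidity scores; POPC
#'   (standard) is the reference 1.
#' @param ads_charge_coeff Linear charge-density coefficient of the
#'   adsorption multiplier for the *empty* transporter.
#' @param ads_packing_coeff Additional adsorption coefficient for the
#'   mol fraction of packing-defect (diphytanoyl) lipids, empty
#'   transporter only.
#' @param ads_load_damp Multiplier on `k_on` once the transporter
#'   carries cargo; loaded transporter adheres less, the PI4P-loaded
#'   one least, and its adsorption is taken charge-independent.
#' @param sensor_shielding If `TRUE`, the sensor-bound share of the
#'   cargo pool is unavailable to the transporter (the sensor shields
#'   its lipid). The default `FALSE` lets extraction act on the whole
#'   accessible pool: the transporter removes the lipid and the sensor
#'   re-equilibrates by mass action. Without this, the shielded tail
#'   makes complete extraction of a stoichiometric pool far slower than
#'   observed; mere binding competition without extraction still
#'   produces no readout change either way (non-extractable cargo never
#'   reacts).
#' @return A list of class `"kinetic_params"`.
#' @export
kinetic_params <- function(k_on = 3e-4,
                           k_off = 200,
                           k_ext = c(PS = 40000, PI4P = 5500),
                           k_rel = c(PS = 0.8, PI4P = 0.015),
                           k_exch = 2150,
                           K_comp = 50,
                           charge_coeff = 8,
                           ext_charge_coeff = 6,
                           fluidity_scores = c(fluid = 1.5, standard = 1.0,
                                               rigidifying = 0.3,
                                               packing_defect = 1.0),
                           ads_charge_coeff = 10,
                           ads_packing_coeff = 6,
                           ads_load_damp = c(none = 1, PS = 0.5, PI4P = 0.25),
                           sensor_shielding = FALSE) {
  p <- list(k_on = k_on, k_off = k_off,
            k_ext = k_ext, k_rel = k_rel,
            k_exch = unname(k_exch[1]), K_comp = K_comp,
            charge_coeff = charge_coeff,
            ext_charge_coeff = ext_charge_coeff,
            fluidity_scores = fluidity_scores,
            ads_charge_coeff = ads_charge_coeff,
            ads_packing_coeff = ads_packing_coeff,
            ads_load_damp = ads_load_damp,
            sensor_shielding = isTRUE(sensor_shielding))
  rates <- c(p$k_on, p$k_off, p$k_ext, p$k_rel, p$k_exch)
  if (any(rates < 0)) stop("all rate constants must be >= 0")
  if (p$K_comp <= 0) stop("K_comp must be positive")
  class(p) <- "kinetic_params"
  p
}

#' Charge/fluidity modulation of release and adsorption
#'
#' Multiplicative factor encoding how the acceptor membrane's charged
#' lipids and fluidity modulate the transporter: release of PS-loaded
#' transporter increases with membrane charge density and fluidity;
#' release of the PI4P-loaded transporter responds to fluidity only (its
#' tightened lid is insensitive to non-cargo charge); adsorption of the
#' empty transporter increases with charge density and with
#' packing-defect lipids, while the loaded transporter adsorbs with a
#' damped, charge-independent rate.
#'
#' A pure POPC membrane is the reference: factor 1 for every load state
#' and context.
#'
#' @param composition Named mol-fraction vector of the membrane.
#' @param cargo_loaded `"none"`, `"PS"` or `"PI4P"`.
#' @param params A [kinetic_params()].
#' @param context `"release"` (factor on `k_rel`) or `"adsorption"`
#'   (factor on `k_on`).
#' @return A nonnegative scalar.
#' @examples
#' p <- kinetic_params()
#' charge_fluidity_multiplier(c(POPC = 1), "PS", p)             # 1
#' charge_fluidity_multiplier(c(POPC = .95, POPG = .05), "PS", p) # > 1
#' @export
charge_fluidity_multiplier <- function(composition,
                                       cargo_loaded = c("none", "PS", "PI4P"),
                                       params = kinetic_params(),
                                       context = c("release", "adsorption")) {
  cargo_loaded <- match.arg(cargo_loaded)
  context <- match.arg(context)
  q <- charge_density(composition)
  f <- fluidity_score(composition, params$fluidity_scores)
  if (context == "adsorption") {
    if (cargo_loaded == "none") {
      pd <- packing_defect_fraction(composition)
      return(1 + params$ads_charge_coeff * q + params$ads_packing_coeff * pd)
    }
    return(unname(params$ads_load_damp[[cargo_loaded]]))
  }
  # release context
  if (cargo_loaded == "none") return(1)
  if (cargo_loaded == "PS") return((1 + params$charge_coeff * q) * f)
  f  # PI4P-loaded: fluidity term only
}
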