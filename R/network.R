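#' Build the reaction network for an assay scenario
#'
#' Enumerates the species and mass-action reactions of the transporter
#' cycle for a given scenario: adsorption/desorption of each transporter
#' load state to each membrane, cargo extraction by the membrane-bound
#' empty transporter, cargo release by the loaded one (modulated by the
#' acceptor's charge/fluidity), and the direct cargo exchange at the
#' membrane with forward/reverse ratio set by the PI4P:PS affinity
#' ratio.
#'
#' Species are the accessible outer-leaflet cargo pools per membrane
#' (`PS_A`, `PI4P_B`, ...) and the transporter states `P_<load>_<loc>`
#' with load in `none`, `PS`, `PI4P` and location `sol` (solution) or a
#' membrane. Non-extractable cargo-headgroup lipids (diphytanoyl
#' variants) contribute to the sensor ligand pool and to the membrane
#' charge, but generate no extraction reaction. The biosensor is treated
#' as a fast binding equilibrium: sensor-bound cargo is not extractable,
#' and the bound fraction is recomputed from the exact isotherm at every
#' evaluation rather than carried as a state.
#'
#' @param scenario An [assay_scenario()].
#' @param params A [kinetic_params()].
#' @return An object of class `"reaction_network"`: species names,
#'   initial state (nM), a reaction table, membrane descriptors and the
#'   sensor model.
#' @export
build_network <- function(scenario, params = kinetic_params()) {
  stopifnot(inherits(scenario, "assay_scenario"),
            inherits(params, "kinetic_params"))

  mems <- list(A = scenario$luv_a)
  if (!is.null(scenario$luv_b)) mems$B <- scenario$luv_b

  # which cargo headgroups circulate anywhere (extractable pools or a
  # preloaded transporter can seed them)
  cargos <- character(0)
  for (luv in mems) {
    info <- lipid_info(names(luv$composition))
    sel <- !is.na(info$cargo) & info$extractable & luv$composition > 0
    cargos <- union(cargos, info$cargo[sel])
  }
  if (!is.null(scenario$preincubation)) {
    luv <- scenario$preincubation$luv
    info <- lipid_info(names(luv$composition))
    sel <- !is.na(info$cargo) & info$extractable & luv$composition > 0
    cargos <- union(cargos, info$cargo[sel])
  }
  cargos <- intersect(c("PS", "PI4P"), cargos)

  membranes <- lapply(names(mems), function(mx) {
    luv <- mems[[mx]]
    comp <- luv$composition
    info <- lipid_info(names(comp))
    pools <- vapply(cargos, function(cg) {
      sel <- !is.na(info$cargo) & info$cargo == cg & info$extractable
      luv$accessible_fraction * sum(comp[sel]) * luv$total_lipid_nM
    }, numeric(1))
    static_sensed <- {
      cg <- scenario$sensed_cargo
      sel <- !is.na(info$cargo) & info$cargo == cg & !info$extractable
      luv$accessible_fraction * sum(comp[sel]) * luv$total_lipid_nM
    }
    list(id = mx,
         acc_lipid_nM = luv$accessible_fraction * luv$total_lipid_nM,
         pools = pools,
         static_sensed_nM = static_sensed,
         composition = comp,
         rel_mult = vapply(c(PS = "PS", PI4P = "PI4P"), function(l)
           charge_fluidity_multiplier(comp, l, params, "release"), numeric(1)),
         ext_mult = c(
           PS = 1 / (1 + params$ext_charge_coeff * charge_density(comp)),
           PI4P = 1),
         ads_mult = vapply(c(none = "none", PS = "PS", PI4P = "PI4P"),
           function(l) charge_fluidity_multiplier(comp, l, params, "adsorption"),
           numeric(1)))
  })
  names(membranes) <- names(mems)

  loads <- c("none", cargos)
  locs <- c("sol", names(membranes))
  p_states <- as.vector(outer(loads, locs,
                              function(l, x) paste("P", l, x, sep = "_")))
  cargo_states <- if (length(cargos))
    as.vector(outer(cargos, names(membranes), paste, sep = "_")) else character(0)
  species <- c(cargo_states, p_states)

  state0 <- setNames(numeric(length(species)), species)
  for (mx in names(membranes))
    for (cg in cargos)
      state0[paste(cg, mx, sep = "_")] <- membranes[[mx]]$pools[[cg]]
  state0["P_none_sol"] <- scenario$protein_nM

  # reaction table: mass-action, free_cargo marks a reactant whose
  # sensor-bound share is unavailable
  rxn <- list()
  add <- function(name, k, reactants, products, free_cargo = NA_character_) {
    if (k > 0)
      rxn[[length(rxn) + 1L]] <<- list(name = name, k = k,
                                       reactants = reactants,
                                       products = products,
                                       free_cargo = free_cargo)
  }
  for (mx in names(membranes)) {
    mem <- membranes[[mx]]
    for (l in loads) {
      add(sprintf("adsorb_%s_%s", l, mx),
          params$k_on * mem$acc_lipid_nM * mem$ads_mult[[l]],
          paste("P", l, "sol", sep = "_"), paste("P", l, mx, sep = "_"))
      add(sprintf("desorb_%s_%s", l, mx), params$k_off,
          paste("P", l, mx, sep = "_"), paste("P", l, "sol", sep = "_"))
    }
    # extraction and exchange run at the surface: the encounter rate of
    # an adsorbed transporter with a cargo lipid scales with the cargo's
    # mole fraction in the accessible leaflet, so the bimolecular
    # coefficient is k / (accessible lipid). Charged lipids damp the
    # (re-)extraction of PS from that membrane.
    for (cg in cargos) {
      cx <- paste(cg, mx, sep = "_")
      add(sprintf("extract_%s_%s", cg, mx),
          params$k_ext[[cg]] * mem$ext_mult[[cg]] / mem$acc_lipid_nM,
          c(paste("P_none", mx, sep = "_"), cx),
          paste("P", cg, mx, sep = "_"), free_cargo = cx)
      add(sprintf("release_%s_%s", cg, mx),
          params$k_rel[[cg]] * mem$rel_mult[[cg]],
          paste("P", cg, mx, sep = "_"),
          c(paste("P_none", mx, sep = "_"), cx))
    }
    if (all(c("PS", "PI4P") %in% cargos)) {
      add(sprintf("exchange_fwd_%s", mx), params$k_exch / mem$acc_lipid_nM,
          c(paste("P_PS", mx, sep = "_"), paste("PI4P", mx, sep = "_")),
          c(paste("P_PI4P", mx, sep = "_"), paste("PS", mx, sep = "_")),
          free_cargo = paste("PI4P", mx, sep = "_"))
      add(sprintf("exchange_rev_%s", mx),
          params$k_exch / params$K_comp / mem$acc_lipid_nM,
          c(paste("P_PI4P", mx, sep = "_"), paste("PS", mx, sep = "_")),
          c(paste("P_PS", mx, sep = "_"), paste("PI4P", mx, sep = "_")),
          free_cargo = paste("PS", mx, sep = "_"))
    }
  }

  sensor <- sensor_model(scenario$sensor, sensor_nM = scenario$sensor_nM)

  structure(list(
    species = species, state0 = state0,
    reactions = rxn, membranes = membranes,
    cargos = cargos, loads = loads,
    sensor = sensor, sensed_cargo = scenario$sensed_cargo,
    scenario = scenario, params = params
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  cat("  membranes:", paste(names(x$membranes), collapse = ", "),
      "| circulating cargo:",
      if (length(x$cargos)) paste(x$cargos, collapse = ", ") else "(none)", "\n")
  for (r in x$reactions)
    cat(sprintf("  %-22s k = %-10.4g %s -> %s\n", r$name, r$k,
                paste(r$reactants, collapse = " + "),
                paste(r$products, collapse = " + ")))
  invisible(x)
}

# sensor-bound total and free-factor for the sensed cargo pools.
# Returns list(free_factor, bound_on, ligand_on) where *_on are named by
# membrane; ligand includes the static non-extractable sensed lipids.
sensor_partition <- function(state, network) {
  sm <- network$sensor
  cg <- network$sensed_cargo
  mems <- network$membranes
  lig <- vapply(names(mems), function(mx) {
    dyn <- if (cg %in% network$cargos) state[[paste(cg, mx, sep = "_")]] else 0
    max(dyn, 0) + mems[[mx]]$static_sensed_nM
  }, numeric(1))
  L <- sum(lig)
  if (L <= 0 || sm$sensor_nM <= 0)
    return(list(free_factor = 1, bound_on = setNames(rep(0, length(mems)),
                                                     names(mems)),
                ligand_on = lig))
  b <- bound_complex(sm$sensor_nM, L * sm$sites_per_cargo, sm$kd_nM)
  list(free_factor = max(0, 1 - b / L),
       bound_on = b * lig / L,
       ligand_on = lig)
}
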