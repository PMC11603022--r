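#' Integrate the kinetic model
#'
#' Deterministic mass-action integration of a [build_network()] on a
#' time grid (minutes). The system is closed: each cargo headgroup and
#' the total transporter are conserved, and the integrator tolerances
#' default tight enough that trajectories conserve them to better than
#' 1e-8 relative.
#'
#' If the scenario requests a preincubation, the transporter is first
#' equilibrated with the preincubation LUV population alone; the
#' resulting load-state distribution (and the depleted preincubation
#' pools, when that population is the assay's LUVs B) seeds the main
#' integration at t = 0.
#'
#' @param network A [build_network()].
#' @param t_grid Increasing times in minutes starting at 0 (defaults to
#'   the scenario's grid).
#' @param rtol,atol Integrator tolerances (deSolve::lsoda).
#' @return A `"kinetic_trajectory"`: data frame of times and species
#'   concentrations (nM) with the network attached as an attribute.
#' @examples
#' net <- build_network(scenario_preset("fig4_pi4p_extraction"))
#' traj <- simulate_kinetics(net, t_grid = 0:15)
#' @export
simulate_kinetics <- function(network, t_grid = NULL,
                              rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(t_grid)) t_grid <- network$scenario$t_grid
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0)
    stop("t_grid must be strictly increasing and start at 0")

  state0 <- network$state0
  pre <- network$scenario$preincubation
  if (!is.null(pre)) state0 <- preincubated_state(network, rtol, atol)

  rhs <- make_rhs(network)
  out <- deSolve::lsoda(y = state0, times = t_grid, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  attr_diag <- attributes(out)$istate
  if (!is.null(attr_diag) && attr_diag[1] < 0) {
    last_t <- max(out[, "time"], na.rm = TRUE)
    stop("kinetic integration failed (lsoda istate ", attr_diag[1],
         "); last good time ", signif(last_t, 4), " min")
  }
  traj <- as.data.frame(out)
  names(traj)[1] <- "time_min"
  structure(traj, class = c("kinetic_trajectory", "data.frame"),
            network = network)
}

# mass-action right-hand side over the reaction table; reactions whose
# flux consumes sensed cargo see only the sensor-free share of the pool
make_rhs <- function(network) {
  rxns <- network$reactions
  nsp <- length(network$species)
  sp_idx <- setNames(seq_len(nsp), network$species)
  r_re <- lapply(rxns, function(r) sp_idx[r$reactants])
  r_pr <- lapply(rxns, function(r) sp_idx[r$products])
  r_k <- vapply(rxns, `[[`, numeric(1), "k")
  r_free <- vapply(rxns, function(r)
    if (is.na(r$free_cargo)) NA_integer_ else sp_idx[[r$free_cargo]],
    integer(1))
  shielding <- isTRUE(network$params$sensor_shielding)
  function(t, y, parms) {
    y <- pmax(y, 0)
    ffac <- if (shielding) sensor_partition(y, network)$free_factor else 1
    dy <- numeric(nsp)
    for (i in seq_along(rxns)) {
      conc <- y[r_re[[i]]]
      fi <- r_free[i]
      if (shielding && !is.na(fi)) {
        j <- which(r_re[[i]] == fi)
        conc[j] <- conc[j] * ffac
      }
      flux <- r_k[i] * prod(conc)
      dy[r_re[[i]]] <- dy[r_re[[i]]] - flux
      dy[r_pr[[i]]] <- dy[r_pr[[i]]] + flux
    }
    list(dy)
  }
}

# phase-1 equilibration of the transporter with the preincubation LUVs;
# maps the resulting state onto the main network's initial state
preincubated_state <- function(network, rtol, atol) {
  pre <- network$scenario$preincubation
  sc <- network$scenario
  pre_scenario <- assay_scenario(
    luv_a = pre$luv, luv_b = NULL,
    protein_nM = sc$protein_nM,
    sensor = sc$sensor, sensor_nM = 0,
    t_grid = c(0, pre$minutes), regime = "extraction")
  pre_net <- build_network(pre_scenario, network$params)
  pre_traj <- simulate_kinetics(pre_net, c(0, pre$minutes),
                                rtol = rtol, atol = atol)
  final <- unlist(pre_traj[nrow(pre_traj), -1])

  # transporter load states carry over; when the preincubation
  # population is the assay's LUVs B, its depleted pools and the
  # membrane-adsorbed transporter carry over to B as well
  state0 <- network$state0
  state0[startsWith(names(state0), "P_")] <- 0
  sc_b <- sc$luv_b
  same_b <- !is.null(sc_b) &&
    isTRUE(all.equal(sc_b$composition, pre$luv$composition)) &&
    isTRUE(all.equal(sc_b$total_lipid_nM, pre$luv$total_lipid_nM))
  val <- function(nm) if (nm %in% names(final)) final[[nm]] else 0
  for (l in network$loads) {
    sol_pre <- val(paste("P", l, "sol", sep = "_"))
    mem_pre <- val(paste("P", l, "A", sep = "_"))
    sol <- paste("P", l, "sol", sep = "_")
    onB <- paste("P", l, "B", sep = "_")
    if (same_b && onB %in% names(state0)) {
      state0[sol] <- state0[sol] + sol_pre
      state0[onB] <- state0[onB] + mem_pre
    } else {
      state0[sol] <- state0[sol] + sol_pre + mem_pre
    }
  }
  if (same_b) {
    for (cg in pre_net$cargos) {
      poolB <- paste(cg, "B", sep = "_")
      if (poolB %in% names(state0)) state0[poolB] <- val(paste(cg, "A", sep = "_"))
    }
  }
  pmax(state0, 0)
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  net <- attr(x, "network")
  cat("Kinetic trajectory:", nrow(x), "time points over",
      max(x$time_min), "min;", length(net$species), "species\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
plot.kinetic_trajectory <- function(x, species = NULL, ...) {
  net <- attr(x, "network")
  if (is.null(species))
    species <- grep("^P(S|I4P)_", names(x), value = TRUE)
  if (!length(species)) species <- setdiff(names(x), "time_min")
  matplot(x$time_min, as.matrix(x[species]), type = "l", lty = 1,
          xlab = "time (min)", ylab = "concentration (nM)", ...)
  legend("topright", legend = species, col = seq_along(species),
         lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Export a trajectory as tidy CSV
#'
#' Long-format export: one row per time, compartment and species, with
#' the amount in nM. Cargo pools map to their membrane compartment;
#' transporter states to `solution` or their membrane.
#'
#' @param traj A [simulate_kinetics()] trajectory.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- setdiff(names(traj), "time_min")
  long <- do.call(rbind, lapply(cols, function(cn) {
    parts <- strsplit(cn, "_")[[1]]
    if (parts[1] == "P") {
      comp <- if (parts[3] == "sol") "solution" else paste0("membrane_", parts[3])
      spec <- paste0("transporter_", parts[2])
    } else {
      comp <- paste0("membrane_", parts[2])
      spec <- parts[1]
    }
    data.frame(time_min = traj$time_min, compartment = comp,
               species = spec, amount_nM = traj[[cn]])
  }))
  long <- long[order(long$time_min, long$compartment, long$species), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Conservation diagnostics for a trajectory
#'
#' Maximum relative drift of each conserved total (each cargo headgroup
#' summed over membranes and transporter-bound pools, and the total
#' transporter) along a trajectory.
#'
#' @param traj A [simulate_kinetics()] trajectory.
#' @return Named numeric vector of maximum relative deviations.
#' @export
conservation_error <- function(traj) {
  net <- attr(traj, "network")
  tots <- list()
  for (cg in net$cargos) {
    cols <- c(grep(paste0("^", cg, "_"), names(traj), value = TRUE),
              grep(paste0("^P_", cg, "_"), names(traj), value = TRUE))
    tots[[cg]] <- rowSums(traj[cols])
  }
  p_cols <- grep("^P_", names(traj), value = TRUE)
  tots[["protein"]] <- rowSums(traj[p_cols])
  vapply(tots, function(v) {
    ref <- v[1]
    if (ref <= 0) return(max(abs(v - ref)))
    max(abs(v - ref) / ref)
  }, numeric(1))
}

#' Transporter state occupancies along a trajectory
#'
#' @param traj A [simulate_kinetics()] trajectory.
#' @return Data frame: time, fraction of transporter in each load state,
#'   and the fraction adsorbed to each membrane (the FCCS observable of
#'   a labeled-transporter binding assay).
#' @export
protein_occupancy <- function(traj) {
  net <- attr(traj, "network")
  tot <- net$scenario$protein_nM
  if (tot <= 0) stop("scenario contains no transporter")
  out <- data.frame(time_min = traj$time_min)
  for (l in net$loads) {
    cols <- grep(paste0("^P_", l, "_"), names(traj), value = TRUE)
    out[[paste0("load_", l)]] <- rowSums(traj[cols]) / tot
  }
  for (mx in names(net$membranes)) {
    cols <- grep(paste0("_", mx, "$"), names(traj), value = TRUE)
    cols <- cols[startsWith(cols, "P_")]
    out[[paste0("on_", mx)]] <- rowSums(traj[cols]) / tot
  }
  out
}
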