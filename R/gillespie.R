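#' Stochastic (Gillespie) realization of a reaction network
#'
#' Exact stochastic simulation of the same mass-action reaction table
#' that [simulate_kinetics()] integrates deterministically, at copy
#' numbers set by a system-size factor `omega` (molecules = nM * omega).
#' Intended as a small-copy-number cross-check of the ODE mean, not as
#' the production engine: the assay observables are ensemble fractions.
#'
#' The quasi-equilibrium sensor is not part of the stochastic state, so
#' the network must be built from a scenario with `sensor_nM = 0`.
#'
#' @param network A [build_network()] with a zero-concentration sensor.
#' @param t_grid Output times (minutes), starting at 0.
#' @param omega Molecules per nM of concentration.
#' @param max_steps Safety cap on the number of reaction events.
#' @return Data frame of times and species copy numbers divided by
#'   `omega` (i.e. concentrations in nM).
#' @export
simulate_gillespie <- function(network, t_grid = NULL, omega = 0.2,
                               max_steps = 5e6) {
  stopifnot(inherits(network, "reaction_network"))
  if (network$sensor$sensor_nM > 0)
    stop("the stochastic engine requires a scenario with sensor_nM = 0")
  if (is.null(t_grid)) t_grid <- network$scenario$t_grid

  sp <- network$species
  sp_idx <- setNames(seq_along(sp), sp)
  rxns <- network$reactions
  re <- lapply(rxns, function(r) unname(sp_idx[r$reactants]))
  pr <- lapply(rxns, function(r) unname(sp_idx[r$products]))
  ks <- vapply(rxns, `[[`, numeric(1), "k")
  order2 <- vapply(re, length, integer(1)) == 2L

  n <- round(network$state0 * omega)
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = length(sp),
                dimnames = list(NULL, sp))
  t_now <- 0
  gi <- 1L
  while (gi <= length(t_grid) && t_grid[gi] <= t_now) {
    out[gi, ] <- n / omega
    gi <- gi + 1L
  }
  steps <- 0L
  while (gi <= length(t_grid) && steps < max_steps) {
    a <- vapply(seq_along(rxns), function(i) {
      cnt <- n[re[[i]]]
      if (order2[i]) ks[i] / omega * prod(cnt) else ks[i] * cnt
    }, numeric(1))
    a0 <- sum(a)
    if (a0 <= 0) {
      out[gi:length(t_grid), ] <- matrix(n / omega, nrow = length(t_grid) - gi + 1,
                                         ncol = length(sp), byrow = TRUE)
      gi <- length(t_grid) + 1L
      break
    }
    tau <- stats::rexp(1, a0)
    while (gi <= length(t_grid) && t_grid[gi] < t_now + tau) {
      out[gi, ] <- n / omega
      gi <- gi + 1L
    }
    t_now <- t_now + tau
    i <- sample.int(length(a), 1L, prob = a)
    n[re[[i]]] <- n[re[[i]]] - 1L
    n[pr[[i]]] <- n[pr[[i]]] + 1L
    steps <- steps + 1L
  }
  if (steps >= max_steps)
    warning("stochastic simulation hit max_steps before the end of t_grid")
  data.frame(time_min = t_grid[seq_len(min(gi - 1L, length(t_grid)))],
             out[seq_len(min(gi - 1L, length(t_grid))), , drop = FALSE])
}
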