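#' Particle ensemble for photon-trace synthesis
#'
#' A snapshot of diffusing fluorescent particles: for each particle its
#' species, diffusion coefficient, and green/red fluorophore counts.
#' Positions are drawn uniformly in the periodic box when the trace is
#' synthesized.
#'
#' @param species Character vector (e.g. `"luv"`, `"sensor"`).
#' @param d_um2s Diffusion coefficients (um^2/s).
#' @param n_green,n_red Fluorophore counts per particle (nonnegative
#'   integers).
#' @return Data frame of class `"particle_ensemble"`.
#' @export
particle_ensemble <- function(species, d_um2s, n_green, n_red) {
  if (any(n_green < 0) || any(n_red < 0)) stop("fluorophore counts must be >= 0")
  if (any(d_um2s < 0)) stop("diffusion coefficients must be >= 0")
  out <- data.frame(species = species, d_um2s = d_um2s,
                    n_green = as.numeric(n_green), n_red = as.numeric(n_red))
  class(out) <- c("particle_ensemble", "data.frame")
  out
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kT / (6 pi eta r)` in um^2/s, water at 25 C by default.
#'
#' @param radius_nm Hydrodynamic radius (nm).
#' @param temperature_K Temperature.
#' @param viscosity_Pa_s Solvent viscosity.
#' @export
stokes_einstein_D <- function(radius_nm, temperature_K = 298.15,
                              viscosity_Pa_s = 8.9e-4) {
  kB <- 1.380649e-23
  kB * temperature_K / (6 * pi * viscosity_Pa_s * radius_nm * 1e-9) * 1e12
}

#' Realize a particle ensemble from a kinetic state
#'
#' Turns the concentrations and bound-sensor fraction of one assay time
#' point into discrete particles in the simulation box: labeled donor
#' LUVs carrying Poisson-distributed red tracer dyes plus one green
#' fluorophore per bound sensor (bound sensors are distributed over the
#' LUVs multinomially), unlabeled acceptor LUVs carrying only the
#' sensors bound to cargo already delivered there, and free sensors with
#' one green fluorophore each. Particle numbers are Poisson draws around
#' concentration x box volume.
#'
#' @param traj A [simulate_kinetics()] trajectory.
#' @param time Assay time (minutes); must be on the trajectory grid, or
#'   -1 for the pre-addition baseline state.
#' @param optics An [optics_config()].
#' @param seed Integer seed (drives all stochastic rounding and
#'   assignment).
#' @param dilution Dilution factor applied to the sensor pool before
#'   realization. The readout Gcc(0)/GR(0) is dilution-invariant (for
#'   the sensors it is a fraction; for the LUVs the vesicle
#'   concentration cancels between Gcc(0) and GR(0)), so a diluted
#'   aliquot measures the same quantity with fewer particles.
#' @param luv_dilution Dilution factor for the vesicle populations;
#'   defaults to `dilution`. Keeping more vesicles than sensors holds
#'   the red channel well-sampled while the (much more concentrated)
#'   sensor pool is thinned for speed.
#' @param d_luv_um2s,d_sensor_um2s Diffusion coefficients; defaults are
#'   Stokes-Einstein values for a 25-nm-radius vesicle (~9.8 um^2/s) and
#'   a small protein domain (80 um^2/s).
#' @return A [particle_ensemble()].
#' @export
ensemble_from_state <- function(traj, time, optics, seed,
                                dilution = 1, luv_dilution = dilution,
                                d_luv_um2s = stokes_einstein_D(25),
                                d_sensor_um2s = 80) {
  net <- attr(traj, "network")
  sc <- net$scenario
  if (identical(time, -1)) {
    state <- net$state0
  } else {
    i <- which(abs(traj$time_min - time) < 1e-9)
    if (!length(i)) stop("time ", time, " min is not on the trajectory grid")
    state <- unlist(traj[i[1], -1])
  }
  part <- sensor_partition(state, net)
  s_tot <- net$sensor$sensor_nM
  bound_frac <- if (s_tot > 0) part$bound_on / s_tot else
    setNames(rep(0, length(net$membranes)), names(net$membranes))

  set.seed(seed %% .Machine$integer.max)
  luv_a_nM <- sc$luv_a$vesicle_nM / luv_dilution
  n_luv_a <- stats::rpois(1, molecules_in_box(luv_a_nM, optics$box_um))
  if (luv_a_nM > 0 && molecules_in_box(luv_a_nM, optics$box_um) < 10)
    stop("fewer than 10 labeled LUVs expected in the box; ",
         "enlarge the box or reduce the dilution")
  n_sensors <- stats::rpois(1, molecules_in_box(s_tot / dilution, optics$box_um))

  # sensors: bound to A, bound to B (dark), free
  n_bound_a <- stats::rbinom(1, n_sensors, min(bound_frac[["A"]], 1))
  p_b <- if ("B" %in% names(bound_frac)) bound_frac[["B"]] else 0
  n_bound_b <- if (p_b > 0 && n_sensors - n_bound_a > 0)
    stats::rbinom(1, n_sensors - n_bound_a,
                  min(p_b / max(1 - bound_frac[["A"]], 1e-12), 1)) else 0
  n_free <- n_sensors - n_bound_a - n_bound_b

  dyes <- stats::rpois(n_luv_a, sc$luv_a$mean_dyes_per_vesicle)
  greens_a <- if (n_luv_a > 0)
    tabulate(sample.int(n_luv_a, n_bound_a, replace = TRUE), nbins = n_luv_a)
  else integer(0)

  sp <- c(rep("luv_a", n_luv_a), rep("sensor", n_free))
  dd <- c(rep(d_luv_um2s, n_luv_a), rep(d_sensor_um2s, n_free))
  ng <- c(greens_a, rep(1, n_free))
  nr <- c(dyes, rep(0, n_free))

  if (n_bound_b > 0 && !is.null(sc$luv_b)) {
    n_luv_b <- max(stats::rpois(1, molecules_in_box(
      sc$luv_b$vesicle_nM / luv_dilution, optics$box_um)), 1)
    greens_b <- tabulate(sample.int(n_luv_b, n_bound_b, replace = TRUE),
                         nbins = n_luv_b)
    keep <- greens_b > 0  # dark acceptor LUVs contribute nothing
    sp <- c(sp, rep("luv_b", sum(keep)))
    dd <- c(dd, rep(d_luv_um2s, sum(keep)))
    ng <- c(ng, greens_b[keep])
    nr <- c(nr, rep(0, sum(keep)))
  }
  particle_ensemble(sp, dd, ng, nr)
}

#' Synthesize a two-channel photon-count trace
#'
#' Brownian-dynamics simulation of the ensemble through the Gaussian
#' observation volume: positions advance by Gaussian steps of variance
#' `2 D dt` per axis with periodic wrapping; the expected count per bin
#' is the sum over particles of brightness x Gaussian profile x bin
#' width, realized as Poisson counts. Bit-reproducible for a given seed.
#'
#' @param ensemble A [particle_ensemble()].
#' @param optics An [optics_config()].
#' @param duration_s Trace length in seconds (at least 1000 bins).
#' @param seed Integer seed.
#' @param positions Optional n x 3 matrix of initial positions (um,
#'   box-centered coordinates); defaults to uniform positions drawn from
#'   the seed.
#' @return A `"photon_trace"`: integer count vectors `g`, `r`, plus
#'   `bin_width_s`, `duration_s`, `seed`.
#' @export
simulate_photon_trace <- function(ensemble, optics, duration_s, seed,
                                  positions = NULL) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(optics, "optics_config"))
  nbins <- floor(duration_s / optics$bin_width_s)
  if (nbins < 1000) stop("duration must cover at least 1000 bins")
  pos0 <- if (is.null(positions))
    uniform_positions_cpp(nrow(ensemble), optics$box_um,
                          seed = as.double(seed) * 2 + 1)
  else {
    stopifnot(is.matrix(positions), nrow(positions) == nrow(ensemble),
              ncol(positions) == 3)
    positions
  }
  res <- simulate_trace_cpp(pos0, ensemble$d_um2s,
                            ensemble$n_green * optics$brightness_g,
                            ensemble$n_red * optics$brightness_r,
                            optics$w0_um, optics$kappa,
                            optics$bin_width_s, nbins, optics$box_um,
                            seed = as.double(seed))
  photon_trace(res$g, res$r, optics$bin_width_s, seed = seed)
}

#' Construct / read / write photon traces
#'
#' A photon trace holds the binned photon counts of the green and red
#' detection channels. The CSV interchange format is two columns
#' (`counts_g`, `counts_r`) preceded by comment lines `# bin_width_s=`,
#' `# duration_s=`, `# seed=`; it is also the entry point for measured
#' data.
#'
#' @param g,r Nonnegative integer count vectors (equal length).
#' @param bin_width_s Bin width in seconds.
#' @param seed Seed used to generate the trace (NA for measured data).
#' @return An object of class `"photon_trace"`.
#' @export
photon_trace <- function(g, r, bin_width_s, seed = NA) {
  if (length(g) != length(r)) stop("channels must have equal length")
  if (any(g < 0) || any(r < 0)) stop("counts must be nonnegative")
  structure(list(g = as.integer(g), r = as.integer(r),
                 bin_width_s = bin_width_s,
                 duration_s = length(g) * bin_width_s, seed = seed),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf(
    "Photon trace: %d bins of %.3g us (%.3g s); <G> = %.3g, <R> = %.3g counts/bin\n",
    length(x$g), x$bin_width_s * 1e6, x$duration_s, mean(x$g), mean(x$r)))
  invisible(x)
}

#' @rdname photon_trace
#' @param trace A `"photon_trace"`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width_s=%.10g", trace$bin_width_s),
               sprintf("# duration_s=%.10g", trace$duration_s),
               sprintf("# seed=%s", trace$seed),
               "counts_g,counts_r"), con)
  utils::write.table(data.frame(trace$g, trace$r), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname photon_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  bw <- as.numeric(get("bin_width_s"))
  if (!is.finite(bw)) stop("trace file lacks a '# bin_width_s=' header")
  dat <- utils::read.csv(path, comment.char = "#")
  seed <- suppressWarnings(as.numeric(get("seed")))
  photon_trace(dat$counts_g, dat$counts_r, bw, seed = seed)
}
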