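# shared fixtures: everything is generated in code at test time

avogadro <- 6.02214076e23

# uniformly labeled single-species ensemble (LUV-like, q red dyes each)
uniform_luv_ensemble <- function(n, dyes = 2, greens = 0,
                                 d = stokes_einstein_D(25)) {
  particle_ensemble(rep("luv", n), rep(d, n),
                    n_green = rep(greens, n), n_red = rep(dyes, n))
}

# mixed ensemble with an exact bound fraction: n_bound sensors sit on
# distinct LUVs (one per vesicle), the rest diffuse freely
bound_fraction_ensemble <- function(n_luv, n_sensor, n_bound, dyes = 2,
                                    seed = 1) {
  set.seed(seed)
  greens <- integer(n_luv)
  greens[sample.int(n_luv, n_bound)] <- 1
  particle_ensemble(
    c(rep("luv", n_luv), rep("sensor", n_sensor - n_bound)),
    c(rep(stokes_einstein_D(25), n_luv), rep(80, n_sensor - n_bound)),
    n_green = c(greens, rep(1, n_sensor - n_bound)),
    n_red = c(rep(dyes, n_luv), rep(0, n_sensor - n_bound)))
}

# expected particles in the effective volume for n particles in a box
neff_in_box <- function(n, optics) {
  n * effective_volume(optics) / optics$box_um^3
}

# brute-force 1-D equilibrium solver for S + L <-> SL by bisection on
# the free-sensor concentration (independent of the quadratic formula)
bound_by_bisection <- function(S, L, kd, tol = 1e-12) {
  if (S <= 0 || L <= 0) return(0)
  f <- function(s_free) s_free + s_free * L / (kd + s_free * L / S) - S
  # solve for bound b directly: free sensor S-b, free ligand L-b,
  # (S-b)(L-b)/b = kd
  g <- function(b) (S - b) * (L - b) / b - kd
  lo <- 1e-15; hi <- min(S, L)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# pooled-variance two-sample t statistic from the textbook formula
ttest_textbook <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
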