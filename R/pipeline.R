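#' Run an assay end to end
#'
#' Orchestrates scenario -> kinetics -> sensor readout -> (optionally)
#' photon synthesis -> correlation -> amplitude-ratio readout -> rate
#' estimate, for one scenario.
#'
#' Two paths are provided. The `"ideal"` path maps the kinetic
#' trajectory through the exact binding isotherm: it is deterministic
#' (replicates differ only if `noise_cv > 0`, which applies
#' multiplicative Gaussian measurement noise to each readout point). The
#' `"optical"` path realizes each time point as a particle ensemble,
#' synthesizes a photon trace, correlates it, fits the amplitudes and
#' forms Gcc(0)/GR(0); replicates are new optical seeds at fixed
#' kinetics, emulating repeated measurements on the same LUV stock.
#'
#' The rate estimator applied to each replicate series follows the
#' scenario regime: extraction rate (extraction regime) or transport
#' rate (release regime); `estimator = "pi4p_drop"` selects the overall
#' ten-minute drop instead.
#'
#' @param scenario An [assay_scenario()] or preset name.
#' @param params [kinetic_params()].
#' @param path `"ideal"` or `"optical"`.
#' @param seed Integer; seeds all randomness of the run.
#' @param n_replicates Replicate measurements (default 10, the assay's
#'   replication level).
#' @param noise_cv Multiplicative noise CV on the ideal path.
#' @param optics [optics_config()] for the optical path.
#' @param trace_duration_s Trace length per time point (optical path).
#' @param n_segments Trace segments for correlation error bars.
#' @param dilution Sensor-pool dilution for the optical path (the
#'   readout is dilution-invariant; simulating a diluted aliquot costs
#'   fewer particles).
#' @param luv_dilution Vesicle-pool dilution for the optical path;
#'   defaults to `dilution`.
#' @param optical_times Optional subset of the scenario's time grid to
#'   realize optically (other points are reported as `NA`); useful when
#'   the chosen estimator only consumes two or three time points.
#' @param estimator `"auto"`, `"extraction"`, `"transport"` or
#'   `"pi4p_drop"`.
#' @param acc_convention `"accessible"` (default: outer-leaflet cargo
#'   concentration enters the estimators) or `"total"` (total cargo
#'   concentration).
#' @param out_dir Optional directory: readout series and rates are
#'   written as CSV plus a JSON provenance record.
#' @return An `"assay_run"`: readout series per replicate, the mean
#'   series, replicate rate values and their [replicate_stats()],
#'   provenance.
#' @export
run_assay <- function(scenario, params = kinetic_params(),
                      path = c("ideal", "optical"), seed = 1,
                      n_replicates = 10, noise_cv = 0,
                      optics = optics_config(),
                      trace_duration_s = 10, n_segments = 8,
                      dilution = 1, luv_dilution = dilution,
                      optical_times = NULL,
                      estimator = c("auto", "extraction", "transport",
                                    "pi4p_drop"),
                      acc_convention = c("accessible", "total"),
                      out_dir = NULL) {
  path <- match.arg(path)
  estimator <- match.arg(estimator)
  acc_convention <- match.arg(acc_convention)
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(scenario, "assay_scenario"))

  net <- build_network(scenario, params)
  traj <- simulate_kinetics(net)
  ideal <- readout_from_trajectory(traj)

  series_list <- if (path == "ideal") {
    lapply(seq_len(n_replicates), function(r) {
      if (noise_cv <= 0) return(ideal)
      set.seed(seed + 7919L * r)
      noisy <- ideal$readout *
        (1 + stats::rnorm(nrow(ideal), sd = noise_cv))
      readout_series(ideal$time_min, pmax(noisy, 0))
    })
  } else {
    mu <- scenario$luv_a$mean_dyes_per_vesicle
    corr <- if (mu > 0) 1 + 1 / mu else 1
    lapply(seq_len(n_replicates), function(r) {
      vals <- vapply(seq_along(ideal$time_min), function(i) {
        t_i <- ideal$time_min[i]
        if (!is.null(optical_times) && !t_i %in% optical_times)
          return(NA_real_)
        sub_seed <- seed + 104729L * r + 1299709L * i
        ens <- ensemble_from_state(traj,
                                   if (t_i == 0) -1 else t_i,
                                   optics, seed = sub_seed,
                                   dilution = dilution,
                                   luv_dilution = luv_dilution)
        tr <- simulate_photon_trace(ens, optics, trace_duration_s,
                                    seed = sub_seed)
        cur <- correlate_multitau(tr, n_segments = n_segments)
        readout_ratio(cur, kappa = optics$kappa,
                      brightness_correction = corr)$ratio
      }, numeric(1))
      readout_series(ideal$time_min, ifelse(is.na(vals), NA_real_, vals))
    })
  }

  mean_series <- {
    mat <- vapply(series_list, function(s) s$readout,
                  numeric(nrow(series_list[[1]])))
    mat <- matrix(mat, nrow = nrow(series_list[[1]]))
    se <- if (ncol(mat) > 1)
      apply(mat, 1, stats::sd, na.rm = TRUE) / sqrt(ncol(mat))
    else rep(NA_real_, nrow(mat))
    readout_series(series_list[[1]]$time_min, rowMeans(mat, na.rm = FALSE),
                   se = se)
  }

  cargo <- scenario$sensed_cargo
  c_acc <- if (acc_convention == "accessible")
    accessible_cargo(scenario$luv_a, cargo)
  else {
    comp <- scenario$luv_a$composition
    info <- lipid_info(names(comp))
    sum(comp[!is.na(info$cargo) & info$cargo == cargo]) *
      scenario$luv_a$total_lipid_nM
  }
  if (estimator == "auto")
    estimator <- if (scenario$regime == "extraction") "extraction"
                 else "transport"
  rate_fun <- switch(estimator,
    extraction = function(s) extraction_rate(s, c_acc, scenario$protein_nM,
                                             cargo = cargo)$value,
    transport = function(s) transport_rate(s, c_acc, scenario$protein_nM,
                                           cargo = cargo)$value,
    pi4p_drop = function(s) pi4p_drop(s, c_acc, scenario$protein_nM)$value)
  rate_values <- vapply(series_list, rate_fun, numeric(1))
  stats <- if (length(rate_values) >= 3) replicate_stats(rate_values)
           else list(mean = mean(rate_values), sem = NA_real_,
                     kept = seq_along(rate_values), excluded = integer(0))

  run <- structure(list(
    scenario = scenario, params = params, trajectory = traj,
    path = path, estimator = estimator,
    series = series_list, mean_series = mean_series,
    rate_values = rate_values, rate_stats = stats,
    c_lipid_acc_nM = c_acc, acc_convention = acc_convention,
    provenance = list(seed = seed, n_replicates = n_replicates,
                      path = path, noise_cv = noise_cv,
                      dilution = dilution, luv_dilution = luv_dilution,
                      trace_duration_s = if (path == "optical")
                        trace_duration_s else NA,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "assay_run")
  if (!is.null(out_dir)) write_assay_run(run, out_dir)
  run
}

#' @export
print.assay_run <- function(x, ...) {
  cat("Assay run (", x$path, " path, ", length(x$series),
      " replicate(s), ", x$estimator, " estimator)\n", sep = "")
  cat(sprintf("  readout: baseline %.3f -> %.3f at %g min\n",
              x$mean_series$readout[1],
              x$mean_series$readout[nrow(x$mean_series)],
              max(x$mean_series$time_min)))
  cat(sprintf("  rate: %.4g +- %.2g (mean +- SEM, %d/%d replicates kept)\n",
              x$rate_stats$mean, x$rate_stats$sem,
              length(x$rate_stats$kept), length(x$rate_values)))
  invisible(x)
}

#' @export
plot.assay_run <- function(x, ...) plot(x$mean_series, ...)

write_assay_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(run$mean_series),
                   file.path(out_dir, "readout_mean.csv"), row.names = FALSE)
  reps <- do.call(rbind, lapply(seq_along(run$series), function(i)
    cbind(replicate = i, as.data.frame(run$series[[i]]))))
  utils::write.csv(reps, file.path(out_dir, "readout_replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(replicate = seq_along(run$rate_values),
               rate = run$rate_values,
               kept = seq_along(run$rate_values) %in% run$rate_stats$kept),
    file.path(out_dir, "rates.csv"), row.names = FALSE)
  prov <- c(run$provenance,
            list(estimator = run$estimator,
                 c_lipid_acc_nM = run$c_lipid_acc_nM,
                 acc_convention = run$acc_convention,
                 rate_mean = run$rate_stats$mean,
                 rate_sem = run$rate_stats$sem))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare the rate estimates of two assay conditions
#'
#' Applies the replicate pipeline of the published assays: single-pass
#' 1.5-SD outlier screening per condition, then a pooled-variance
#' two-sample t-test on the surviving replicate rate estimates.
#'
#' @param run_a,run_b Two [run_assay()] results with the same estimator
#'   kind.
#' @return Data frame: means, SEMs, t, df, p.
#' @export
compare_conditions <- function(run_a, run_b) {
  stopifnot(inherits(run_a, "assay_run"), inherits(run_b, "assay_run"))
  if (!identical(run_a$estimator, run_b$estimator))
    stop("runs use different estimator kinds: ",
         run_a$estimator, " vs ", run_b$estimator)
  if (length(run_a$rate_values) < 2 || length(run_b$rate_values) < 2)
    stop("each run needs at least 2 replicates for a t-test")
  va <- run_a$rate_values[run_a$rate_stats$kept]
  vb <- run_b$rate_values[run_b$rate_stats$kept]
  tt <- two_sample_ttest(va, vb)
  data.frame(estimator = run_a$estimator,
             mean_a = mean(va), sem_a = run_a$rate_stats$sem,
             mean_b = mean(vb), sem_b = run_b$rate_stats$sem,
             t = tt$t, df = tt$df, p = tt$p)
}
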