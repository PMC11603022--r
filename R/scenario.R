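#' Define an assay scenario
#'
#' Bundles the donor (labeled) LUV population, an optional acceptor or
#' competitor (unlabeled) population, the transporter and biosensor
#' concentrations, the assay time grid, and the regime the
#' concentrations put the experiment in.
#'
#' The two regimes follow from the calibration curve of the biosensor:
#' in the *extraction* regime the accessible cargo on the donor roughly
#' equals the transporter concentration, so uptake alone empties the
#' sensed pool and the readout drops with extraction; in the *release*
#' regime the cargo saturates the sensor, so the initial extraction step
#' barely registers and the subsequent decay reports delivery to the
#' acceptor vesicles.
#'
#' @param luv_a Donor [luv_population()] (DiD labeled).
#' @param luv_b Acceptor/competitor [luv_population()] or `NULL`.
#' @param protein_nM Transporter (Osh6) concentration in nM.
#' @param sensor `"C2Lact"` (senses PS) or `"SidC"` (senses PI4P).
#' @param sensor_nM Biosensor concentration in nM.
#' @param t_grid Assay times in minutes, starting at 0 (the moment of
#'   protein addition).
#' @param regime `"extraction"`, `"release"`, or `"auto"` to derive it
#'   from the cargo/protein ratio.
#' @param preincubation `NULL`, or `list(luv = <luv_population>,
#'   minutes = <numeric>)`: the protein is pre-incubated with that
#'   population (e.g. to preload it with cargo) before the assay starts.
#' @return An object of class `"assay_scenario"`.
#' @export
assay_scenario <- function(luv_a, luv_b = NULL, protein_nM,
                           sensor = c("C2Lact", "SidC"), sensor_nM,
                           t_grid = 0:10, regime = "auto",
                           preincubation = NULL) {
  stopifnot(inherits(luv_a, "luv_population"))
  if (!is.null(luv_b)) stopifnot(inherits(luv_b, "luv_population"))
  sensor <- match.arg(sensor)
  if (protein_nM < 0 || sensor_nM < 0) stop("concentrations must be nonnegative")
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0)
    stop("t_grid must be strictly increasing and start at 0")
  if (!is.null(preincubation)) {
    stopifnot(is.list(preincubation), inherits(preincubation$luv, "luv_population"),
              is.numeric(preincubation$minutes), preincubation$minutes > 0)
  }
  sensed <- sensed_cargo(sensor)
  acc <- accessible_cargo(luv_a, sensed)
  regime <- match.arg(regime, c("auto", "extraction", "release"))
  if (regime == "auto") {
    if (protein_nM == 0) {
      regime <- if (acc > 0) "release" else "extraction"
    } else {
      ratio <- acc / protein_nM
      regime <- if (ratio <= 1.5) "extraction" else "release"
    }
  }
  structure(list(
    luv_a = luv_a, luv_b = luv_b,
    protein_nM = protein_nM,
    sensor = sensor, sensor_nM = sensor_nM,
    sensed_cargo = sensed,
    t_grid = t_grid, regime = regime,
    preincubation = preincubation
  ), class = "assay_scenario")
}

sensed_cargo <- function(sensor) {
  switch(sensor, C2Lact = "PS", SidC = "PI4P",
         stop("unknown sensor: ", sensor))
}

#' @export
print.assay_scenario <- function(x, ...) {
  cat("Assay scenario (", x$regime, " regime)\n", sep = "")
  cat("  transporter:", x$protein_nM, "nM; sensor:", x$sensor,
      paste0("(", x$sensed_cargo, ")"), x$sensor_nM, "nM\n")
  cat("  accessible sensed cargo on donor:",
      signif(accessible_cargo(x$luv_a, x$sensed_cargo), 4), "nM\n")
  cat("  donor  "); print(x$luv_a)
  if (!is.null(x$luv_b)) { cat("  acceptor "); print(x$luv_b) }
  if (!is.null(x$preincubation))
    cat("  protein pre-incubated", x$preincubation$minutes,
        "min with a separate LUV population\n")
  invisible(x)
}

#' Preset assay scenarios
#'
#' Returns fully populated scenarios matching the published assay
#' layouts: donor composition, concentrations of lipid, transporter and
#' sensor. Compositions that list only the added species are completed
#' with POPC. Presets:
#'
#' * `fig2_ps_extraction`: donor POPC/phPG/POPS 94/5/1 at 50 uM (250 nM
#'   accessible PS), Osh6 250 nM, C2Lact 50 nM; optional competitor
#'   LUVs B at 200 uM.
#' * `fig3_ps_transport`: donor POPC/phPG/POPS 91/5/4 at 50 uM (2 uM
#'   total PS), Osh6 250 nM, C2Lact 50 nM; acceptor LUVs B at 200 uM
#'   (POPC unless overridden).
#' * `fig4_pi4p_extraction`: donor POPC/PI4P 99/1 at 50 uM, Osh6
#'   250 nM, SidC 100 nM; optional competitor LUVs B.
#' * `fig5_pi4p_transport`: donor POPC/PI4P 97/3 at 50 uM, Osh6 250 nM,
#'   SidC 100 nM; acceptor LUVs B at 200 uM (DOPC unless overridden).
#' * `fig6_binding`: labeled LUVs A at 200 uM of a chosen composition,
#'   labeled transporter 10 nM, no sensor readout (the transporter
#'   itself is the green species); optional preincubation LUVs B at
#'   7.5 uM.
#' * `fig7_pm_like`: donor POPC/PI4P/POPS 79/1/20 at 50 uM, SidC
#'   100 nM, Osh6 250 nM pre-incubated 10 min with POPC/POPS 80/20
#'   LUVs B at 200 uM.
#'
#' @param name Preset name (see above).
#' @param luv_b_composition Named mol-fraction (or mol-percent) vector
#'   overriding the acceptor/competitor composition, or `NULL` for the
#'   preset default. For extraction presets, `NULL` means no LUVs B.
#' @param luv_a_composition Optional override of the donor composition.
#' @return An [assay_scenario()].
#' @examples
#' scenario_preset("fig4_pi4p_extraction")
#' scenario_preset("fig2_ps_extraction",
#'                 luv_b_composition = c(POPC = 99, PI4P = 1))
#' @export
scenario_preset <- function(name, luv_b_composition = NULL,
                            luv_a_composition = NULL) {
  presets <- c("fig2_ps_extraction", "fig3_ps_transport",
               "fig4_pi4p_extraction", "fig5_pi4p_transport",
               "fig6_binding", "fig7_pm_like")
  if (!name %in% presets)
    stop("unknown preset \"", name, "\"; valid presets: ",
         paste(presets, collapse = ", "))

  luv_b <- function(comp, default = NULL) {
    comp <- if (is.null(comp)) default else comp
    if (is.null(comp)) return(NULL)
    luv_population(comp, total_lipid_nM = 2e5, did_per_lipid = 0)
  }

  switch(name,
    fig2_ps_extraction = assay_scenario(
      luv_a = luv_population(
        if (is.null(luv_a_composition)) c(POPC = 0.94, phPG = 0.05, POPS = 0.01)
        else luv_a_composition, total_lipid_nM = 5e4),
      luv_b = luv_b(luv_b_composition),
      protein_nM = 250, sensor = "C2Lact", sensor_nM = 50,
      t_grid = 0:10),
    fig3_ps_transport = assay_scenario(
      luv_a = luv_population(
        if (is.null(luv_a_composition)) c(POPC = 0.91, phPG = 0.05, POPS = 0.04)
        else luv_a_composition, total_lipid_nM = 5e4),
      luv_b = luv_b(luv_b_composition, c(POPC = 1)),
      protein_nM = 250, sensor = "C2Lact", sensor_nM = 50,
      t_grid = 0:12),
    fig4_pi4p_extraction = assay_scenario(
      luv_a = luv_population(
        if (is.null(luv_a_composition)) c(POPC = 0.99, PI4P = 0.01)
        else luv_a_composition, total_lipid_nM = 5e4),
      luv_b = luv_b(luv_b_composition),
      protein_nM = 250, sensor = "SidC", sensor_nM = 100,
      t_grid = 0:15),
    fig5_pi4p_transport = assay_scenario(
      luv_a = luv_population(
        if (is.null(luv_a_composition)) c(POPC = 0.97, PI4P = 0.03)
        else luv_a_composition, total_lipid_nM = 5e4),
      luv_b = luv_b(luv_b_composition, c(DOPC = 1)),
      protein_nM = 250, sensor = "SidC", sensor_nM = 100,
      t_grid = 0:18),
    fig6_binding = {
      # labeled-transporter binding assay: LUVs B (7.5 uM) preload the
      # transporter with cargo for 10 min before the labeled LUVs A are
      # probed; with no LUVs B the transporter arrives empty
      luvb <- if (!is.null(luv_b_composition))
        luv_population(luv_b_composition, total_lipid_nM = 7.5e3,
                       did_per_lipid = 0)
      assay_scenario(
        luv_a = luv_population(
          if (is.null(luv_a_composition)) c(POPC = 1)
          else luv_a_composition, total_lipid_nM = 2e5),
        luv_b = luvb,
        protein_nM = 10, sensor = "C2Lact", sensor_nM = 0,
        t_grid = 0:10, regime = "extraction",
        preincubation = if (!is.null(luvb)) list(luv = luvb, minutes = 10))
    },
    fig7_pm_like = {
      luvb <- luv_b(luv_b_composition, c(POPC = 0.8, POPS = 0.2))
      assay_scenario(
        luv_a = luv_population(
          if (is.null(luv_a_composition))
            c(POPC = 0.79, PI4P = 0.01, POPS = 0.20)
          else luv_a_composition, total_lipid_nM = 5e4),
        luv_b = luvb,
        protein_nM = 250, sensor = "SidC", sensor_nM = 100,
        t_grid = 0:15,
        preincubation = if (!is.null(luvb)) list(luv = luvb, minutes = 10))
    })
}

#' List available scenario presets
#' @return Character vector of preset names accepted by [scenario_preset()].
#' @export
scenario_presets <- function() {
  c("fig2_ps_extraction", "fig3_ps_transport", "fig4_pi4p_extraction",
    "fig5_pi4p_transport", "fig6_binding", "fig7_pm_like")
}

#' Write / read an assay scenario as YAML
#'
#' Scenario files use nM for concentrations and mol% for compositions,
#' one file per assay.
#'
#' @param scenario An [assay_scenario()].
#' @param path File path.
#' @return `read_scenario` returns an [assay_scenario()];
#'   `write_scenario` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "assay_scenario"))
  luv_fields <- function(luv) {
    if (is.null(luv)) return(NULL)
    list(composition_mol_percent = as.list(100 * luv$composition),
         total_lipid_nM = luv$total_lipid_nM,
         diameter_nm = luv$diameter_nm,
         did_per_lipid = luv$did_per_lipid,
         accessible_fraction = luv$accessible_fraction)
  }
  obj <- list(
    luv_a = luv_fields(scenario$luv_a),
    luv_b = luv_fields(scenario$luv_b),
    protein_nM = scenario$protein_nM,
    sensor = scenario$sensor,
    sensor_nM = scenario$sensor_nM,
    t_grid_min = scenario$t_grid,
    regime = scenario$regime,
    preincubation = if (!is.null(scenario$preincubation))
      c(luv_fields(scenario$preincubation$luv),
        list(minutes = scenario$preincubation$minutes))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  luv_from <- function(fields) {
    if (is.null(fields)) return(NULL)
    luv_population(unlist(fields$composition_mol_percent) / 100,
                   total_lipid_nM = fields$total_lipid_nM,
                   diameter_nm = fields$diameter_nm %||% 50,
                   did_per_lipid = fields$did_per_lipid %||% 1e-4,
                   accessible_fraction = fields$accessible_fraction %||% 0.5)
  }
  assay_scenario(
    luv_a = luv_from(obj$luv_a),
    luv_b = luv_from(obj$luv_b),
    protein_nM = obj$protein_nM,
    sensor = obj$sensor,
    sensor_nM = obj$sensor_nM,
    t_grid = obj$t_grid_min,
    regime = obj$regime %||% "auto",
    preincubation = if (!is.null(obj$preincubation))
      list(luv = luv_from(obj$preincubation),
           minutes = obj$preincubation$minutes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
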