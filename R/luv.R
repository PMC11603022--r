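#' Build a LUV population
#'
#' Describes one population of large unilamellar vesicles: its lipid
#' composition, total lipid concentration, and the geometry-derived
#' per-vesicle lipid count and vesicle number concentration. Lipid
#' counts follow from the sphere areas of the two leaflets at a given
#' area per lipid: the outer leaflet at the vesicle radius, the inner
#' leaflet one bilayer thickness below.
#'
#' The `accessible_fraction` is the share of each lipid pool exposed to
#' the solution and hence available to the transporter and the
#' biosensor. The default 0.5 treats half of the lipid as outer-leaflet;
#' passing `"geometric"` uses the outer/total leaflet area ratio
#' (about 0.586 for a 50-nm vesicle).
#'
#' @param composition Named numeric vector of mol fractions (sum 1) or
#'   mol percents (sum 100); names must be lipid species, see
#'   [lipid_table()].
#' @param total_lipid_nM Total lipid concentration in nM (50 uM = 5e4).
#' @param diameter_nm Vesicle diameter in nm.
#' @param did_per_lipid DiD tracer per lipid ratio (1/10,000 for labeled
#'   populations; 0 for unlabeled ones).
#' @param area_per_lipid_nm2 Area per lipid in the fluid phase.
#' @param bilayer_thickness_nm Bilayer thickness.
#' @param accessible_fraction Number in (0, 1] or `"geometric"`.
#' @return An object of class `"luv_population"`.
#' @examples
#' luv <- luv_population(c(POPC = 99, PI4P = 1), total_lipid_nM = 5e4)
#' luv$lipids_per_vesicle   # about 20,600 for a 50-nm vesicle
#' luv$vesicle_nM           # about 2.43 nM at 50 uM lipid
#' @export
luv_population <- function(composition, total_lipid_nM,
                           diameter_nm = 50, did_per_lipid = 1e-4,
                           area_per_lipid_nm2 = 0.65,
                           bilayer_thickness_nm = 4,
                           accessible_fraction = 0.5) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector of lipid mol fractions")
  s <- sum(composition)
  if (abs(s - 100) < 1e-6 * 100) composition <- composition / 100
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition mol fractions must sum to 1 (or mol percents to 100)")
  if (any(composition < 0)) stop("mol fractions must be nonnegative")
  if (!is.numeric(total_lipid_nM) || total_lipid_nM <= 0)
    stop("total_lipid_nM must be positive")
  if (diameter_nm <= 2 * bilayer_thickness_nm)
    stop("diameter must exceed twice the bilayer thickness")

  r_out <- diameter_nm / 2
  r_in <- r_out - bilayer_thickness_nm
  n_outer <- 4 * pi * r_out^2 / area_per_lipid_nm2
  n_inner <- 4 * pi * r_in^2 / area_per_lipid_nm2
  n_lipids <- n_outer + n_inner

  if (identical(accessible_fraction, "geometric"))
    accessible_fraction <- n_outer / n_lipids
  if (!is.numeric(accessible_fraction) ||
      accessible_fraction <= 0 || accessible_fraction > 1)
    stop("accessible_fraction must be in (0, 1] or \"geometric\"")

  structure(list(
    composition = composition,
    total_lipid_nM = total_lipid_nM,
    diameter_nm = diameter_nm,
    did_per_lipid = did_per_lipid,
    area_per_lipid_nm2 = area_per_lipid_nm2,
    bilayer_thickness_nm = bilayer_thickness_nm,
    lipids_per_vesicle = n_lipids,
    outer_leaflet_lipids = n_outer,
    inner_leaflet_lipids = n_inner,
    vesicle_nM = total_lipid_nM / n_lipids,
    mean_dyes_per_vesicle = did_per_lipid * n_lipids,
    accessible_fraction = accessible_fraction
  ), class = "luv_population")
}

#' @export
print.luv_population <- function(x, ...) {
  cat("LUV population:", x$diameter_nm, "nm,",
      format(x$total_lipid_nM / 1e3), "uM lipid,",
      round(x$lipids_per_vesicle), "lipids/vesicle,",
      signif(x$vesicle_nM, 4), "nM vesicles\n")
  comp <- sort(x$composition, decreasing = TRUE)
  cat("  composition:",
      paste(sprintf("%s %.3g%%", names(comp), 100 * comp), collapse = ", "), "\n")
  if (x$did_per_lipid > 0)
    cat("  DiD labeled:", signif(x$mean_dyes_per_vesicle, 3),
        "dyes/vesicle on average\n")
  invisible(x)
}

#' Accessible cargo concentration in a LUV population
#'
#' The solution-facing concentration of a cargo lipid:
#' `accessible_fraction * mol fraction * total lipid concentration`.
#' A species absent from the composition contributes 0.
#'
#' @param population A [luv_population()].
#' @param species Lipid name (e.g. `"POPS"`, `"PI4P"`), or a cargo
#'   headgroup (`"PS"`, `"PI4P"`) to sum over all species carrying it.
#' @param extractable_only If `TRUE`, count only species the transporter
#'   can actually pull out (excludes diphytanoyl variants).
#' @return Concentration in nM.
#' @export
accessible_cargo <- function(population, species, extractable_only = FALSE) {
  stopifnot(inherits(population, "luv_population"))
  comp <- population$composition
  info <- lipid_info(names(comp))
  if (species %in% c("PS", "PI4P") && !(species %in% names(comp))) {
    sel <- !is.na(info$cargo) & info$cargo == species
  } else {
    sel <- names(comp) == species
  }
  if (extractable_only) sel <- sel & info$extractable
  if (!any(sel)) return(0)
  population$accessible_fraction * sum(comp[sel]) * population$total_lipid_nM
}
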