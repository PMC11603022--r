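#' Lipid species registry
#'
#' Built-in table of the lipid species used throughout the assay
#' definitions. Each species carries the headgroup net charge at neutral
#' pH (in elementary charges), whether it is a transporter cargo (PS or
#' PI4P headgroup), whether it can actually be extracted from a bilayer
#' (diphytanoyl variants cannot: their methylated chains prevent uptake
#' even though the headgroup is recognised), and a coarse acyl-tail
#' class used by the membrane fluidity and lipid-packing multipliers.
#'
#' Tail classes: `"fluid"` (di-unsaturated chains, DAG), `"standard"`
#' (palmitoyl-oleoyl), `"rigidifying"` (cholesterol), and
#' `"packing_defect"` (diphytanoyl chains, which expose headgroup charge
#' through packing defects).
#'
#' @return A data frame with columns `name`, `headgroup_charge`,
#'   `cargo` (`NA`, `"PS"` or `"PI4P"`), `extractable`, `tail_class`.
#' @examples
#' lipid_table()
#' @export
lipid_table <- function() {
  tab <- rbind(
    data.frame(name = "POPC",        headgroup_charge =  0, cargo = NA,     extractable = FALSE, tail_class = "standard"),
    data.frame(name = "DOPC",        headgroup_charge =  0, cargo = NA,     extractable = FALSE, tail_class = "fluid"),
    data.frame(name = "POPE",        headgroup_charge =  0, cargo = NA,     extractable = FALSE, tail_class = "standard"),
    data.frame(name = "POPS",        headgroup_charge = -1, cargo = "PS",   extractable = TRUE,  tail_class = "standard"),
    data.frame(name = "DOPS",        headgroup_charge = -1, cargo = "PS",   extractable = TRUE,  tail_class = "fluid"),
    data.frame(name = "phPS",        headgroup_charge = -1, cargo = "PS",   extractable = FALSE, tail_class = "packing_defect"),
    data.frame(name = "POPG",        headgroup_charge = -1, cargo = NA,     extractable = FALSE, tail_class = "standard"),
    data.frame(name = "phPG",        headgroup_charge = -1, cargo = NA,     extractable = FALSE, tail_class = "packing_defect"),
    data.frame(name = "POPA",        headgroup_charge = -1, cargo = NA,     extractable = FALSE, tail_class = "standard"),
    data.frame(name = "phPA",        headgroup_charge = -1, cargo = NA,     extractable = FALSE, tail_class = "packing_defect"),
    data.frame(name = "PI",          headgroup_charge = -1, cargo = NA,     extractable = FALSE, tail_class = "standard"),
    data.frame(name = "PI4P",        headgroup_charge = -1, cargo = "PI4P", extractable = TRUE,  tail_class = "standard"),
    data.frame(name = "PI4P_di16_0", headgroup_charge = -1, cargo = "PI4P", extractable = TRUE,  tail_class = "standard"),
    data.frame(name = "PI4P_16_0_18_1", headgroup_charge = -1, cargo = "PI4P", extractable = TRUE, tail_class = "standard"),
    data.frame(name = "PIP2",        headgroup_charge = -4, cargo = NA,     extractable = FALSE, tail_class = "standard"),
    data.frame(name = "cholesterol", headgroup_charge =  0, cargo = NA,     extractable = FALSE, tail_class = "rigidifying"),
    data.frame(name = "DAG",         headgroup_charge =  0, cargo = NA,     extractable = FALSE, tail_class = "fluid")
  )
  tab
}

#' Look up lipid species by name
#'
#' @param names Character vector of lipid names; must be present in
#'   [lipid_table()]. Unknown names are returned as neutral, standard,
#'   non-cargo placeholders with a warning, so that a composition with an
#'   exotic spacer lipid still builds.
#' @return Rows of [lipid_table()] in the order of `names`.
#' @export
lipid_info <- function(names) {
  tab <- lipid_table()
  idx <- match(names, tab$name)
  if (anyNA(idx)) {
    unknown <- names[is.na(idx)]
    warning("unknown lipid(s) treated as neutral/standard: ",
            paste(unknown, collapse = ", "))
    filler <- data.frame(name = unknown, headgroup_charge = 0, cargo = NA,
                         extractable = FALSE, tail_class = "standard")
    out <- rbind(tab[idx[!is.na(idx)], , drop = FALSE], filler)
    out <- out[match(names, out$name), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# charge density: sum of |headgroup charge| x mol fraction
charge_density <- function(composition) {
  info <- lipid_info(names(composition))
  sum(abs(info$headgroup_charge) * composition)
}

# fluidity score: mol-fraction weighted ordinal tail-class score,
# normalised so a pure POPC membrane scores 1
fluidity_score <- function(composition,
                           scores = c(fluid = 1.5, standard = 1.0,
                                      rigidifying = 0.3, packing_defect = 1.0)) {
  info <- lipid_info(names(composition))
  sum(scores[info$tail_class] * composition)
}

# mol fraction of packing-defect (diphytanoyl) lipids
packing_defect_fraction <- function(composition) {
  info <- lipid_info(names(composition))
  sum(composition[info$tail_class == "packing_defect"])
}
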