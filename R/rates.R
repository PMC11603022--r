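#' Initial extraction rate from a readout series
#'
#' The initial extraction rate (cargo per transporter per minute) is
#' estimated from the relative drop of the readout R = Gcc(0)/GR(0)
#' between protein addition and time `t`:
#'
#'   v_ext = (c_lipid_acc / c_protein) * (R_0 - R_t) / (R_0 * t)
#'
#' `t` defaults to 1 min for PS (the temporal resolution of the assay;
#' PS extraction is essentially complete within it) and 3 min for the
#' slower PI4P extraction.
#'
#' @param series A [readout_series()] containing t = 0 and t.
#' @param c_lipid_acc_nM Accessible cargo concentration in the donor
#'   LUVs (nM). By the package's default convention this is the
#'   outer-leaflet (accessible) pool; pass the total cargo concentration
#'   to switch conventions.
#' @param c_protein_nM Transporter concentration (nM).
#' @param t Evaluation time in minutes, or `NULL` to use the
#'   cargo-specific default.
#' @param cargo `"PS"` or `"PI4P"`; sets the default `t`.
#' @return A `"rate_estimate"` list: `kind`, `value` (1/min), echoed
#'   inputs.
#' @examples
#' s <- readout_series(c(0, 1), c(1, 0))
#' extraction_rate(s, 250, 250, t = 1)$value   # 1 cargo/protein/min
#' @export
extraction_rate <- function(series, c_lipid_acc_nM, c_protein_nM,
                            t = NULL, cargo = c("PS", "PI4P")) {
  cargo <- match.arg(cargo)
  if (is.null(t)) t <- c(PS = 1, PI4P = 3)[[cargo]]
  R0 <- series_value(series, 0)
  Rt <- series_value(series, t)
  if (R0 <= 0) stop("baseline readout is zero; extraction rate undefined")
  v <- (c_lipid_acc_nM / c_protein_nM) * (R0 - Rt) / (R0 * t)
  rate_estimate("extraction", v,
                c_lipid_acc_nM = c_lipid_acc_nM, c_protein_nM = c_protein_nM,
                t = t, cargo = cargo)
}

#' Average transport rate from a readout series
#'
#' Average cargo delivery rate to the acceptor vesicles between `t1`
#' (extraction complete, transporter loaded) and `t2`:
#'
#'   v_transport = ((c_lipid_acc - c_protein) / c_protein) *
#'                 (R_t1 - R_t2) / (R_t1 * (t2 - t1))
#'
#' The available lipid is reduced by `c_protein` because, with the
#' extraction finished, one cargo per transporter already sits inside
#' the protein. Defaults: t1 = 1, t2 = 10 min for PS; t1 = 6,
#' t2 = 16 min for PI4P.
#'
#' @inheritParams extraction_rate
#' @param t1,t2 Evaluation window in minutes (`t2 > t1`), `NULL` for the
#'   cargo-specific defaults.
#' @export
transport_rate <- function(series, c_lipid_acc_nM, c_protein_nM,
                           t1 = NULL, t2 = NULL, cargo = c("PS", "PI4P")) {
  cargo <- match.arg(cargo)
  if (is.null(t1)) t1 <- c(PS = 1, PI4P = 6)[[cargo]]
  if (is.null(t2)) t2 <- c(PS = 10, PI4P = 16)[[cargo]]
  if (t2 <= t1) stop("t2 must exceed t1")
  if (c_lipid_acc_nM <= c_protein_nM)
    stop("transport rate requires the release regime ",
         "(accessible cargo > protein)")
  R1 <- series_value(series, t1)
  R2 <- series_value(series, t2)
  if (R1 <= 0) stop("readout at t1 is zero; transport rate undefined")
  v <- ((c_lipid_acc_nM - c_protein_nM) / c_protein_nM) *
    (R1 - R2) / (R1 * (t2 - t1))
  rate_estimate("transport", v,
                c_lipid_acc_nM = c_lipid_acc_nM, c_protein_nM = c_protein_nM,
                t1 = t1, t2 = t2, cargo = cargo)
}

#' Overall PI4P drop over the first ten minutes
#'
#' Dimensionless overall loss of PI4P from the donor vesicles within the
#' first `t_end` minutes, irrespective of whether it proceeded through
#' extraction or transport:
#'
#'   Delta = (c_lipid_acc / c_protein) * (R_0 - R_t_end) / R_0
#'
#' @inheritParams extraction_rate
#' @param t_end End of the monitoring window (minutes).
#' @export
pi4p_drop <- function(series, c_lipid_acc_nM, c_protein_nM, t_end = 10) {
  R0 <- series_value(series, 0)
  Rt <- series_value(series, t_end)
  if (R0 <= 0) stop("baseline readout is zero; drop undefined")
  v <- (c_lipid_acc_nM / c_protein_nM) * (R0 - Rt) / R0
  rate_estimate("pi4p_drop", v,
                c_lipid_acc_nM = c_lipid_acc_nM, c_protein_nM = c_protein_nM,
                t = t_end, cargo = "PI4P")
}

rate_estimate <- function(kind, value, ...) {
  structure(list(kind = kind, value = value, inputs = list(...)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  unit <- if (x$kind == "pi4p_drop") "(cargo/protein)" else "cargo/protein/min"
  cat(sprintf("%s estimate: %.4g %s\n", x$kind, x$value, unit))
  cat("  inputs:", paste(names(x$inputs), unlist(x$inputs),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

series_value <- function(series, t) {
  i <- which(abs(series$time_min - t) < 1e-9)
  if (!length(i) || is.na(series$readout[i[1]]))
    stop("readout series has no value at t = ", t,
         " min (interpolation is refused)")
  series$readout[i[1]]
}

#' Replicate statistics with single-pass outlier screening
#'
#' Points deviating from the full-sample mean by more than 1.5 standard
#' deviations are excluded in one pass; the survivors give the mean and
#' its standard error.
#'
#' @param values Numeric vector of replicate estimates (>= 3).
#' @return List: `mean`, `sem`, `kept` (indices of surviving points),
#'   `excluded`.
#' @examples
#' replicate_stats(c(rep(1, 9), 5))  # the 5.0 point is excluded
#' @export
replicate_stats <- function(values) {
  if (length(values) < 3) stop("need at least 3 replicate values")
  m <- mean(values)
  s <- stats::sd(values)
  keep <- if (s == 0) rep(TRUE, length(values))
          else abs(values - m) <= 1.5 * s
  if (!any(keep)) stop("all points excluded by the outlier screen")
  kept_vals <- values[keep]
  sem <- if (length(kept_vals) > 1) stats::sd(kept_vals) / sqrt(length(kept_vals))
         else 0
  list(mean = mean(kept_vals), sem = sem,
       kept = which(keep), excluded = which(!keep))
}

#' Two-sample pooled-variance t-test
#'
#' Classical two-sample t-test with pooled variance, two-sided.
#' Degenerate zero-variance inputs are handled explicitly: equal means
#' give p = 1, unequal means give p = 0 with a `degenerate` flag.
#'
#' @param a,b Numeric vectors (each >= 2 values).
#' @return List: `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
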