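#' Direct (brute-force) correlation estimator
#'
#' Unbiased direct evaluation of the temporal auto- and
#' cross-correlation functions
#' `G(tau) = <dI_a(t) dI_b(t + tau)> / (<I_a><I_b>)`
#' at a set of lags, with the means taken over the overlapping windows
#' of each lag. O(N x L); serves as the oracle the multi-tau estimator
#' is checked against.
#'
#' @param trace A [photon_trace()].
#' @param lag_bins Integer lags in bins (each < half the trace length).
#' @return A `"correlation_curve"` data frame: `lag_s`, `GG`, `GR`,
#'   `Gcc` (green -> red), `Gcc_rev` (red -> green).
#' @export
correlate_direct <- function(trace, lag_bins) {
  stopifnot(inherits(trace, "photon_trace"))
  n <- length(trace$g)
  lag_bins <- as.integer(lag_bins)
  if (any(lag_bins < 1) || any(lag_bins >= n / 2))
    stop("lags must be >= 1 bin and < half the trace length")
  if (mean(trace$g) == 0 || mean(trace$r) == 0)
    stop("zero-mean channel: correlation undefined")
  g <- as.numeric(trace$g)
  r <- as.numeric(trace$r)
  one <- function(a, b, k) {
    cnt <- n - k
    ia <- seq_len(cnt)
    ib <- ia + k
    ma <- mean(a[ia]); mb <- mean(b[ib])
    mean(a[ia] * b[ib]) / (ma * mb) - 1
  }
  out <- data.frame(
    lag_s = lag_bins * trace$bin_width_s,
    GG = vapply(lag_bins, function(k) one(g, g, k), numeric(1)),
    GR = vapply(lag_bins, function(k) one(r, r, k), numeric(1)),
    Gcc = vapply(lag_bins, function(k) one(g, r, k), numeric(1)),
    Gcc_rev = vapply(lag_bins, function(k) one(r, g, k), numeric(1)))
  class(out) <- c("correlation_curve", "data.frame")
  attr(out, "bin_width_s") <- trace$bin_width_s
  out
}

#' Multi-tau correlation estimator
#'
#' Logarithmically spaced correlation curves with progressive binning
#' (m points per cascade, pairwise averaging between cascades) and
#' symmetric normalization. Optionally the trace is split into equal
#' segments that are correlated independently; the returned curve is
#' then the segment mean with a standard error per lag, which the
#' diffusion fit uses as weights.
#'
#' @param trace A [photon_trace()].
#' @param m Points per cascade (even, default 16).
#' @param n_segments Number of trace segments (1 = no segmentation).
#' @return A `"correlation_curve"` with columns `lag_s`, `GG`, `GR`,
#'   `Gcc`, `Gcc_rev` and, when segmented, `se_GG`, `se_GR`, `se_Gcc`.
#' @export
correlate_multitau <- function(trace, m = 16, n_segments = 1) {
  stopifnot(inherits(trace, "photon_trace"))
  if (m %% 2 != 0) stop("m must be even")
  n <- length(trace$g)
  seg_len <- floor(n / n_segments)
  if (seg_len < 4 * m)
    stop("trace too short for one multi-tau cascade per segment")
  pairs <- list(GG = c("g", "g"), GR = c("r", "r"),
                Gcc = c("g", "r"), Gcc_rev = c("r", "g"))
  dead <- c(g = mean(trace$g) == 0, r = mean(trace$r) == 0)
  live <- vapply(pairs, function(p) !any(dead[p]), logical(1))
  if (!any(live)) stop("both channels are empty: nothing to correlate")
  if (any(dead))
    warning("channel(s) with zero mean skipped: ",
            paste(names(dead)[dead], collapse = ", "))
  seg_idx <- lapply(seq_len(n_segments), function(s)
    ((s - 1) * seg_len + 1):(s * seg_len))
  if (n_segments > 1) {
    # a segment in which a live channel recorded nothing carries no
    # correlation information at all; drop it (rare at sane count rates)
    ok <- vapply(seg_idx, function(idx) {
      all(vapply(c("g", "r")[!dead], function(ch)
        sum(trace[[ch]][idx]) > 0, logical(1)))
    }, logical(1))
    if (sum(ok) < 2)
      stop("fewer than 2 trace segments with counts in every live channel")
    if (!all(ok)) {
      warning(sum(!ok), " empty segment(s) dropped")
      seg_idx <- seg_idx[ok]
    }
  }
  seg_curves <- lapply(seg_idx, function(idx) {
    lapply(pairs[live], function(p)
      multitau_cpp(as.numeric(trace[[p[1]]][idx]),
                   as.numeric(trace[[p[2]]][idx]), m))
  })
  n_segments <- length(seg_curves)
  lags <- seg_curves[[1]][[1]]$lag_bins
  out <- data.frame(lag_s = lags * trace$bin_width_s)
  for (nm in names(pairs)) {
    if (!live[[nm]]) { out[[nm]] <- NA_real_; next }
    gmat <- vapply(seg_curves, function(sc) sc[[nm]]$G, numeric(length(lags)))
    gmat <- matrix(gmat, nrow = length(lags))
    out[[nm]] <- rowMeans(gmat)
    if (n_segments > 1 && nm != "Gcc_rev")
      out[[paste0("se_", nm)]] <- apply(gmat, 1, stats::sd) / sqrt(n_segments)
  }
  class(out) <- c("correlation_curve", "data.frame")
  attr(out, "bin_width_s") <- trace$bin_width_s
  out
}

#' @export
plot.correlation_curve <- function(x, which = c("GG", "GR", "Gcc"), ...) {
  which <- intersect(which, names(x))
  matplot(x$lag_s, as.matrix(x[which]), log = "x", type = "l", lty = 1,
          xlab = expression(tau ~ "(s)"), ylab = expression(G(tau)), ...)
  legend("topright", legend = which, col = seq_along(which), lty = 1,
         bty = "n")
  invisible(x)
}
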