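#' SPGR steady-state signal model
#'
#' Forward model for a spoiled gradient-recalled echo acquisition:
#' \deqn{S = M_0 \sin(b_1\alpha)\,(1 - E_1) / (1 - E_1\cos(b_1\alpha)),}
#' with \eqn{E_1 = \exp(-TR/T_1)} and \eqn{b_1} the ratio of true to
#' nominal flip angle. Used both as the simulation oracle for the fitters
#' and by the synthetic-data generator.
#'
#' @param m0 Equilibrium magnetisation (arbitrary units).
#' @param t1_ms Longitudinal relaxation time, ms (> 0).
#' @param tr_ms Repetition time, ms (> 0).
#' @param flip_nominal_deg Nominal flip angle, degrees.
#' @param b1_factor True/nominal flip-angle ratio (1 = perfect excitation).
#' @return Signal amplitude (same units as `m0`).
#' @export
spgr_signal <- function(m0, t1_ms, tr_ms, flip_nominal_deg,
                        b1_factor = 1) {
  stopifnot(all(t1_ms > 0), all(tr_ms > 0))
  a <- b1_factor * flip_nominal_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Two-point variable flip angle T1 estimate
#'
#' Linearises the SPGR equation with the B1-corrected true angles
#' \eqn{\alpha' = b_1 \alpha}: plotting \eqn{y = S/\sin\alpha'} against
#' \eqn{x = S/\tan\alpha'} puts both measurements on a line of slope
#' \eqn{E_1}, and \eqn{T_1 = -TR/\ln E_1}. With exactly two flip angles the
#' slope is solved exactly rather than by least squares.
#'
#' @param s_low,s_high Signals at the low (default 3 deg) and high (default
#'   14 deg) nominal flip angles; vectorised over voxels.
#' @param tr_ms Repetition time, ms (acquisition default 10.6 ms).
#' @param b1_factor True/nominal flip-angle ratio per voxel.
#' @param flip_low_deg,flip_high_deg Nominal flip angles, degrees.
#' @return T1 in ms; `NA` flags non-physical voxels where the implied
#'   \eqn{E_1} falls outside `(0, 1)`.
#' @examples
#' s3 <- spgr_signal(1000, 1300, 10.6, 3)
#' s14 <- spgr_signal(1000, 1300, 10.6, 14)
#' vfa_t1_fit(s3, s14)  # 1300
#' @export
vfa_t1_fit <- function(s_low, s_high, tr_ms = 10.6, b1_factor = 1,
                       flip_low_deg = 3, flip_high_deg = 14) {
  stopifnot(tr_ms > 0)
  a_lo <- b1_factor * flip_low_deg * pi / 180
  a_hi <- b1_factor * flip_high_deg * pi / 180
  y_lo <- s_low / sin(a_lo); x_lo <- s_low / tan(a_lo)
  y_hi <- s_high / sin(a_hi); x_hi <- s_high / tan(a_hi)
  e1 <- (y_hi - y_lo) / (x_hi - x_lo)
  t1 <- -tr_ms / log(e1)
  t1[!(e1 > 0 & e1 < 1)] <- NA_real_  # non-physical voxel, flagged not fatal
  t1
}

#' B1 factor by the method of slopes
#'
#' Near the signal null at 180 degrees the SPGR signal falls roughly
#' linearly with flip angle. Extrapolating the line through the two
#' calibration measurements (nominal 130 and 150 degrees) to zero signal
#' locates the nominal angle \eqn{\alpha_0} at which the true angle is 180
#' degrees, so \eqn{b_1 = 180/\alpha_0}.
#'
#' @param s_130,s_150 Signals at nominal 130 and 150 degrees; must be
#'   decreasing (`s_130 > s_150 >= 0`) for the extrapolation to be valid.
#' @return Estimated B1 factor.
#' @examples
#' b1_method_of_slopes(50, 30)  # null at 180: b1 = 1
#' @export
b1_method_of_slopes <- function(s_130, s_150) {
  if (any(!(s_130 > s_150) | s_150 < 0)) {
    stop("signals must decrease toward the null: s_130 > s_150 >= 0")
  }
  slope <- (s_150 - s_130) / 20
  alpha0 <- 130 - s_130 / slope
  180 / alpha0
}

#' Regional T1 from the histogram mode
#'
#' Regional T1 distributions are generally unimodal but positively skewed
#' (gray matter/CSF partial volumes), and may show a small low-T1 white
#' matter shoulder, so the mode rather than the mean represents the region.
#' Voxels with gray matter probability at or below `gm_threshold` are
#' discarded (strict `>`), T1 values are clipped inclusively to the
#' histogram window, counts are binned at `bin_width_ms` with the left edge
#' fixed at `t1_min`, a smoothing spline is fit to the (bin center, count)
#' pairs with smoothing chosen by generalized cross-validation (falling
#' back to cubic interpolation when fewer than 8 occupied-range bins
#' exist), and the mode is the argmax of the fitted curve on a 1 ms grid.
#' Ties break toward lower T1. The spline is fit to square-root counts — a
#' variance-stabilising transform for Poisson-like bin counts that matches
#' the homoscedasticity GCV assumes; being monotone it leaves the argmax of
#' the underlying shape unchanged.
#'
#' @param t1_ms Numeric vector of voxel T1 values, ms.
#' @param gm_prob Gray matter probabilities in `[0, 1]`, same length.
#' @param gm_threshold Strict lower bound on gray matter probability
#'   (default 0.40).
#' @param t1_min,t1_max Histogram window, ms (default 500-5000, inclusive).
#' @param bin_width_ms Bin width, ms (default 30).
#' @param min_voxels Minimum retained voxels required (default 50); fewer
#'   marks the region missing rather than erroring.
#' @return A list with `mode_ms` (`NA` when too few voxels),
#'   `n_voxels_used`, and `reason` (`NA` or an explanation string).
#' @export
roi_t1_mode <- function(t1_ms, gm_prob, gm_threshold = 0.40,
                        t1_min = 500, t1_max = 5000, bin_width_ms = 30,
                        min_voxels = 50) {
  stopifnot(length(t1_ms) == length(gm_prob), t1_max > t1_min,
            bin_width_ms > 0)
  keep <- gm_prob > gm_threshold & t1_ms >= t1_min & t1_ms <= t1_max
  x <- t1_ms[keep]
  n <- length(x)
  if (n < min_voxels) {
    return(list(mode_ms = NA_real_, n_voxels_used = n,
                reason = sprintf("only %d voxels after filtering (< %d)",
                                 n, min_voxels)))
  }
  n_bins <- ceiling((t1_max - t1_min) / bin_width_ms)
  ## left edge fixed at t1_min; the closed upper edge folds into the last bin
  bin <- pmin(floor((x - t1_min) / bin_width_ms) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- t1_min + (seq_len(n_bins) - 0.5) * bin_width_ms
  occupied <- which(counts > 0)
  if (length(occupied) == 1L) {  # degenerate: all mass in one bin
    return(list(mode_ms = centers[occupied], n_voxels_used = n,
                reason = NA_character_))
  }
  ## Fit over the occupied span only; empty far tails carry no shape
  ## information and drag the GCV smoother toward a flat line.
  span <- seq(min(occupied), max(occupied))
  cx <- centers[span]
  cy <- sqrt(counts[span])  # variance-stabilised; argmax-preserving
  grid <- seq(max(t1_min, min(cx)), min(t1_max, max(cx)), by = 1)
  fitted <- if (length(cx) >= 8L) {
    fit <- stats::smooth.spline(cx, cy, cv = FALSE)  # GCV smoothing
    stats::predict(fit, grid)$y
  } else {
    stats::spline(cx, cy, xout = grid)$y
  }
  mode_ms <- grid[which.max(fitted)]  # which.max ties -> lowest T1
  list(mode_ms = mode_ms, n_voxels_used = n, reason = NA_character_)
}

#' Extract per-region T1 modes from a long voxel table
#'
#' @param voxels Data frame with columns `roi_name`, `t1_ms`, `gm_prob`
#'   (long format, one row per voxel).
#' @param ... Passed to [roi_t1_mode()].
#' @return Data frame with one row per region: `roi_name`, `mode_ms`,
#'   `n_voxels_used`, `reason`.
#' @export
extract_t1_modes <- function(voxels, ...) {
  stopifnot(all(c("roi_name", "t1_ms", "gm_prob") %in% names(voxels)))
  rois <- unique(voxels$roi_name)
  rows <- lapply(rois, function(r) {
    sub <- voxels[voxels$roi_name == r, ]
    m <- roi_t1_mode(sub$t1_ms, sub$gm_prob, ...)
    data.frame(roi_name = r, mode_ms = m$mode_ms,
               n_voxels_used = m$n_voxels_used, reason = m$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
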