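#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the structure of the study cohort the analyses are
#' designed for: three groups (14 cisgender boys, 16 gender-dysphoric
#' adolescents assigned female at birth, 17 cisgender girls) aged 12-17;
#' group-specific EROS phase/strength and GIDYQ-AA score distributions at
#' the reported group moments; a surface-area (and smaller cortical
#' thickness) elevation in cisgender boys on a designated set of regions;
#' and negative within-group correlations of designated T1 columns with age
#' and phase present only in the CB and GD groups.
#'
#' @param group_sizes Named integer vector `c(CB=, GD=, CG=)`.
#' @param age_range_months Inclusive age range in months.
#' @param eros_phase_params,eros_strength_params,gidyq_params Per-group
#'   `(mean, sd)` rows, groups in CB/GD/CG order. Phase in degrees.
#' @param sa_effect,ct_effect Standardised CB-vs-rest shift on the planted
#'   surface-area / cortical-thickness columns.
#' @param t1_behavior_corr Target within-group correlation of planted T1
#'   columns with age and with phase inside CB and GD (zero in CG); must
#'   satisfy `2 * corr^2 < 1`.
#' @param noise_sd Standard deviation of the ROI noise.
#' @param n_sa_planted,n_ct_planted,n_t1_planted Sizes of the planted
#'   column sets (disjoint per metric by construction).
#' @param voxels_per_roi Voxel count for [simulate_roi_voxels()] defaults.
#' @param seed Integer seed; same seed, bit-identical dataset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(CB = 14L, GD = 16L, CG = 17L),
                       age_range_months = c(144L, 215L),
                       eros_phase_params = rbind(CB = c(64.60, 9.29),
                                                 GD = c(46.38, 15.23),
                                                 CG = c(30.94, 13.18)),
                       eros_strength_params = rbind(CB = c(3.25, 1.28),
                                                    GD = c(3.00, 1.30),
                                                    CG = c(2.83, 0.76)),
                       gidyq_params = rbind(CB = c(4.91, 0.12),
                                            GD = c(2.21, 0.35),
                                            CG = c(4.90, 0.15)),
                       sa_effect = 0.8, ct_effect = 0.5,
                       t1_behavior_corr = -0.5, noise_sd = 1.0,
                       n_sa_planted = 20L, n_ct_planted = 5L,
                       n_t1_planted = 33L, voxels_per_roi = 2000L,
                       seed = 1L) {
  stopifnot(all(names(group_sizes) == GROUP_CODES),
            all(group_sizes >= 2L),
            is.finite(sa_effect), is.finite(ct_effect),
            abs(t1_behavior_corr) < 1 / sqrt(2),
            noise_sd > 0)
  structure(list(
    group_sizes = group_sizes, age_range_months = age_range_months,
    eros_phase_params = eros_phase_params,
    eros_strength_params = eros_strength_params,
    gidyq_params = gidyq_params,
    sa_effect = sa_effect, ct_effect = ct_effect,
    t1_behavior_corr = t1_behavior_corr, noise_sd = noise_sd,
    n_sa_planted = as.integer(n_sa_planted),
    n_ct_planted = as.integer(n_ct_planted),
    n_t1_planted = as.integer(n_t1_planted),
    voxels_per_roi = as.integer(voxels_per_roi),
    seed = as.integer(seed)), class = "sim_config")
}

## Draw (phase, strength) pairs from normals at the group moments and
## invert to (androphilia, gynephilia); redraw on range violation rather
## than clipping, so the marginals carry no boundary atoms. Errors out if
## the rejection rate exceeds 20%.
draw_eros_pairs <- function(n, phase_mean, phase_sd, str_mean, str_sd,
                            max_reject = 0.20) {
  a <- g <- numeric(n)
  drawn <- 0L; kept <- 0L
  while (kept < n) {
    m <- max(n - kept, 16L)
    theta <- stats::rnorm(m, phase_mean, phase_sd) * pi / 180
    mag <- stats::rnorm(m, str_mean, str_sd)
    ai <- mag * cos(theta)
    gi <- mag * sin(theta)
    ok <- ai >= 1 & ai <= 5 & gi >= 1 & gi <= 5
    drawn <- drawn + m
    take <- which(ok)[seq_len(min(sum(ok), n - kept))]
    if (length(take) > 0L) {
      a[kept + seq_along(take)] <- ai[take]
      g[kept + seq_along(take)] <- gi[take]
      kept <- kept + length(take)
    }
    if (drawn >= 50L * n && kept / drawn < 1 - max_reject) {
      stop("EROS phase/strength parameters imply > ",
           round(100 * max_reject),
           "% invalid (androphilia, gynephilia) pairs; ",
           "adjust the group moments")
    }
  }
  list(androphilia = a, gynephilia = g)
}

## Truncated-normal draw by redraw within [lo, hi].
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  kept <- 0L
  while (kept < n) {
    x <- stats::rnorm(max(n - kept, 16L), mean, sd)
    x <- x[x >= lo & x <= hi]
    take <- seq_len(min(length(x), n - kept))
    out[kept + take] <- x[take]
    kept <- kept + length(take)
  }
  out
}

## Gaussian-copula scores of a vector: standard-normal quantiles of the
## mid-ranks, preserving the ordering of arbitrary marginals.
copula_scores <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Simulate a complete synthetic cohort
#'
#' Generates a participant table, a canonical ROI matrix with planted
#' effect structure, and a truth record listing the planted columns and
#' generating parameters. Ages are uniform over the configured range; EROS
#' phase/strength pairs are drawn at the configured group moments and
#' inverted to valid raw scores; GIDYQ-AA scores are drawn from truncated
#' normals that keep cisgender participants above and GD participants at or
#' below the caseness region. The ROI matrix is column-wise Gaussian noise
#' plus (i) an additive CB-group elevation on the planted surface-area and
#' cortical-thickness columns and (ii) planted T1 columns built through a
#' Gaussian copula so that, within CB and GD rows only, they correlate at
#' the target level with age and with phase.
#'
#' @param config A [sim_config()].
#' @param dictionary ROI dictionary (default packaged one).
#' @return List with `participants` (validated data frame), `roi` (an
#'   [roi_matrix()]), and `truth` (planted column labels + config).
#' @export
simulate_cohort <- function(config = sim_config(),
                            dictionary = roi_dictionary()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- config$group_sizes
  n <- sum(sizes)
  group <- factor(rep(GROUP_CODES, sizes), levels = GROUP_CODES)

  age <- sample(seq(config$age_range_months[1], config$age_range_months[2]),
                n, replace = TRUE)
  andro <- gyne <- gidyq <- numeric(n)
  for (g in GROUP_CODES) {
    rows <- which(group == g)
    pp <- config$eros_phase_params[g, ]
    sp <- config$eros_strength_params[g, ]
    eros <- draw_eros_pairs(length(rows), pp[1], pp[2], sp[1], sp[2])
    andro[rows] <- eros$androphilia
    gyne[rows] <- eros$gynephilia
    qp <- config$gidyq_params[g, ]
    ## cisgender scores stay above the caseness threshold; GD at or below
    ## the top observed GD score
    bounds <- if (g == "GD") c(1, 3.04) else c(3.001, 5)
    gidyq[rows] <- rnorm_trunc(length(rows), qp[1], qp[2],
                               bounds[1], bounds[2])
  }
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = group, age_months = age, gidyq_mean = gidyq,
    eros_androphilia = andro, eros_gynephilia = gyne,
    stringsAsFactors = FALSE)
  participants <- score_eros_vector(participants)
  participants <- validate_participants(participants)

  idx <- canonical_column_index(dictionary)
  p <- nrow(idx)
  values <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)

  planted <- list(
    ct = which(idx$metric == "CT")[seq_len(config$n_ct_planted)],
    sa = which(idx$metric == "SA")[seq_len(config$n_sa_planted)],
    t1 = which(idx$metric == "T1")[seq_len(config$n_t1_planted)])
  cb_rows <- which(group == "CB")
  values[cb_rows, planted$sa] <- values[cb_rows, planted$sa] +
    config$sa_effect * config$noise_sd
  values[cb_rows, planted$ct] <- values[cb_rows, planted$ct] +
    config$ct_effect * config$noise_sd

  rho <- config$t1_behavior_corr
  resid_sd <- sqrt(1 - 2 * rho^2)
  for (g in c("CB", "GD")) {
    rows <- which(group == g)
    z_age <- copula_scores(participants$age_months[rows])
    z_phase <- copula_scores(participants$attraction_phase_deg[rows])
    for (col in planted$t1) {
      values[rows, col] <- config$noise_sd *
        (rho * z_age + rho * z_phase +
           resid_sd * stats::rnorm(length(rows)))
    }
  }

  rownames(values) <- participants$participant_id
  roi <- roi_matrix(values, idx, is_zscored = FALSE)
  labels <- colnames(roi$values)
  truth <- list(
    planted_sa = labels[planted$sa],
    planted_ct = labels[planted$ct],
    planted_t1 = labels[planted$t1],
    config = config)
  list(participants = participants, roi = roi, truth = truth)
}

#' Simulate voxel T1 samples for one region
#'
#' Draws a right-skewed unimodal T1 distribution with its analytic mode at
#' `true_mode_ms` (a shifted gamma whose skewness equals `skew`; `skew = 0`
#' gives a normal), plus optional contaminant voxels — half a white-matter
#' like low-T1 peak, half a CSF-like high-T1 tail — whose gray matter
#' probabilities fall at or below the 0.40 screening threshold while the
#' main sample sits above it.
#'
#' @param true_mode_ms Mode of the clean distribution, ms, in (500, 5000).
#' @param skew Gamma skewness of the clean sample (>= 0; 0 = symmetric).
#' @param contamination_frac Fraction of contaminant voxels in `[0, 1)`.
#' @param n Total voxel count.
#' @param scale_ms Spread of the clean distribution, ms.
#' @param seed Optional integer seed.
#' @return Data frame with `t1_ms` and `gm_prob` (one row per voxel).
#' @export
simulate_roi_voxels <- function(true_mode_ms, skew = 1,
                                contamination_frac = 0, n = 2000L,
                                scale_ms = 150, seed = NULL) {
  stopifnot(true_mode_ms > 500, true_mode_ms < 5000, skew >= 0,
            contamination_frac >= 0, contamination_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  n_cont <- round(n * contamination_frac)
  n_clean <- n - n_cont
  t1 <- if (skew == 0) {
    stats::rnorm(n_clean, true_mode_ms, scale_ms)
  } else {
    shape <- (2 / skew)^2          # gamma skewness = 2 / sqrt(shape)
    theta <- scale_ms / sqrt(shape)  # sd = sqrt(shape) * theta = scale_ms
    shift <- true_mode_ms - (shape - 1) * theta  # mode = (shape-1)*theta
    shift + stats::rgamma(n_clean, shape = shape, scale = theta)
  }
  gm <- stats::runif(n_clean, 0.55, 1)
  if (n_cont > 0L) {
    n_wm <- n_cont %/% 2L
    n_csf <- n_cont - n_wm
    t1 <- c(t1,
            stats::rnorm(n_wm, max(600, true_mode_ms - 400), 80),
            stats::rnorm(n_csf, 3500, 300))
    gm <- c(gm, stats::runif(n_cont, 0, 0.40))
  }
  data.frame(t1_ms = t1, gm_prob = gm)
}

#' Simulate noisy SPGR signals for one voxel
#'
#' Forward-simulates the two T1-mapping signals (nominal 3 and 14 degrees,
#' TR 10.6 ms) and the two B1-calibration signals (nominal 130 and 150
#' degrees, TR 55 ms) from [spgr_signal()], with additive Gaussian noise.
#'
#' @param t1_ms True T1, ms.
#' @param m0 Equilibrium magnetisation.
#' @param b1 True/nominal flip-angle ratio.
#' @param noise_sd Additive noise SD (signal units).
#' @param seed Optional integer seed.
#' @param tr_t1_ms,tr_b1_ms Repetition times for the two acquisitions.
#' @return List with `s_low`, `s_high`, `tr_ms`, `s_130`, `s_150`,
#'   `tr_b1_ms`, `b1`.
#' @export
simulate_spgr_voxel <- function(t1_ms, m0 = 1000, b1 = 1, noise_sd = 0,
                                seed = NULL, tr_t1_ms = 10.6,
                                tr_b1_ms = 55) {
  if (!is.null(seed)) set.seed(seed)
  noise <- function(s) s + stats::rnorm(length(s), 0, noise_sd)
  list(
    s_low = noise(spgr_signal(m0, t1_ms, tr_t1_ms, 3, b1)),
    s_high = noise(spgr_signal(m0, t1_ms, tr_t1_ms, 14, b1)),
    tr_ms = tr_t1_ms,
    s_130 = noise(spgr_signal(m0, t1_ms, tr_b1_ms, 130, b1)),
    s_150 = noise(spgr_signal(m0, t1_ms, tr_b1_ms, 150, b1)),
    tr_b1_ms = tr_b1_ms,
    b1 = b1)
}
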