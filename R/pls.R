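#' Z-score the columns of a brain matrix
#'
#' Each column (one region-metric pair) is centered and scaled by its
#' sample standard deviation across all participants, so cortical
#' thickness, surface area and T1 enter the multivariate analyses on a
#' common scale regardless of units or distributional range.
#'
#' @param x An [roi_matrix()] or plain numeric matrix.
#' @return The same type of object, z-scored (mean 0, unit n-1 SD per
#'   column); idempotent up to numerical precision.
#' @export
zscore_columns <- function(x) {
  is_roi <- inherits(x, "roi_matrix")
  values <- if (is_roi) x$values else as.matrix(x)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(values)[sds == 0], collapse = ", "))
  }
  z <- scale(values, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (is_roi) roi_matrix(z, x$column_index, is_zscored = TRUE) else z
}

pls_values <- function(x) if (inherits(x, "roi_matrix")) x$values else as.matrix(x)

group_indices <- function(group, min_groups = 2L) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < min_groups) {
    stop("need at least ", min_groups, " groups")
  }
  if (any(table(group) < 2L)) stop("every group needs at least 2 members")
  split(seq_along(group), group)
}

## SVD of a cross-block matrix M (design rows x brain columns), returning
## brain saliences u (columns of M'), design weights v, singular values s.
## Sign fixed per LV so the largest-magnitude element of v is positive.
pls_svd <- function(M) {
  sv <- svd(M)
  v <- sv$u
  u <- sv$v
  s <- sv$d
  for (j in seq_along(s)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  list(u = u, s = s, v = v)
}

## Group-mean matrix minus the column grand mean. "unweighted": grand mean
## of the group means (classical mean-centered Task PLS); "weighted":
## participant-weighted grand mean.
task_cross_block <- function(Z, idx, centering = "unweighted") {
  M <- do.call(rbind, lapply(idx, function(i) colMeans(Z[i, , drop = FALSE])))
  grand <- if (centering == "unweighted") colMeans(M) else colMeans(Z)
  sweep(M, 2, grand)
}

## Stacked within-group behavior-brain Pearson correlations, group-major:
## rows are (group 1: behavior 1..b), (group 2: behavior 1..b), ...
behavior_cross_block <- function(Z, idx, B, check = TRUE) {
  blocks <- lapply(idx, function(i) {
    Bg <- B[i, , drop = FALSE]
    if (check) {
      sds <- apply(Bg, 2, stats::sd)
      if (any(sds == 0)) {
        stop("zero behavior variance within a group: ",
             paste(colnames(B)[sds == 0], collapse = ", "))
      }
    }
    stats::cor(Bg, Z[i, , drop = FALSE])
  })
  R <- do.call(rbind, blocks)
  rownames(R) <- as.vector(t(outer(names(idx), colnames(B), paste,
                                   sep = ":")))
  R
}

new_pls_result <- function(analysis, core, Z, group, idx, B = NULL,
                           column_index = NULL, centering = "unweighted") {
  s <- core$s
  structure(list(
    analysis = analysis,
    u = core$u, s = s, v = core$v,
    cov_explained = s^2 / sum(s^2),
    brain_scores = Z %*% core$u,
    design_rows = rownames(core$v),
    group = group, group_index = idx,
    Z = Z, B = B,
    column_index = column_index,
    centering = centering,
    perm_p = NULL, bootstrap_ratio = NULL, stable_mask = NULL,
    ci = NULL), class = "pls_result")
}

#' Mean-centered Task PLS
#'
#' Decomposes the group structure of a z-scored brain matrix: the group
#' means are column-centered (by default at the unweighted mean of the
#' group means) and the centered matrix is factored by singular value
#' decomposition into latent variables, each pairing a group contrast `v`
#' with brain saliences `u` and a strength `s`. Covariance explained by
#' latent variable i is \eqn{s_i^2 / \sum_j s_j^2}; brain scores are the
#' projections `Z u`.
#'
#' @param Z Z-scored brain data ([roi_matrix()] with `is_zscored` or plain
#'   matrix); see [zscore_columns()].
#' @param group Group label per participant row (factor or character);
#'   at least two groups of two.
#' @param centering `"unweighted"` (default) or `"weighted"` grand-mean
#'   removal.
#' @return A `pls_result` with saliences `u` (columns x LV), singular
#'   values `s`, group contrasts `v`, `cov_explained`, and `brain_scores`;
#'   inference fields are filled by [pls_permutation()] and
#'   [pls_bootstrap()].
#' @export
task_pls <- function(Z, group, centering = c("unweighted", "weighted")) {
  centering <- match.arg(centering)
  values <- pls_values(Z)
  idx <- group_indices(group)
  Mc <- task_cross_block(values, idx, centering)
  rownames(Mc) <- names(idx)
  core <- pls_svd(Mc)
  rownames(core$v) <- names(idx)
  new_pls_result("task", core, values, as.factor(group), idx,
                 column_index = if (inherits(Z, "roi_matrix")) Z$column_index,
                 centering = centering)
}

#' Behavior PLS of brain-behavior correlations
#'
#' Correlates each behavior with every brain column within each group
#' (Pearson, on the raw behavior values and the globally z-scored brain
#' columns), stacks the correlation blocks group-major, and factors the
#' stack by singular value decomposition. Latent variables express
#' commonalities and differences in brain-behavior correlation patterns
#' across groups. For reporting, the correlations of the brain scores with
#' each behavior within each group are also computed — these reflect the
#' observed contrast.
#'
#' @inheritParams task_pls
#' @param B Numeric matrix of behaviors (participants x behaviors), complete,
#'   with column names (e.g. strength, phase, age).
#' @return A `pls_result`; `v` rows are group-by-behavior (group-major) and
#'   the element `bs_behavior_cor` holds the per-group brain-score/behavior
#'   correlations (same row layout, columns = latent variables).
#' @export
behavior_pls <- function(Z, group, B) {
  values <- pls_values(Z)
  B <- as.matrix(B)
  if (is.null(colnames(B))) colnames(B) <- paste0("b", seq_len(ncol(B)))
  if (anyNA(B)) stop("behavior values must be complete for all participants")
  if (nrow(B) != nrow(values)) stop("Z and B row counts differ")
  idx <- group_indices(group, min_groups = 1L)
  R <- behavior_cross_block(values, idx, B)
  core <- pls_svd(R)
  rownames(core$v) <- rownames(R)
  res <- new_pls_result("behavior", core, values, as.factor(group), idx,
                        B = B,
                        column_index = if (inherits(Z, "roi_matrix"))
                          Z$column_index)
  res$bs_behavior_cor <- brain_score_behavior_cor(res$brain_scores, idx, B)
  res
}

## Per-group correlations of brain scores with each behavior; rows
## group-major matching the behavior cross-block layout.
brain_score_behavior_cor <- function(scores, idx, B) {
  out <- do.call(rbind, lapply(idx, function(i) {
    stats::cor(B[i, , drop = FALSE], scores[i, , drop = FALSE])
  }))
  rownames(out) <- as.vector(t(outer(names(idx), colnames(B), paste,
                                     sep = ":")))
  out
}

recompute_s <- function(res, Z, idx, B = NULL) {
  M <- if (res$analysis == "task") {
    task_cross_block(Z, idx, res$centering)
  } else {
    behavior_cross_block(Z, idx, B, check = FALSE)
  }
  svd(M, nu = 0, nv = 0)$d
}

#' Permutation test on latent variable strength
#'
#' Re-runs the cross-block construction and SVD under the null: for Task
#' PLS, participants are randomly reassigned to groups (rows of the brain
#' matrix permuted against the fixed group structure); for Behavior PLS,
#' the behavior rows are permuted against the brain rows with group
#' membership fixed. The p-value of latent variable i is the fraction of
#' permutations whose i-th singular value meets or exceeds the observed one
#' (position-wise, no rotation), with no add-one smoothing — a never-exceeded
#' observed value reports p = 0.
#'
#' @param result A `pls_result` from [task_pls()] or [behavior_pls()].
#' @param n_perm Number of permutations (>= 1; 1000 in the reference
#'   analyses).
#' @param seed Optional integer seed for reproducibility.
#' @return The `pls_result` with `perm_p` (one p per latent variable) and
#'   `n_perm` filled in.
#' @export
pls_permutation <- function(result, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(result, "pls_result"), n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(result$Z)
  exceed <- numeric(length(result$s))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    s_perm <- if (result$analysis == "task") {
      recompute_s(result, result$Z[perm, , drop = FALSE], result$group_index)
    } else {
      recompute_s(result, result$Z, result$group_index,
                  B = result$B[perm, , drop = FALSE])
    }
    exceed <- exceed + (s_perm >= result$s)
  }
  result$perm_p <- exceed / n_perm
  result$n_perm <- n_perm
  result
}

procrustes_rotation <- function(v_rep, v_orig) {
  sv <- svd(crossprod(v_rep, v_orig))
  sv$u %*% t(sv$v)
}

#' Bootstrap stability of saliences and contrast estimates
#'
#' Participants are resampled with replacement within group (stratified
#' bootstrap) and the full cross-block + SVD recomputed per replicate. Each
#' replicate's axes are aligned to the original solution by an orthogonal
#' Procrustes rotation of the design weights `v`, with the same rotation
#' applied to the scaled saliences `u diag(s)`. The bootstrap ratio of a
#' brain column is its observed scaled salience divided by the standard
#' deviation of the aligned replicate values; ratios beyond the threshold
#' (default 3, approximately a z-score) mark stable columns. Percentile
#' confidence intervals are computed for the contrast quantities: group
#' mean brain scores (Task) or per-group brain-score/behavior correlations
#' (Behavior). Degenerate Behavior replicates (zero within-group variance)
#' are redrawn and counted.
#'
#' @param result A `pls_result`.
#' @param n_boot Number of bootstrap replicates (1000 in the reference
#'   analyses).
#' @param threshold Bootstrap-ratio stability threshold (default 3).
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @param seed Optional integer seed.
#' @return The `pls_result` with `bootstrap_ratio` (columns x LV),
#'   `stable_mask`, `ci` (a list with `estimate`, `lower`, `upper` for the
#'   contrast quantities), `n_boot`, `threshold` and `n_redrawn` filled in.
#' @export
pls_bootstrap <- function(result, n_boot = 1000, threshold = 3,
                          ci_level = 0.95, seed = NULL) {
  stopifnot(inherits(result, "pls_result"), n_boot >= 1, threshold > 0,
            ci_level > 0, ci_level < 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- result$group_index
  if (any(lengths(idx) < 2L)) stop("every group must have >= 2 members")
  k <- length(result$s)
  p <- nrow(result$u)
  US_obs <- result$u %*% diag(result$s, k)
  US_reps <- array(NA_real_, c(p, k, n_boot))
  contrast_obs <- if (result$analysis == "task") {
    t(vapply(idx, function(i)
      colMeans(result$brain_scores[i, , drop = FALSE]), numeric(k)))
  } else {
    result$bs_behavior_cor
  }
  contrast_reps <- array(NA_real_, c(nrow(contrast_obs), k, n_boot))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      rows <- unlist(lapply(idx, function(i) {
        i[sample.int(length(i), replace = TRUE)]
      }), use.names = FALSE)
      ## after row subsetting, groups sit in consecutive blocks
      blocks <- split(seq_along(rows),
                      rep(seq_along(idx), lengths(idx)))
      names(blocks) <- names(idx)
      Zb <- result$Z[rows, , drop = FALSE]
      if (result$analysis == "behavior") {
        Bb <- result$B[rows, , drop = FALSE]
        degenerate <- any(vapply(blocks, function(i) {
          any(apply(Bb[i, , drop = FALSE], 2, stats::sd) == 0) ||
            any(apply(Zb[i, , drop = FALSE], 2, stats::sd) == 0)
        }, logical(1)))
        if (degenerate) { n_redrawn <- n_redrawn + 1L; next }
        M <- behavior_cross_block(Zb, blocks, Bb, check = FALSE)
      } else {
        M <- task_cross_block(Zb, blocks, result$centering)
      }
      break
    }
    sv <- svd(M)
    Q <- procrustes_rotation(sv$u, result$v)
    u_rot <- sv$v %*% Q              # unit axes, aligned to the original
    US_reps[, , b] <- sv$v %*% diag(sv$d, k) %*% Q
    scores_b <- Zb %*% u_rot
    contrast_reps[, , b] <- if (result$analysis == "task") {
      t(vapply(blocks, function(i)
        colMeans(scores_b[i, , drop = FALSE]), numeric(k)))
    } else {
      brain_score_behavior_cor(scores_b, blocks, Bb)
    }
  }
  se <- apply(US_reps, c(1, 2), stats::sd)
  result$bootstrap_ratio <- US_obs / se
  result$stable_mask <- abs(result$bootstrap_ratio) >= threshold
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  result$ci <- list(
    estimate = contrast_obs,
    lower = apply(contrast_reps, c(1, 2), stats::quantile, probs = probs[1]),
    upper = apply(contrast_reps, c(1, 2), stats::quantile, probs = probs[2]))
  dimnames(result$ci$lower) <- dimnames(contrast_obs)
  dimnames(result$ci$upper) <- dimnames(contrast_obs)
  result$n_boot <- n_boot
  result$threshold <- threshold
  result$ci_level <- ci_level
  result$n_redrawn <- n_redrawn
  result
}

#' Tabulate stable regions on a latent variable
#'
#' Lists the brain columns whose bootstrap ratio magnitude meets the
#' stability threshold on the chosen latent variable, organised by lobe as
#' in a stable-region table, with per-metric counts attached.
#'
#' @param result A `pls_result` with inference fields set and a column
#'   index (i.e. built from an [roi_matrix()]).
#' @param lv Latent variable number (default 1).
#' @return Data frame with columns `roi_name`, `hemisphere`, `lobe`,
#'   `metric`, `salience`, `ratio`, ordered by lobe then metric; the
#'   attribute `metric_counts` holds the CT/SA/T1 counts.
#' @export
summarize_stable_regions <- function(result, lv = 1) {
  stopifnot(inherits(result, "pls_result"))
  if (is.null(result$stable_mask)) stop("run pls_bootstrap() first")
  if (is.null(result$column_index)) stop("result has no ROI column index")
  ci <- result$column_index
  stable <- which(result$stable_mask[, lv])
  out <- data.frame(
    roi_name = ci$roi_name[stable],
    hemisphere = ci$hemisphere[stable],
    lobe = ci$lobe[stable],
    metric = ci$metric[stable],
    salience = result$u[stable, lv],
    ratio = result$bootstrap_ratio[stable, lv],
    stringsAsFactors = FALSE)
  lobe_order <- c("frontal", "parietal", "temporal", "occipital",
                  "insula_cingulate")
  out <- out[order(match(out$lobe, lobe_order), out$metric, out$roi_name), ]
  rownames(out) <- NULL
  counts <- vapply(ROI_METRICS, function(m) sum(out$metric == m), integer(1))
  attr(out, "metric_counts") <- counts
  out
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result: %s PLS> %d participants, %d brain columns\n",
              x$analysis, nrow(x$Z), nrow(x$u)))
  k_show <- min(length(x$s), 3L)
  for (j in seq_len(k_show)) {
    cat(sprintf("  LV%d: s = %.3f, %5.2f%% covariance%s\n", j, x$s[j],
                100 * x$cov_explained[j],
                if (!is.null(x$perm_p))
                  sprintf(", perm p = %.3f", x$perm_p[j]) else ""))
  }
  if (!is.null(x$stable_mask)) {
    cat(sprintf("  LV1 stable columns (|BSR| >= %g): %d\n", x$threshold,
                sum(x$stable_mask[, 1])))
  }
  invisible(x)
}
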