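#' Run the full multimodal analysis pipeline
#'
#' End-to-end orchestration: validates and matches the participant and ROI
#' tables, scores the EROS vector metrics if absent, builds the univariate
#' descriptive battery (age, GIDYQ-AA, attraction strength, phase), z-scores
#' the brain columns, and runs Task PLS (group contrast) and — when the
#' EROS scores are present — Behavior PLS on strength, phase and age, each
#' with permutation tests and stratified bootstrap stability. A
#' machine-readable manifest of every switch in force allows bit-identical
#' re-runs.
#'
#' @param participants Participant data frame or CSV path (see
#'   [read_participant_table()]).
#' @param roi An [roi_matrix()] or path to a wide ROI table.
#' @param dictionary ROI dictionary used when `roi` is a path.
#' @param n_perm,n_boot Permutation and bootstrap counts (defaults 1000).
#' @param bsr_threshold Bootstrap-ratio stability threshold (default 3).
#' @param ci_level Confidence level (default 0.95).
#' @param centering Task PLS mean-centering variant.
#' @param seed Integer seed; independent substreams are derived for each
#'   resampling stage.
#' @param out_dir Optional directory; when given, summary CSVs and a JSON
#'   manifest are written there.
#' @return List with `univariate` (per-variable [anova_report()]s and the
#'   psychosexual correlation table), `task` and `behavior` `pls_result`s
#'   (`behavior` is `NULL` when EROS scores are absent), `task_stable` and
#'   `behavior_stable` region tables, and `manifest`.
#' @export
run_full <- function(participants, roi, dictionary = roi_dictionary(),
                     n_perm = 1000, n_boot = 1000, bsr_threshold = 3,
                     ci_level = 0.95,
                     centering = c("unweighted", "weighted"),
                     seed = 1L, out_dir = NULL) {
  centering <- match.arg(centering)
  stopifnot(n_perm >= 1, n_boot >= 1, bsr_threshold > 0,
            ci_level > 0, ci_level < 1)
  if (is.character(participants)) {
    participants <- read_participant_table(participants)
  } else {
    participants <- validate_participants(participants)
  }
  if (is.character(roi)) roi <- read_roi_matrix(roi, dictionary)
  stopifnot(inherits(roi, "roi_matrix"))

  ids_p <- as.character(participants$participant_id)
  ids_r <- rownames(roi$values)
  if (!identical(sort(ids_p), sort(ids_r))) {
    offenders <- c(setdiff(ids_p, ids_r), setdiff(ids_r, ids_p))
    stop("participant ids do not match between tables: ",
         paste(offenders, collapse = ", "))
  }
  roi$values <- roi$values[ids_p, , drop = FALSE]  # align row order

  have_eros <- all(c("eros_androphilia", "eros_gynephilia") %in%
                     names(participants)) &&
    !anyNA(participants$eros_androphilia) &&
    !anyNA(participants$eros_gynephilia)
  if (have_eros) participants <- score_eros_vector(participants)

  group <- participants$group
  univariate <- list(age = anova_report(participants$age_months, group))
  if ("gidyq_mean" %in% names(participants) &&
      !anyNA(participants$gidyq_mean)) {
    univariate$gidyq <- anova_report(participants$gidyq_mean, group)
  }
  if (have_eros) {
    univariate$strength <- anova_report(participants$attraction_strength,
                                        group)
    univariate$phase <- anova_report(participants$attraction_phase_deg,
                                     group)
    univariate$correlations <- pearson_matrix(
      participants[, c("eros_androphilia", "eros_gynephilia",
                       "attraction_strength", "attraction_phase_deg",
                       "age_months")],
      group = group)
  }

  Z <- zscore_columns(roi)
  task <- task_pls(Z, group, centering = centering)
  task <- pls_permutation(task, n_perm = n_perm, seed = seed + 1L)
  task <- pls_bootstrap(task, n_boot = n_boot, threshold = bsr_threshold,
                        ci_level = ci_level, seed = seed + 2L)
  task_stable <- summarize_stable_regions(task, lv = 1)

  behavior <- behavior_stable <- NULL
  if (have_eros) {
    B <- cbind(strength = participants$attraction_strength,
               phase = participants$attraction_phase_deg,
               age = as.numeric(participants$age_months))
    behavior <- behavior_pls(Z, group, B)
    behavior <- pls_permutation(behavior, n_perm = n_perm,
                                seed = seed + 3L)
    behavior <- pls_bootstrap(behavior, n_boot = n_boot,
                              threshold = bsr_threshold,
                              ci_level = ci_level, seed = seed + 4L)
    behavior_stable <- summarize_stable_regions(behavior, lv = 1)
  }

  manifest <- list(
    package = "cortexpls",
    version = as.character(utils::packageVersion("cortexpls")),
    n_participants = nrow(participants),
    group_sizes = as.list(table(group)),
    n_columns = ncol(roi$values),
    n_perm = n_perm, n_boot = n_boot, bsr_threshold = bsr_threshold,
    ci_level = ci_level, centering = centering, seed = seed,
    behavior_pls_run = have_eros,
    behavior_variables = if (have_eros) c("strength", "phase", "age"))

  out <- list(participants = participants, univariate = univariate,
              task = task, task_stable = task_stable,
              behavior = behavior, behavior_stable = behavior_stable,
              manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir)
  out
}

pls_summary_frame <- function(res) {
  data.frame(lv = seq_along(res$s), s = res$s,
             cov_explained = res$cov_explained,
             perm_p = if (!is.null(res$perm_p)) res$perm_p else NA_real_)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(pls_summary_frame(bundle$task), "task_pls_summary.csv")
  wr(data.frame(column = colnames(bundle$task$Z),
                salience = bundle$task$u[, 1],
                bootstrap_ratio = bundle$task$bootstrap_ratio[, 1]),
     "task_pls_saliences_lv1.csv")
  wr(bundle$task_stable, "task_pls_stable_regions_lv1.csv")
  wr(data.frame(participant_id = bundle$participants$participant_id,
                group = bundle$participants$group,
                bundle$task$brain_scores), "task_pls_brain_scores.csv")
  if (!is.null(bundle$behavior)) {
    wr(pls_summary_frame(bundle$behavior), "behavior_pls_summary.csv")
    wr(bundle$behavior_stable, "behavior_pls_stable_regions_lv1.csv")
    ci <- bundle$behavior$ci
    wr(data.frame(design_row = rownames(ci$estimate),
                  correlation = ci$estimate[, 1],
                  ci_lower = ci$lower[, 1], ci_upper = ci$upper[, 1]),
       "behavior_pls_brainscore_correlations_lv1.csv")
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
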