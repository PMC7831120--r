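#' Scale mean with a minimum-response rule
#'
#' Questionnaire scale scores are item means, computed only for respondents
#' who answered at least a given fraction of the items (default 75%, so 6 of
#' 8 EROS subscale items is enough). Below the threshold the score is
#' missing.
#'
#' @param responses Numeric vector of item responses in `[1, 5]`; `NA`
#'   marks an unanswered item.
#' @param min_frac Minimum answered fraction required, in `(0, 1]`;
#'   inclusive ("at least").
#' @return The mean of the answered items, or `NA` if too few were answered.
#' @examples
#' scale_mean(c(4, 4, 4, 4, 4, 4, NA, NA))  # 6/8 answered: 4
#' scale_mean(c(4, 4, 4, 4, 4, NA, NA, NA)) # 5/8 answered: NA
#' @export
scale_mean <- function(responses, min_frac = 0.75) {
  stopifnot(min_frac > 0, min_frac <= 1)
  answered <- !is.na(responses)
  if (any(responses[answered] < 1 | responses[answered] > 5)) {
    stop("item responses must lie in [1, 5]")
  }
  if (mean(answered) >= min_frac) mean(responses[answered]) else NA_real_
}

#' Score long-format item responses into scale means
#'
#' Takes an item-level table (one row per participant, scale and item) and
#' applies [scale_mean()] with the minimum-response rule per participant
#' and scale.
#'
#' @param items Data frame with columns `participant_id`, `scale`,
#'   `item_index`, `response` (`NA` = unanswered); every participant-scale
#'   pair must carry the scale's full item count, answered or not.
#' @param min_frac Minimum answered fraction (default 0.75).
#' @return Wide data frame: `participant_id` plus one column per scale.
#' @export
score_items_long <- function(items, min_frac = 0.75) {
  stopifnot(all(c("participant_id", "scale", "item_index", "response")
                %in% names(items)))
  scales <- sort(unique(items$scale))
  ids <- unique(items$participant_id)
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (sc in scales) {
    sub <- items[items$scale == sc, ]
    out[[sc]] <- vapply(ids, function(id) {
      scale_mean(sub$response[sub$participant_id == id], min_frac)
    }, numeric(1))
  }
  out
}

#' Cronbach's alpha internal consistency
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' item variances and \eqn{s_T^2} the variance of the item sums.
#'
#' @param item_matrix Numeric matrix, participants in rows, items in
#'   columns; no missing values.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  if (k < 2L) stop("need at least 2 items")
  if (nrow(item_matrix) < 3L) stop("need at least 3 participants")
  if (anyNA(item_matrix)) stop("item matrix must be complete")
  item_var <- apply(item_matrix, 2, stats::var)
  if (any(item_var <= 0)) stop("every item must have positive variance")
  total_var <- stats::var(rowSums(item_matrix))
  if (total_var <= 0) stop("total score variance is zero")
  k / (k - 1) * (1 - sum(item_var) / total_var)
}

check_eros_scores <- function(androphilia, gynephilia) {
  if (any(androphilia < 1 | androphilia > 5, na.rm = TRUE) ||
      any(gynephilia < 1 | gynephilia > 5, na.rm = TRUE)) {
    stop("EROS scores must lie in [1, 5]")
  }
}

#' Strength of sexual attractions (EROS vector magnitude)
#'
#' The androphilia and gynephilia subscale scores are treated as the x and y
#' components of an attraction vector; strength is its Euclidean length
#' \eqn{\sqrt{a^2 + g^2}}, ranging from \eqn{\sqrt{2} \approx 1.41} (both
#' minimal) to \eqn{\sqrt{50} \approx 7.07} (both maximal).
#'
#' @param androphilia,gynephilia EROS subscale means in `[1, 5]`
#'   (vectorised; `NA` propagates).
#' @return Attraction strength (vector length).
#' @examples
#' attraction_strength(3, 4)  # 5
#' @export
attraction_strength <- function(androphilia, gynephilia) {
  check_eros_scores(androphilia, gynephilia)
  sqrt(androphilia^2 + gynephilia^2)
}

#' Degree of androphilia-gynephilia (EROS vector phase)
#'
#' The angle of the attraction vector from the androphilia axis,
#' \eqn{\theta = \arccos(a / \sqrt{a^2+g^2}) \cdot 180/\pi} degrees.
#' Exclusive androphilia (5, 1) gives 11.31 degrees, exclusive gynephilia
#' (1, 5) gives 78.69 degrees, and equal scores give exactly 45 degrees;
#' larger angles mean more gynephilic. Values are returned at full
#' precision; round only for display.
#'
#' @inheritParams attraction_strength
#' @return Phase in degrees, in `[11.31, 78.69]` for valid scores.
#' @examples
#' round(attraction_phase(5, 1))  # 11
#' round(attraction_phase(1, 5))  # 79
#' attraction_phase(2, 2)         # 45
#' @export
attraction_phase <- function(androphilia, gynephilia) {
  check_eros_scores(androphilia, gynephilia)
  acos(androphilia / sqrt(androphilia^2 + gynephilia^2)) * 180 / pi
}

#' Gender dysphoria caseness flag
#'
#' A mean GIDYQ-AA score at or below 3.00 marks the threshold for a
#' potential gender dysphoria diagnosis (lower scores indicate stronger
#' dysphoria).
#'
#' @param gidyq_mean Mean GIDYQ-AA score in `[1, 5]` (vectorised).
#' @return Logical flag (`NA` when the score is missing).
#' @export
gidyq_caseness <- function(gidyq_mean) {
  if (any(gidyq_mean < 1 | gidyq_mean > 5, na.rm = TRUE)) {
    stop("gidyq_mean must lie in [1, 5]")
  }
  gidyq_mean <= 3.00
}

#' Append derived EROS vector metrics to a participant table
#'
#' Computes `attraction_strength` and `attraction_phase_deg` from the raw
#' EROS subscale scores; rows with either score missing get missing derived
#' fields.
#'
#' @param df Participant data frame with `eros_androphilia` and
#'   `eros_gynephilia` columns.
#' @return The data frame with the two derived columns filled in.
#' @export
score_eros_vector <- function(df) {
  ok <- !is.na(df$eros_androphilia) & !is.na(df$eros_gynephilia)
  df$attraction_strength <- NA_real_
  df$attraction_phase_deg <- NA_real_
  df$attraction_strength[ok] <-
    attraction_strength(df$eros_androphilia[ok], df$eros_gynephilia[ok])
  df$attraction_phase_deg[ok] <-
    attraction_phase(df$eros_androphilia[ok], df$eros_gynephilia[ok])
  df
}
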