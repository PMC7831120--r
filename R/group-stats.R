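split_groups <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 values")
  if (anyNA(values)) stop("values must be complete")
  split(values, group)
}

#' Classical one-way ANOVA
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation.
#' @return List with `f`, `df` (between, within) and `p` (two-tailed).
#' @export
one_way_anova <- function(values, group) {
  g <- split_groups(values, group)
  if (all(vapply(g, stats::var, numeric(1)) == 0)) {
    stop("all groups constant: F undefined")
  }
  fit <- stats::oneway.test(values ~ factor(group), var.equal = TRUE)
  list(f = unname(fit$statistic),
       df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Levene's test for homogeneity of variance
#'
#' ANOVA on the absolute deviations of each observation from its group
#' mean (mean-centered variant).
#'
#' @inheritParams one_way_anova
#' @return List with `stat` (the F statistic), `df`, `p`.
#' @export
levene_test <- function(values, group) {
  g <- split_groups(values, group)
  group <- droplevels(as.factor(group))
  dev <- abs(values - stats::ave(values, group))
  if (stats::var(dev) == 0) {
    return(list(stat = 0, df = c(nlevels(group) - 1,
                                 length(values) - nlevels(group)), p = 1))
  }
  fit <- stats::oneway.test(dev ~ group, var.equal = TRUE)
  list(stat = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' @inheritParams one_way_anova
#' @return List with `f`, `df1`, `df2` (Satterthwaite), `p`.
#' @export
welch_anova <- function(values, group) {
  split_groups(values, group)
  fit <- stats::oneway.test(values ~ factor(group), var.equal = FALSE)
  list(f = unname(fit$statistic),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       p = unname(fit$p.value))
}

#' Brown-Forsythe robust one-way ANOVA
#'
#' The robust test of equality of means
#' \deqn{F^* = \sum_j n_j(\bar x_j - \bar x)^2 \Big/ \sum_j (1 - n_j/N)s_j^2,}
#' with denominator degrees of freedom by the Satterthwaite approximation.
#'
#' @inheritParams one_way_anova
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
brown_forsythe_anova <- function(values, group) {
  g <- split_groups(values, group)
  n <- lengths(g)
  N <- sum(n)
  k <- length(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  if (all(v == 0)) stop("zero within-group variance in all groups")
  grand <- mean(values)
  num <- sum(n * (m - grand)^2)
  w <- (1 - n / N) * v
  f <- num / sum(w)
  c_j <- w / sum(w)
  df2 <- 1 / sum(c_j^2 / (n - 1))
  list(f = f, df1 = k - 1, df2 = df2,
       p = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

#' Least significant difference pairwise comparisons
#'
#' Pairwise t tests using the pooled ANOVA mean square error with N - k
#' degrees of freedom; no multiplicity adjustment (Fisher's protected LSD:
#' run after a significant omnibus test).
#'
#' @inheritParams one_way_anova
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `mean_difference`, `se`, `df`, `p`, `method`.
#' @export
lsd_posthoc <- function(values, group) {
  g <- split_groups(values, group)
  n <- lengths(g)
  k <- length(g)
  N <- sum(n)
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1))) /
    (N - k)
  m <- vapply(g, mean, numeric(1))
  pairs <- utils::combn(names(g), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(mse * (1 / n[[i]] + 1 / n[[j]]))
    md <- m[[i]] - m[[j]]
    data.frame(group1 = i, group2 = j, mean_difference = md, se = se,
               df = N - k,
               p = 2 * stats::pt(abs(md / se), N - k, lower.tail = FALSE),
               method = "LSD", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Games-Howell pairwise comparisons
#'
#' Robust to heterogeneity of variance: each pair uses its own variance
#' estimate \eqn{s_i^2/n_i + s_j^2/n_j}, Welch-Satterthwaite degrees of
#' freedom, and p-values from the studentized range distribution with k
#' means.
#'
#' @inheritParams one_way_anova
#' @return Data frame as in [lsd_posthoc()] with `method = "GamesHowell"`.
#' @export
games_howell_posthoc <- function(values, group) {
  g <- split_groups(values, group)
  n <- lengths(g)
  k <- length(g)
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  pairs <- utils::combn(names(g), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    if (v[[i]] == 0 && v[[j]] == 0) {
      stop("both variances zero for pair ", i, "-", j)
    }
    vi <- v[[i]] / n[[i]]; vj <- v[[j]] / n[[j]]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (n[[i]] - 1) + vj^2 / (n[[j]] - 1))
    md <- m[[i]] - m[[j]]
    q <- abs(md) / sqrt((vi + vj) / 2)
    data.frame(group1 = i, group2 = j, mean_difference = md, se = se,
               df = df,
               p = stats::ptukey(q, nmeans = k, df = df,
                                 lower.tail = FALSE),
               method = "GamesHowell", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full one-way report for a variable
#'
#' Combines the descriptives, classical ANOVA, Levene's test, and — when
#' Levene is significant at `levene_alpha` — the Welch and Brown-Forsythe
#' robust tests, plus post hoc comparisons chosen by the same rule (LSD by
#' default, Games-Howell under variance heterogeneity).
#'
#' @inheritParams one_way_anova
#' @param levene_alpha Significance level for the heterogeneity switch
#'   (default 0.05).
#' @return List with `descriptives` (per-group n/mean/sd/min/max), `anova`,
#'   `levene`, `welch`, `brown_forsythe` (the latter two `NULL` unless
#'   Levene fires), and `posthoc`.
#' @export
anova_report <- function(values, group, levene_alpha = 0.05) {
  g <- split_groups(values, group)
  desc <- data.frame(
    group = names(g), n = lengths(g),
    mean = vapply(g, mean, numeric(1)),
    sd = vapply(g, stats::sd, numeric(1)),
    min = vapply(g, min, numeric(1)),
    max = vapply(g, max, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  lev <- levene_test(values, group)
  heterosc <- lev$p < levene_alpha
  list(descriptives = desc,
       anova = one_way_anova(values, group),
       levene = lev,
       welch = if (heterosc) welch_anova(values, group),
       brown_forsythe = if (heterosc) brown_forsythe_anova(values, group),
       posthoc = if (heterosc) games_howell_posthoc(values, group)
                 else lsd_posthoc(values, group))
}

#' Pearson correlations with two-tailed p-values
#'
#' Every pair of variables, overall and (optionally) within each group.
#'
#' @param table Data frame or matrix of numeric variables (participants x
#'   variables).
#' @param group Optional group labels; adds within-group rows.
#' @return Long data frame: `var1`, `var2`, `scope` (`all` or a group
#'   level), `n`, `r`, `p`. Constant variables yield `NA` with a reason.
#' @export
pearson_matrix <- function(table, group = NULL) {
  X <- as.data.frame(table)
  vars <- names(X)
  scopes <- list(all = seq_len(nrow(X)))
  if (!is.null(group)) {
    scopes <- c(scopes, split(seq_len(nrow(X)), as.factor(group)))
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  rows <- list()
  for (sc in names(scopes)) {
    idx <- scopes[[sc]]
    for (pr in pairs) {
      x <- X[[pr[1]]][idx]; y <- X[[pr[2]]][idx]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          var1 = pr[1], var2 = pr[2], scope = sc, n = sum(ok),
          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        var1 = pr[1], var2 = pr[2], scope = sc, n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}
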