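test_that("one-way ANOVA matches the textbook decomposition", {
  # groups with identical means and variances: F = 0, p = 1
  g <- rep(c(1, 2, 3, 4), 3)
  grp <- rep(1:3, each = 4)
  res <- one_way_anova(g, grp)
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, c(2, 9))

  # moment-matched three-group construction vs the formula oracle
  mm <- moment_matched_groups(c(184.93, 193.38, 191.71),
                              c(25.61, 14.20, 19.00), c(14, 16, 17))
  res <- one_way_anova(mm$values, mm$group)
  expect_equal(res$f, anova_f_oracle(mm$values, mm$group),
               tolerance = 1e-10)
  expect_equal(res$df, c(2, 44))

  # two groups: F equals the squared pooled t
  set.seed(1)
  x <- rnorm(12); y <- rnorm(15, 1)
  tt <- t.test(x, y, var.equal = TRUE)
  res <- one_way_anova(c(x, y), rep(1:2, c(12, 15)))
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  expect_error(one_way_anova(rep(5, 9), rep(1:3, 3)), "constant")
})

test_that("Levene's test responds to variance heterogeneity", {
  # two identical groups: statistic exactly 0
  expect_equal(levene_test(rep(c(1, 2, 5), 2), rep(1:2, each = 3))$stat, 0)

  # equal variances, large n: p typically large
  set.seed(2)
  x <- rnorm(900)
  expect_gt(levene_test(x, rep(1:3, each = 300))$p, 0.05)

  # one group with 10x the spread at n = 15/group: detected
  set.seed(3)
  y <- c(rnorm(15, sd = 1), rnorm(15, sd = 10), rnorm(15, sd = 1))
  expect_lt(levene_test(y, rep(1:3, each = 15))$p, 0.01)
})

test_that("Welch and Brown-Forsythe reproduce the reported robust tests", {
  # moment-matched GIDYQ-AA construction from the printed group moments
  mm <- moment_matched_groups(c(4.91, 2.21, 4.90), c(0.12, 0.35, 0.15),
                              c(14, 16, 17))
  w <- welch_anova(mm$values, mm$group)
  bf <- brown_forsythe_anova(mm$values, mm$group)
  # the printed group SDs are rounded to 2 decimals, which propagates a
  # ~2% wobble into variance-weighted statistics
  expect_equal(w$f, 422.50, tolerance = 0.025)
  expect_equal(w$df2, 27.46, tolerance = 0.025)
  expect_equal(bf$f, 713.80, tolerance = 0.025)
  expect_equal(bf$df2, 24.31, tolerance = 0.025)
  # exact check against an independently coded Brown-Forsythe oracle
  g <- split(mm$values, mm$group)
  n <- lengths(g); N <- sum(n)
  v <- sapply(g, var); m <- sapply(g, mean)
  f_star <- sum(n * (m - mean(mm$values))^2) / sum((1 - n / N) * v)
  expect_equal(bf$f, f_star, tolerance = 1e-12)

  # two groups: Welch F equals the squared Welch t
  set.seed(4)
  x <- rnorm(10); y <- rnorm(20, 1, 3)
  tt <- t.test(x, y)
  w2 <- welch_anova(c(x, y), rep(1:2, c(10, 20)))
  expect_equal(w2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w2$df2, unname(tt$parameter), tolerance = 1e-10)

  # homoscedastic balanced data: Welch tracks the classical F on average
  set.seed(5)
  ratios <- replicate(100, {
    z <- rnorm(120, rep(c(0, 0.3, 0.6), each = 40))
    grp <- rep(1:3, each = 40)
    welch_anova(z, grp)$f / one_way_anova(z, grp)$f
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("LSD equals the pooled t and Games-Howell matches its oracle", {
  # three identical groups: all pairwise p = 1
  g <- rep(c(1, 2, 3, 4), 3)
  grp <- rep(1:3, each = 4)
  expect_true(all(lsd_posthoc(g, grp)$p == 1))

  # LSD pair p equals pooled-t p with N - k degrees of freedom
  mm <- moment_matched_groups(c(64.60, 46.38, 30.94),
                              c(9.29, 15.23, 13.18), c(14, 16, 17))
  lsd <- lsd_posthoc(mm$values, mm$group)
  pair <- lsd[lsd$group1 == "1" & lsd$group2 == "2", ]
  g1 <- mm$values[mm$group == 1]; g2 <- mm$values[mm$group == 2]
  mse <- sum(tapply(mm$values, mm$group,
                    function(x) sum((x - mean(x))^2))) / 44
  se <- sqrt(mse * (1 / 14 + 1 / 16))
  expect_equal(pair$mean_difference, mean(g1) - mean(g2), tolerance = 1e-10)
  expect_equal(pair$se, se, tolerance = 1e-10)
  expect_equal(pair$p,
               2 * pt(abs((mean(g1) - mean(g2)) / se), 44, lower.tail = FALSE),
               tolerance = 1e-12)
  # reported pairwise values for the phase contrast (printed as MD/SE)
  expect_equal(round(pair$mean_difference, 2), 18.21, tolerance = 0.01)
  expect_equal(round(pair$se, 2), 4.74, tolerance = 0.01)

  # Games-Howell against an independently coded formula oracle
  gh_oracle <- function(values, group) {
    g <- split(values, group)
    n <- lengths(g); m <- sapply(g, mean); v <- sapply(g, var)
    k <- length(g)
    do.call(rbind, utils::combn(names(g), 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      vi <- v[[i]] / n[[i]]; vj <- v[[j]] / n[[j]]
      df <- (vi + vj)^2 / (vi^2 / (n[[i]] - 1) + vj^2 / (n[[j]] - 1))
      q <- abs(m[[i]] - m[[j]]) / sqrt((vi + vj) / 2)
      data.frame(p = ptukey(q, k, df, lower.tail = FALSE))
    }, simplify = FALSE))
  }
  set.seed(6)
  for (rep in 1:20) {
    vals <- rnorm(36, rep(rnorm(3, sd = 0.5), each = 12),
                  rep(runif(3, 0.5, 3), each = 12))
    grp2 <- rep(1:3, each = 12)
    expect_equal(games_howell_posthoc(vals, grp2)$p,
                 gh_oracle(vals, grp2)$p, tolerance = 1e-12)
  }

  # Games-Howell SE for the printed GIDYQ GD-vs-CG contrast
  mm2 <- moment_matched_groups(c(4.91, 2.21, 4.90), c(0.12, 0.35, 0.15),
                               c(14, 16, 17))
  gh <- games_howell_posthoc(mm2$values, mm2$group)
  gd_cg <- gh[gh$group1 == "2" & gh$group2 == "3", ]
  expect_equal(gd_cg$se, sqrt(0.35^2 / 16 + 0.15^2 / 17),
               tolerance = 1e-10)
  expect_equal(gd_cg$se, 0.10, tolerance = 0.06)  # printed-SD rounding
  expect_equal(round(gd_cg$mean_difference, 2), -2.69)
})

test_that("Pearson matrix reports r and two-tailed p, by scope", {
  df <- data.frame(x = 1:10, y = (1:10) * 2, z = rnorm(10))
  pm <- pearson_matrix(df)
  xy <- pm[pm$var1 == "x" & pm$var2 == "y" & pm$scope == "all", ]
  expect_equal(xy$r, 1)
  ct <- cor.test(df$x, df$z)
  xz <- pm[pm$var1 == "x" & pm$var2 == "z" & pm$scope == "all", ]
  expect_equal(xz$r, unname(ct$estimate))
  expect_equal(xz$p, ct$p.value)

  # constant variable: missing, not an error
  df$c <- 1
  pm2 <- pearson_matrix(df)
  expect_true(all(is.na(pm2$r[pm2$var2 == "c"])))

  # grouped scopes appear
  pm3 <- pearson_matrix(df[, c("x", "z")], group = rep(c("a", "b"), 5))
  expect_setequal(unique(pm3$scope), c("all", "a", "b"))
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(7)
  for (rep in 1:10) {
    p <- runif(25)^2
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("null rejection rates sit in the binomial band", {
  set.seed(8)
  n_rep <- 500
  rej <- matrix(FALSE, n_rep, 3)
  grp <- rep(1:3, each = 50)
  for (r in seq_len(n_rep)) {
    x <- rnorm(150)
    rej[r, 1] <- one_way_anova(x, grp)$p < 0.05
    rej[r, 2] <- levene_test(x, grp)$p < 0.05
    rej[r, 3] <- welch_anova(x, grp)$p < 0.05
  }
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_rep)
  rates <- colMeans(rej)
  expect_true(all(rates > band[1] & rates < band[2]))
})

test_that("anova_report switches post hocs on Levene heterogeneity", {
  mm_hom <- moment_matched_groups(c(64.60, 46.38, 30.94),
                                  c(13, 13, 13), c(14, 16, 17))
  rep_hom <- anova_report(mm_hom$values, mm_hom$group)
  expect_equal(unique(rep_hom$posthoc$method), "LSD")
  expect_null(rep_hom$welch)

  mm_het <- moment_matched_groups(c(4.91, 2.21, 4.90), c(0.12, 0.35, 0.15),
                                  c(14, 16, 17))
  rep_het <- anova_report(mm_het$values, mm_het$group)
  expect_lt(rep_het$levene$p, 0.05)
  expect_equal(unique(rep_het$posthoc$method), "GamesHowell")
  expect_false(is.null(rep_het$welch))
  expect_false(is.null(rep_het$brown_forsythe))
})
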