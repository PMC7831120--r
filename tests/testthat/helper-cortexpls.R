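# Shared fixture builders; everything is generated in code at test time.

# Tiny valid participant table (no brain data attached).
make_participants <- function(n_per_group = c(CB = 3L, GD = 3L, CG = 3L)) {
  n <- sum(n_per_group)
  df <- data.frame(
    participant_id = sprintf("S%02d", seq_len(n)),
    group = rep(names(n_per_group), n_per_group),
    age_months = seq(150L, by = 6L, length.out = n),
    gidyq_mean = c(rep(4.8, n_per_group[1]), rep(2.2, n_per_group[2]),
                   rep(4.9, n_per_group[3])),
    eros_androphilia = seq(1.2, 4.8, length.out = n),
    eros_gynephilia = seq(4.8, 1.2, length.out = n),
    stringsAsFactors = FALSE)
  score_eros_vector(df)
}

# Rescale a vector to exact sample mean m and sd s.
moment_match <- function(x, m, s) {
  (x - mean(x)) / stats::sd(x) * s + m
}

# Groups constructed to have exactly the given means/sds/sizes.
moment_matched_groups <- function(means, sds, ns) {
  set.seed(42)
  values <- unlist(mapply(function(m, s, n) {
    moment_match(stats::rnorm(n), m, s)
  }, means, sds, ns, SIMPLIFY = FALSE))
  list(values = values,
       group = rep(seq_along(ns), ns))
}

# Textbook one-way ANOVA F from raw data (independent oracle).
anova_f_oracle <- function(values, group) {
  g <- split(values, group)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  k <- length(g); N <- length(values)
  (ssb / (k - 1)) / (ssw / (N - k))
}
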