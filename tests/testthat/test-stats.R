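test_that("ANOVA matches hand-computed sums of squares", {
  df <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  res <- anova_oneway(df, y, g)
  # SSB = 13.5 on 1 df, SSW = 4 on 4 df -> F = 13.5 / 1
  expect_equal(res$f, 13.5, tolerance = 1e-12)
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(c(res$df_between, res$df_within), c(1, 4))
})

test_that("identical groups give F = 0, p = 1 and no stars", {
  df <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  res <- anova_oneway(df, y, g)
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  pw <- pairwise_bonferroni(df, y, g)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$bonferroni_p == 1))
  expect_true(all(pw$stars == ""))
})

test_that("F is invariant to a constant shift", {
  set.seed(41)
  df <- data.frame(y = rnorm(30), g = rep(letters[1:3], each = 10))
  f1 <- anova_oneway(df, y, g)$f
  df$y <- df$y + 17.3
  expect_equal(anova_oneway(df, y, g)$f, f1, tolerance = 1e-9)
})

test_that("undersized groups are refused by name", {
  df <- data.frame(y = c(1, 2, 3, NA), g = c("a", "a", "b", "b"))
  expect_error(anova_oneway(df, y, g), "'b'")
  expect_error(compare_features(data.frame(amplitude = 1:3, g = "a"), g),
               "2 groups")
})

test_that("pooled pairwise t matches the reference implementation", {
  set.seed(43)
  df <- data.frame(y = rnorm(24, rep(c(0, 0.5, 1), each = 8)),
                   g = rep(c("a", "b", "c"), each = 8))
  pw <- pairwise_bonferroni(df, y, g)
  ref <- stats::pairwise.t.test(df$y, df$g, p.adjust.method = "bonferroni",
                                pool.sd = TRUE)$p.value
  expect_equal(pw$bonferroni_p[pw$group_a == "a" & pw$group_b == "b"],
               ref["b", "a"], tolerance = 1e-12)
  expect_equal(pw$bonferroni_p[pw$group_a == "a" & pw$group_b == "c"],
               ref["c", "a"], tolerance = 1e-12)
  expect_equal(pw$bonferroni_p[pw$group_a == "b" & pw$group_b == "c"],
               ref["c", "b"], tolerance = 1e-12)
  expect_true(all(pw$bonferroni_p >= pw$raw_p))
})

test_that("parametric pairwise p agrees with a permutation oracle at n = 6", {
  set.seed(9)
  df <- data.frame(y = c(rnorm(6), rnorm(6, 0.8), rnorm(6, 0.4)),
                   g = rep(c("a", "b", "c"), each = 6))
  pw <- pairwise_bonferroni(df, y, g)
  perm_pair_p <- function(df, a, b, nperm = 10000) {
    pair_t <- function(yy, gg) {
      cg <- split(yy, gg)
      ns <- lengths(cg); k <- length(cg)
      msw <- sum((ns - 1) * vapply(cg, stats::var, 1.0)) / (sum(ns) - k)
      (mean(cg[[a]]) - mean(cg[[b]])) / sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
    }
    obs <- abs(pair_t(df$y, df$g))
    hits <- vapply(seq_len(nperm), function(i) {
      abs(pair_t(df$y, sample(df$g))) >= obs
    }, TRUE)
    mean(hits)
  }
  set.seed(77)
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    p_perm <- perm_pair_p(df, pr[1], pr[2])
    p_param <- pw$raw_p[pw$group_a == pr[1] & pw$group_b == pr[2]]
    expect_lt(abs(p_perm - p_param), 0.05)
  }
})

test_that("null simulations stay within the familywise error budget", {
  set.seed(5)
  starred <- vapply(1:200, function(i) {
    df <- data.frame(y = rnorm(24), g = rep(c("a", "b", "c"), each = 8))
    any(pairwise_bonferroni(df, y, g)$stars != "")
  }, TRUE)
  expect_lte(mean(starred), 0.08)
})

test_that("star thresholds follow the conventional cut points", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
               c("***", "**", "*", "", NA))
})

test_that("group power: a decay-tau difference is starred, equal amplitudes differ little", {
  gen <- function(tau, seed) {
    s <- simulate_traces(n_cells = 30, rate_hz = 0.5, decay_tau_s = tau,
                         noise_sigma = 2, cell_cv = 0.1, seed = seed)
    analyze_traces(normalize_to_background(s$table))$cells
  }
  cells <- dplyr::bind_rows(
    dplyr::mutate(gen(0.3, 101), line = "short_tau"),
    dplyr::mutate(gen(0.6, 202), line = "long_tau")
  )
  cmp <- compare_features(cells, line,
                          features = c("decay_tau_s", "amplitude"))
  td <- tidy(cmp)
  tau_row <- td[td$feature == "decay_tau_s", ]
  expect_equal(tau_row$stars, "***")
  expect_lt(tau_row$bonferroni_p, 0.001)
  expect_lt(abs(abs(tau_row$mean_difference) - 0.3), 0.06)
  # equal amplitude parameters: group means agree within the sampled-peak
  # discretization bias (a few percent), whatever their significance
  expect_lt(abs(td$mean_difference[td$feature == "amplitude"]), 0.1)
})

test_that("comparison results are tidy, glanceable and plottable", {
  set.seed(47)
  cells <- data.frame(
    line = rep(c("ctrl", "dcm1", "dcm2"), each = 6),
    amplitude = rnorm(18, rep(c(1, 0.6, 0.7), each = 6), 0.1),
    decay_tau_s = rnorm(18, 0.4, 0.05)
  )
  cmp <- compare_features(cells, line,
                          features = c("amplitude", "decay_tau_s"))
  expect_equal(nrow(glance(cmp)), 2)
  expect_equal(nrow(tidy(cmp)), 6) # 2 features x 3 pairs
  expect_true(all(c("anova_f", "anova_p", "stars") %in% names(tidy(cmp))))
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
  gs <- cmp$group_stats
  expect_equal(unname(gs$n), rep(6L, 6))
})

test_that("all eleven features produce one comparison record each", {
  gen <- function(seed) {
    s <- simulate_traces(n_cells = 6, rate_hz = 0.5, noise_sigma = 2,
                         cell_cv = 0.1, seed = seed)
    analyze_traces(normalize_to_background(s$table))$cells
  }
  cells <- dplyr::bind_rows(
    dplyr::mutate(gen(1), line = "a"),
    dplyr::mutate(gen(2), line = "b")
  )
  cmp <- compare_features(cells, line)
  expect_equal(nrow(glance(cmp)), 11)
  expect_setequal(glance(cmp)$feature, ca_feature_names())
})
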