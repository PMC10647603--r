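#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise. Applied to Bonferroni-adjusted p-values in group
#' comparisons.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

check_groups <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2L) abort("Need at least 2 groups to compare.")
  ns <- table(groups)
  small <- names(ns)[ns < 2L]
  if (length(small)) {
    abort(sprintf("Group '%s' has fewer than 2 non-missing values.", small[1]))
  }
  list(values = values, groups = groups)
}

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA F test with (k - 1, N - k) degrees of freedom
#' across k groups, after dropping missing values.
#'
#' @param data Data frame with one row per cell.
#' @param value Column of per-cell feature values (bare name).
#' @param group Column identifying the group / cell line (bare name).
#' @return One-row tibble: `f`, `p`, `df_between`, `df_within`, `n`.
#' @export
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 4, 5, 6),
#'                  g = rep(c("a", "b"), each = 3))
#' anova_oneway(df, y, g)
anova_oneway <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  cg <- check_groups(v, g)
  ft <- stats::oneway.test(cg$values ~ cg$groups, var.equal = TRUE)
  tibble(
    f = unname(ft$statistic),
    p = unname(ft$p.value),
    df_between = unname(ft$parameter[1]),
    df_within = unname(ft$parameter[2]),
    n = length(cg$values)
  )
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All k(k-1)/2 two-sample t tests using the pooled within-group variance
#' (the ANOVA mean square within, on N - k degrees of freedom — the
#' classical Bonferroni post-hoc). Each raw p-value is multiplied by the
#' number of comparisons and capped at 1; stars come from the adjusted
#' p-values. Welch tests (per-pair variances) are available behind
#' `pool_sd = FALSE` for heteroscedastic data.
#'
#' @inheritParams anova_oneway
#' @param pool_sd Use the pooled ANOVA within-group variance (default
#'   `TRUE`); otherwise Welch per-pair t tests.
#' @return Tibble with one row per pair: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `mean_difference` (a minus b), `raw_p`, `bonferroni_p`,
#'   `stars`.
#' @export
pairwise_bonferroni <- function(data, value, group, pool_sd = TRUE) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  cg <- check_groups(v, g)
  lev <- levels(cg$groups)
  k <- length(lev)
  ns <- tapply(cg$values, cg$groups, length)
  means <- tapply(cg$values, cg$groups, mean)
  vars <- tapply(cg$values, cg$groups, stats::var)
  n_tot <- sum(ns)
  msw <- sum((ns - 1) * vars) / (n_tot - k)
  m <- k * (k - 1) / 2
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff_ab <- means[[a]] - means[[b]]
    if (pool_sd) {
      se <- sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
      df <- n_tot - k
    } else {
      se <- sqrt(vars[[a]] / ns[[a]] + vars[[b]] / ns[[b]])
      df <- se^4 / ((vars[[a]] / ns[[a]])^2 / (ns[[a]] - 1) +
                      (vars[[b]] / ns[[b]])^2 / (ns[[b]] - 1))
    }
    tstat <- diff_ab / se
    raw_p <- if (se == 0) as.numeric(diff_ab != 0) * 0 + (diff_ab == 0) else
      2 * pt(-abs(tstat), df)
    tibble(group_a = a, group_b = b, n_a = ns[[a]], n_b = ns[[b]],
           mean_difference = diff_ab, raw_p = raw_p)
  })
  res$bonferroni_p <- pmin(1, res$raw_p * m)
  res$stars <- p_stars(res$bonferroni_p)
  res
}

#' Compare per-cell features across groups
#'
#' Runs, independently for each of the eleven features, a one-way ANOVA
#' and Bonferroni-corrected pairwise comparisons across groups of cells
#' (cell lines or treatments). The cell — not the transient — is the unit
#' of analysis; missing per-cell values are dropped feature by feature.
#'
#' @param cells Per-cell summaries from [summarize_cells()] for all
#'   groups combined, with a grouping column.
#' @param group Bare name of the grouping column.
#' @param features Character vector of feature columns to compare
#'   (default [ca_feature_names()]).
#' @param pool_sd Passed to [pairwise_bonferroni()].
#' @return Object of class `ca_comparison`: a list with tibbles `anova`
#'   (one row per feature), `pairwise` (one row per feature per pair),
#'   `group_stats` (per feature per group: n, mean, sem), and the input
#'   data. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' cells <- data.frame(
#'   line = rep(c("ctrl", "dcm"), each = 4),
#'   amplitude = c(1.0, 1.1, 0.9, 1.2, 0.5, 0.6, 0.4, 0.7)
#' )
#' cmp <- compare_features(cells, line, features = "amplitude")
#' tidy(cmp)
compare_features <- function(cells, group, features = ca_feature_names(),
                             pool_sd = TRUE) {
  gname <- as_name(enquo(group))
  if (!gname %in% names(cells)) {
    abort(sprintf("Grouping column '%s' not found.", gname))
  }
  present <- intersect(features, names(cells))
  if (!length(present)) abort("None of the requested feature columns are present.")
  g_all <- factor(cells[[gname]])
  if (nlevels(g_all) < 2L) abort("Need at least 2 groups to compare.")
  res <- purrr::map(present, function(feat) {
    df <- tibble(value = cells[[feat]], group = g_all)
    out <- tryCatch(
      list(
        anova = anova_oneway(df, value, group),
        pairwise = pairwise_bonferroni(df, value, group, pool_sd = pool_sd)
      ),
      error = function(e) {
        abort(sprintf("Feature '%s': %s", feat, conditionMessage(e)))
      }
    )
    out$anova$feature <- feat
    out$pairwise$feature <- feat
    out
  })
  gs <- purrr::map_dfr(present, function(feat) {
    tibble(value = cells[[feat]], group = g_all) %>%
      dplyr::filter(!is.na(.data$value)) %>%
      dplyr::group_by(.data$group) %>%
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$value),
        sem = stats::sd(.data$value) / sqrt(dplyr::n()),
        .groups = "drop"
      ) %>%
      dplyr::mutate(feature = feat, .before = 1)
  })
  structure(
    list(
      anova = dplyr::relocate(purrr::map_dfr(res, "anova"), "feature"),
      pairwise = dplyr::relocate(purrr::map_dfr(res, "pairwise"), "feature"),
      group_stats = gs,
      data = as_tibble(cells),
      group_var = gname,
      features = present
    ),
    class = "ca_comparison"
  )
}

#' @export
print.ca_comparison <- function(x, ...) {
  cat(sprintf("<ca_comparison> %d feature(s) across %d groups\n",
              length(x$features), dplyr::n_distinct(x$group_stats$group)))
  print(x$anova)
  starred <- x$pairwise[x$pairwise$stars != "", ]
  if (nrow(starred)) {
    cat("Starred pairwise comparisons (Bonferroni):\n")
    print(starred[, c("feature", "group_a", "group_b", "mean_difference",
                      "bonferroni_p", "stars")])
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `ca_comparison` from [compare_features()].
#' @param ... Unused.
#' @return `tidy()`: the pairwise table (one row per feature per pair,
#'   with ANOVA p attached); `glance()`: the per-feature ANOVA table.
#' @method tidy ca_comparison
#' @export
tidy.ca_comparison <- function(x, ...) {
  dplyr::left_join(x$pairwise, x$anova[, c("feature", "f", "p")],
                   by = "feature", suffix = c("", "_anova")) %>%
    dplyr::rename(anova_f = "f", anova_p = "p")
}

#' @rdname tidy.ca_comparison
#' @method glance ca_comparison
#' @export
glance.ca_comparison <- function(x, ...) {
  x$anova
}
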