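# Group-level statistics: mean +/- SEM summaries, one-way ANOVA with Tukey
# HSD, pairwise Welch t tests, two-sided F tests of variances, and fold
# changes. Beyond Tukey's adjustment no further multiple-testing correction
# is applied, and the pairwise Welch tests are reported unadjusted.

#' Group summaries (mean +/- SEM)
#'
#' @param estimates Tibble with one row per chip, containing a grouping
#'   column and a k_in column (e.g. the output of [fit_cohort()]).
#' @param value Column holding the per-chip estimates (default `k_in`).
#' @param group Grouping column (default `group`).
#' @return A tibble with columns `label`, `n`, `mean`, `sem` (`NA` and
#'   flagged when n = 1) and `pretty`, a display string on the conventional
#'   x 10^-3 scale, e.g. `"2.5 +/- 0.3 x 10^-3, n = 6"`.
#' @export
group_summary <- function(estimates, value = "k_in", group = "group") {
  stop_if(!is.data.frame(estimates) ||
            !all(c(value, group) %in% names(estimates)),
          sprintf("`estimates` must contain columns `%s` and `%s`",
                  value, group))
  stop_if(nrow(estimates) == 0, "`estimates` is empty")
  estimates |>
    dplyr::group_by(label = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() >= 2) sd(.data[[value]]) / sqrt(dplyr::n())
            else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(pretty = ifelse(
      is.na(.data$sem),
      sprintf("%.1f x 10^-3, n = %d (SEM undefined)", .data$mean * 1e3,
              .data$n),
      sprintf("%.1f +/- %.1f x 10^-3, n = %d", .data$mean * 1e3,
              .data$sem * 1e3, .data$n)))
}

#' Compare k_in across experimental groups
#'
#' Runs the full comparison battery: one-way ANOVA across all groups, Tukey
#' HSD on all pairs (studentized-range adjustment on the ANOVA residual
#' variance, Tukey-Kramer for unbalanced designs), an unpaired Welch t test
#' per pair, and a two-sided F test of variances per pair with the larger
#' sample variance in the numerator. Degenerate inputs (zero variance
#' everywhere) yield `NA` statistics flagged `indeterminate`, not errors.
#'
#' @param estimates Tibble with per-chip estimates; see [group_summary()].
#' @param value,group Column names, as in [group_summary()].
#' @param alpha Significance level (default 0.05).
#' @return An object of class `kin_comparison`: list with `summary`
#'   (group means +/- SEM), `anova` (F, df, p), `pairwise` (per pair:
#'   Tukey difference and adjusted p, Welch t/df/p, variance-ratio F/p,
#'   significance flags), `alpha` and `significant_pairs` (Tukey-adjusted
#'   p < alpha).
#' @examples
#' est <- tibble::tibble(group = rep(c("BBB", "BTB"), each = 4),
#'                       k_in = c(2.3, 2.6, 2.4, 2.7, 12, 14, 13, 13.5) / 1e3)
#' cmp <- compare_groups(est)
#' tidy(cmp)
#' @export
compare_groups <- function(estimates, value = "k_in", group = "group",
                           alpha = 0.05) {
  stop_if(!is.data.frame(estimates) ||
            !all(c(value, group) %in% names(estimates)),
          sprintf("`estimates` must contain columns `%s` and `%s`",
                  value, group))
  stop_if(!is.numeric(alpha) || alpha <= 0 || alpha >= 1,
          "`alpha` must be in (0, 1)")
  x <- estimates[[value]]
  g <- factor(estimates[[group]])
  stop_if(nlevels(g) < 2, "need at least 2 groups")
  counts <- table(g)
  stop_if(any(counts < 2), "every group needs n >= 2 for variance-based tests")

  fit <- aov(x ~ g)
  atab <- summary(fit)[[1]]
  anova_row <- tibble::tibble(
    f_statistic = atab[["F value"]][1], df_between = atab[["Df"]][1],
    df_within = atab[["Df"]][2], p_value = atab[["Pr(>F)"]][1])
  tk <- tryCatch(as.data.frame(TukeyHSD(fit)$g), error = function(e) NULL)

  pairs <- combn(levels(g), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x1 <- x[g == g1]; x2 <- x[g == g2]
    key <- paste(g2, g1, sep = "-")  # TukeyHSD labels level2-level1
    tukey_diff <- if (!is.null(tk) && key %in% rownames(tk))
      tk[key, "diff"] else NA_real_
    tukey_p <- if (!is.null(tk) && key %in% rownames(tk))
      tk[key, "p adj"] else NA_real_

    welch <- tryCatch(t.test(x1, x2), error = function(e) NULL)
    # two-sided variance-ratio F with the larger variance in the numerator
    if (var(x1) >= var(x2)) {hi <- x1; lo <- x2} else {hi <- x2; lo <- x1}
    vf <- tryCatch(var.test(hi, lo), error = function(e) NULL)

    tibble::tibble(
      group1 = g1, group2 = g2,
      mean_diff = mean(x1) - mean(x2),
      tukey_diff = tukey_diff, tukey_p = tukey_p,
      welch_t = if (is.null(welch)) NA_real_ else unname(welch$statistic),
      welch_df = if (is.null(welch)) NA_real_ else unname(welch$parameter),
      welch_p = if (is.null(welch)) NA_real_ else welch$p.value,
      var_f = if (is.null(vf)) NA_real_ else unname(vf$statistic),
      var_f_p = if (is.null(vf)) NA_real_ else vf$p.value,
      indeterminate = is.null(welch) || is.na(tukey_p))
  })
  pairwise$tukey_significant <- !is.na(pairwise$tukey_p) &
    pairwise$tukey_p < alpha
  pairwise$welch_significant <- !is.na(pairwise$welch_p) &
    pairwise$welch_p < alpha

  structure(
    list(summary = group_summary(estimates, value, group),
         anova = anova_row, pairwise = pairwise, alpha = alpha,
         significant_pairs = pairwise[pairwise$tukey_significant,
                                      c("group1", "group2")]),
    class = "kin_comparison")
}

#' @export
print.kin_comparison <- function(x, ...) {
  cat("<kin_comparison>\n")
  cat("Groups:\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-22s %s\n", x$summary$label[i], x$summary$pretty[i]))
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f_statistic,
              x$anova$p_value))
  cat(sprintf("Pairs with Tukey-adjusted p < %.2g:\n", x$alpha))
  if (nrow(x$significant_pairs) == 0) cat("  (none)\n")
  else for (i in seq_len(nrow(x$significant_pairs)))
    cat(sprintf("  %s vs %s\n", x$significant_pairs$group1[i],
                x$significant_pairs$group2[i]))
  invisible(x)
}

#' Tidiers for `kin_comparison` objects
#'
#' `tidy()` returns the per-pair table (Tukey, Welch, variance F);
#' `glance()` the one-row ANOVA summary.
#'
#' @param x A `kin_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kin_comparison
#' @export
tidy.kin_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.kin_comparison
#' @method glance kin_comparison
#' @export
glance.kin_comparison <- function(x, ...) x$anova

#' Fold change between two groups
#'
#' Ratio of group means, reported alongside both means.
#'
#' @param estimates Tibble of per-chip estimates (see [group_summary()]).
#' @param numerator,denominator Group labels.
#' @param value,group Column names, as in [group_summary()].
#' @return A one-row tibble: `numerator`, `denominator`, `numerator_mean`,
#'   `denominator_mean`, `fold_change`.
#' @export
fold_change <- function(estimates, numerator, denominator, value = "k_in",
                        group = "group") {
  s <- group_summary(estimates, value, group)
  stop_if(!numerator %in% s$label, sprintf("no group '%s'", numerator))
  stop_if(!denominator %in% s$label, sprintf("no group '%s'", denominator))
  num <- s$mean[s$label == numerator]
  den <- s$mean[s$label == denominator]
  stop_if(den == 0, "denominator group mean is zero")
  tibble::tibble(numerator = numerator, denominator = denominator,
                 numerator_mean = num, denominator_mean = den,
                 fold_change = num / den)
}
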