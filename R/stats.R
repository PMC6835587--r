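#' Principal component analysis over samples
#'
#' Samples are the observations and metabolite annotations the variables.
#' By default intensities are mean-centred only -- no scaling and no
#' normalisation, matching a raw-intensity direct-infusion workflow;
#' unit-variance scaling is available by option (features with zero
#' variance are dropped with a message when scaling).
#'
#' @param am An `annotated_matrix`, or a plain metabolites x samples matrix.
#' @param centering `"center_only"` (default) or `"center_scale"`.
#' @param include_excluded Keep excluded samples? Default `FALSE`.
#' @return A list with `scores` (samples x components), `loadings`
#'   (features x components, orthonormal), `explained_variance`
#'   (proportions, non-increasing) and `sdev`.
#' @export
pca_samples <- function(am, centering = c("center_only", "center_scale"),
                        include_excluded = FALSE) {
  centering <- match.arg(centering)
  if (inherits(am, "annotated_matrix")) {
    m <- am$intensity
    if (!include_excluded) {
      m <- m[, am$samples$sample_id[!am$samples$excluded], drop = FALSE]
    }
  } else {
    m <- as.matrix(am)
  }
  x <- t(m)  # samples x features
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 samples and 2 features")
  scale. <- centering == "center_scale"
  if (scale.) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      message("dropping ", sum(v == 0), " zero-variance feature(s) before scaling")
      x <- x[, v > 0, drop = FALSE]
    }
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = scale.)
  total <- sum(fit$sdev^2)
  ev <- if (total > 0) fit$sdev^2 / total else rep(0, length(fit$sdev))
  list(scores = fit$x, loadings = fit$rotation, explained_variance = ev,
       sdev = fit$sdev)
}

#' One-way repeated-measures ANOVA (pools as subjects)
#'
#' Within-subject decomposition for a complete subjects x conditions grid:
#' \eqn{F = MS_{condition} / MS_{condition \times subject}} with
#' \eqn{(k-1)} and \eqn{(k-1)(n-1)} degrees of freedom. No sphericity
#' correction is applied. Subjects (pools) with any missing condition are
#' dropped with a message. With two conditions, F equals the square of the
#' paired t statistic.
#'
#' @param values Numeric matrix, subjects (pools) in rows, conditions
#'   (storage levels) in columns.
#' @return A list: `statistic` (F), `df1`, `df2`, `p_value`, `degenerate`
#'   (`TRUE` when the error term is zero). `NA` statistic when fewer than 2
#'   complete subjects or conditions remain.
#' @export
rm_anova <- function(values) {
  y <- as.matrix(values)
  complete <- stats::complete.cases(y)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " incomplete subject(s) from RM-ANOVA")
    y <- y[complete, , drop = FALSE]
  }
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) {
    return(list(statistic = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p_value = NA_real_, degenerate = FALSE))
  }
  gm <- mean(y)
  ss_cond <- n * sum((colMeans(y) - gm)^2)
  ss_subj <- k * sum((rowMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  if (ss_err == 0) {
    if (ss_cond == 0) {
      # flat grid: no condition signal and no error term
      return(list(statistic = 0, df1 = df1, df2 = df2, p_value = 1,
                  degenerate = TRUE))
    }
    return(list(statistic = Inf, df1 = df1, df2 = df2, p_value = 0,
                degenerate = TRUE))
  }
  f <- (ss_cond / df1) / (ss_err / df2)
  list(statistic = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' Kruskal-Wallis test between two groups
#'
#' Rank-based comparison of the most extreme storage condition against the
#' reference sample, with mid-rank tie correction and a chi-squared
#' reference distribution on k - 1 = 1 degree of freedom. With three pools
#' per group the chi-squared p-value cannot go below about 0.0495 (the
#' rank-extreme arrangement), so Bonferroni correction over a
#' thousand-feature family can never reach significance -- a discreteness
#' limit to keep in mind when interpreting null results.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A list: `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(c(1, 2, 3), c(4, 5, 6)) # H = 3.857
#' @export
kruskal_wallis <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(unique(c(group_a, group_b))) == 1) {
    # every observation tied: no rank information at all
    return(list(statistic = 0, df = 1L, p_value = 1))
  }
  fit <- stats::kruskal.test(list(group_a, group_b))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param m Family size; must be at least `length(p_values)`. Defaults to
#'   the number of p-values. Use the number of features actually tested in
#'   the run (e.g. the full peak set or the panel subset).
#' @return `pmin(1, m * p_values)`, order preserved.
#' @examples
#' bonferroni(1e-5, m = 1852) # 0.01852
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("family size m cannot be smaller than the list")
  pmin(1, m * p_values)
}

#' Per-feature statistical battery for one storage series
#'
#' For every non-sILC metabolite annotation (optionally restricted to the
#' neurometabolic panel): a one-way repeated-measures ANOVA across the
#' reference and all levels of the series with pools as subjects, and a
#' Kruskal-Wallis test comparing the most extreme level to the reference
#' (pool-level intensities, typically 3 vs 3). Both raw p-values are
#' Bonferroni-adjusted with the family size equal to the number of features
#' tested.
#'
#' @param am An `annotated_matrix`.
#' @param series Storage series to test (e.g. `"freeze_thaw"`).
#' @param subset `"all"` or `"panel"`.
#' @return A data frame of class `feature_tests`: `metabolite`,
#'   `f_statistic`, `df1`, `df2`, `p_anova`, `p_anova_bonf`,
#'   `h_statistic`, `df_kw`, `p_kw`, `p_kw_bonf`, and the family size as
#'   attribute `family_size`.
#' @export
feature_tests <- function(am, series, subset = c("all", "panel")) {
  subset <- match.arg(subset)
  samples <- am$samples
  if (!series %in% samples$series) stop("unknown series: ", series)
  included <- samples[!samples$excluded, , drop = FALSE]
  lib <- am$library[!am$library$is_silc, , drop = FALSE]
  if (subset == "panel") lib <- lib[lib$in_neuro_panel, , drop = FALSE]
  if (!nrow(lib)) stop("no features to test")

  pools <- sort(unique(samples$pool))
  levels_s <- c(0, sort(unique(samples$level[samples$series == series])))
  extreme <- max(levels_s)

  # sample id per (pool, level); NA when excluded/absent
  ids <- matrix(NA_character_, length(pools), length(levels_s),
                dimnames = list(NULL, paste0("L", levels_s)))
  for (p in seq_along(pools)) {
    for (l in seq_along(levels_s)) {
      sel <- if (levels_s[l] == 0) {
        included$is_reference & included$pool == pools[p]
      } else {
        included$series == series & included$level == levels_s[l] &
          included$pool == pools[p]
      }
      id <- included$sample_id[sel]
      if (length(id) == 1) ids[p, l] <- id
    }
  }

  m <- nrow(lib)
  res <- data.frame(metabolite = lib$name, f_statistic = NA_real_,
                    df1 = NA_integer_, df2 = NA_integer_, p_anova = NA_real_,
                    h_statistic = NA_real_, df_kw = NA_integer_,
                    p_kw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    grid <- matrix(NA_real_, length(pools), length(levels_s))
    ok <- !is.na(ids)
    grid[ok] <- am$intensity[lib$name[i], ids[ok]]
    fit <- suppressMessages(rm_anova(grid))
    res$f_statistic[i] <- fit$statistic
    res$df1[i] <- fit$df1
    res$df2[i] <- fit$df2
    res$p_anova[i] <- fit$p_value
    ref <- grid[, 1]
    ext <- grid[, which(levels_s == extreme)]
    kw <- kruskal_wallis(ref[!is.na(ref)], ext[!is.na(ext)])
    res$h_statistic[i] <- kw$statistic
    res$df_kw[i] <- kw$df
    res$p_kw[i] <- kw$p_value
  }
  res$p_anova_bonf <- bonferroni(res$p_anova, m = m)
  res$p_kw_bonf <- bonferroni(res$p_kw, m = m)
  res <- res[, c("metabolite", "f_statistic", "df1", "df2", "p_anova",
                 "p_anova_bonf", "h_statistic", "df_kw", "p_kw", "p_kw_bonf")]
  attr(res, "family_size") <- m
  class(res) <- c("feature_tests", "data.frame")
  res
}
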