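#' Fold change of a stored sample against its reference
#'
#' @param sample_intensity Intensity under the storage condition.
#' @param reference_intensity Intensity of the pool's reference sample
#'   (stored at -80 C at time zero); must be positive for a defined result.
#' @return `sample_intensity / reference_intensity`, vectorised; `NA` where
#'   the reference is zero or missing.
#' @export
fold_change <- function(sample_intensity, reference_intensity) {
  out <- ifelse(!is.na(reference_intensity) & reference_intensity > 0,
                sample_intensity / reference_intensity, NA_real_)
  as.numeric(out)
}

#' Confidence interval for per-pool fold changes
#'
#' Default method `"t"`: center is the mean fold change across pools and
#' the half-width is \eqn{t_{1-\alpha/2, n-1} \, s/\sqrt{n}}. Method
#' `"minmax"` reports the observed range around the mean, a conservative
#' alternative when the distributional assumption across 3 pools is
#' doubtful.
#'
#' @param fcs Per-pool fold changes; at least two non-missing values.
#' @param conf_level Confidence level, default 0.95.
#' @param method `"t"` or `"minmax"`.
#' @return Named numeric vector `c(center, low, high)`; all `NA` when fewer
#'   than two fold changes are defined.
#' @examples
#' fc_confidence_interval(c(0.9, 1.0, 1.1)) # half-width 4.3027 * 0.1/sqrt(3)
#' @export
fc_confidence_interval <- function(fcs, conf_level = 0.95,
                                   method = c("t", "minmax")) {
  method <- match.arg(method)
  fcs <- fcs[!is.na(fcs)]
  if (length(fcs) < 2) {
    return(c(center = NA_real_, low = NA_real_, high = NA_real_))
  }
  center <- mean(fcs)
  if (method == "t") {
    n <- length(fcs)
    hw <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(fcs) / sqrt(n)
    c(center = center, low = center - hw, high = center + hw)
  } else {
    c(center = center, low = min(fcs), high = max(fcs))
  }
}

#' Classify a fold-change confidence interval against the variability band
#'
#' A metabolite is called `increased` when the lower confidence limit lies
#' strictly above `1 + mav`, `decreased` when the upper limit lies strictly
#' below `1 - mav`, and `unaffected` otherwise (`undefined` when the
#' interval could not be computed). `mav` is the median absolute variation
#' of the spiked internal standards for the series, i.e. the fold-change
#' variation attributable to the analysis alone.
#'
#' @param ci_low,ci_high Confidence limits (vectorised).
#' @param mav Median absolute variation (>= 0), scalar or vectorised.
#' @return Character vector of calls.
#' @examples
#' classify_call(1.10, 1.40, mav = 0.072) # "increased"
#' @export
classify_call <- function(ci_low, ci_high, mav) {
  stopifnot(all(mav >= 0, na.rm = TRUE))
  band_high <- 1 + mav
  band_low <- 1 - mav
  out <- rep("unaffected", length(ci_low))
  out[ci_low > band_high] <- "increased"
  out[ci_high < band_low] <- "decreased"
  out[is.na(ci_low) | is.na(ci_high)] <- "undefined"
  out
}

#' Per-metabolite stability records for every storage condition
#'
#' For each non-reference series and level, computes per-pool fold changes
#' (triplicate-averaged condition intensity over the pool's reference
#' intensity), aggregates them into a confidence interval across pools, and
#' classifies each metabolite against the series' analysis-variability
#' band. Spiked internal standards are excluded: they calibrate the band
#' and are not themselves assessed. Pools whose reference intensity is zero
#' or whose sample is excluded contribute no fold change; metabolites with
#' fewer than two usable pools get an `undefined` call and are excluded
#' from affected counts.
#'
#' @param am An `annotated_matrix`.
#' @param mav Named numeric vector of per-series median absolute variation
#'   (as `silc_qc()$mav`), or a single number applied to every series.
#' @param conf_level Confidence level for the fold-change interval.
#' @param ci_method `"t"` or `"minmax"`, see [fc_confidence_interval()].
#' @return A data frame of class `stability_records` with one row per
#'   metabolite x series x level: `metabolite`, `group`, `in_neuro_panel`,
#'   `series`, `level`, `n_pools`, `center`, `ci_low`, `ci_high`,
#'   `band_low`, `band_high`, `call`, plus per-pool fold-change columns
#'   `fc_pool<i>`.
#' @export
stability_records <- function(am, mav, conf_level = 0.95,
                              ci_method = c("t", "minmax")) {
  ci_method <- match.arg(ci_method)
  samples <- am$samples
  included <- samples[!samples$excluded, , drop = FALSE]
  series <- setdiff(unique(samples$series), "reference")
  if (length(mav) == 1 && is.null(names(mav))) {
    mav <- stats::setNames(rep(mav, length(series)), series)
  }
  missing_mav <- setdiff(series, names(mav))
  if (length(missing_mav)) {
    stop("no median absolute variation supplied for series: ",
         paste(missing_mav, collapse = ", "))
  }

  lib <- am$library[!am$library$is_silc, , drop = FALSE]
  pools <- sort(unique(samples$pool))

  # reference intensity per pool (NA when excluded or absent)
  ref_col <- vapply(pools, function(p) {
    id <- included$sample_id[included$is_reference & included$pool == p]
    if (length(id) == 1) id else NA_character_
  }, character(1))
  ref_int <- matrix(NA_real_, nrow(lib), length(pools))
  ok <- !is.na(ref_col)
  ref_int[, ok] <- am$intensity[lib$name, ref_col[ok], drop = FALSE]

  rows <- list()
  for (s in series) {
    levels_s <- sort(unique(samples$level[samples$series == s]))
    for (lv in levels_s) {
      cond_int <- matrix(NA_real_, nrow(lib), length(pools))
      for (p in seq_along(pools)) {
        id <- included$sample_id[included$series == s & included$level == lv &
                                   included$pool == pools[p]]
        if (length(id) == 1) cond_int[, p] <- am$intensity[lib$name, id]
      }
      fcs <- matrix(fold_change(cond_int, ref_int), nrow(lib), length(pools))
      ci <- t(apply(fcs, 1, fc_confidence_interval, conf_level = conf_level,
                    method = ci_method))
      band <- variability_band(mav[[s]])
      rec <- data.frame(
        metabolite = lib$name, group = lib$group,
        in_neuro_panel = lib$in_neuro_panel,
        series = s, level = lv,
        n_pools = rowSums(!is.na(fcs)),
        center = ci[, "center"], ci_low = ci[, "low"], ci_high = ci[, "high"],
        band_low = band$band_low, band_high = band$band_high,
        call = classify_call(ci[, "low"], ci[, "high"], mav[[s]]),
        stringsAsFactors = FALSE
      )
      colnames(fcs) <- paste0("fc_pool", pools)
      rows[[length(rows) + 1L]] <- cbind(rec, fcs)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_undef <- sum(out$call == "undefined")
  if (n_undef > 0) {
    message(n_undef, " record(s) undefined (fewer than two usable pools)")
  }
  class(out) <- c("stability_records", "data.frame")
  out
}

#' Count metabolites possibly affected by the most extreme condition
#'
#' Tallies `decreased` and `increased` calls per storage series, by default
#' at the most extreme level of each series, for the full metabolite set or
#' the neurometabolic panel subset. `undefined` records are excluded from
#' the totals and reported separately.
#'
#' @param records A `stability_records` data frame (or any data frame with
#'   `series`, `level`, `call`, `in_neuro_panel` columns).
#' @param subset `"all"` or `"panel"` (neurometabolic panel members only).
#' @param extreme_only If `TRUE` (default), count only the highest level of
#'   each series, the paper-style headline; otherwise count every level.
#' @return Data frame with one row per series: `series`, `level`,
#'   `n_decreased`, `n_increased`, `n_affected`, `n_assessed`,
#'   `n_undefined`.
#' @export
count_affected <- function(records, subset = c("all", "panel"),
                           extreme_only = TRUE) {
  subset <- match.arg(subset)
  if (subset == "panel") {
    records <- records[records$in_neuro_panel, , drop = FALSE]
  }
  series <- unique(records$series)
  if (!length(series)) {
    return(data.frame(series = character(0), level = numeric(0),
                      n_decreased = integer(0), n_increased = integer(0),
                      n_affected = integer(0), n_assessed = integer(0),
                      n_undefined = integer(0)))
  }
  out <- do.call(rbind, lapply(series, function(s) {
    rec <- records[records$series == s, , drop = FALSE]
    lv <- if (extreme_only) max(rec$level) else NA
    if (extreme_only) rec <- rec[rec$level == lv, , drop = FALSE]
    undef <- rec$call == "undefined"
    data.frame(
      series = s, level = lv,
      n_decreased = sum(rec$call == "decreased"),
      n_increased = sum(rec$call == "increased"),
      n_affected = sum(rec$call %in% c("decreased", "increased")),
      n_assessed = sum(!undef),
      n_undefined = sum(undef),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Plot stability records for one series
#'
#' Mean fold change per metabolite with its confidence interval, against
#' the analysis-variability band of the series (dashed lines) and fold
#' change 1 (solid line). Metabolites whose interval clears the band are
#' drawn in colour.
#'
#' @param x A `stability_records` data frame.
#' @param series Series to plot; default the first one present.
#' @param level Level to plot; default the most extreme level present.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted subset.
#' @export
plot.stability_records <- function(x, series = NULL, level = NULL, ...) {
  if (is.null(series)) series <- x$series[1]
  rec <- x[x$series == series, , drop = FALSE]
  if (is.null(level)) level <- max(rec$level)
  rec <- rec[rec$level == level & rec$call != "undefined", , drop = FALSE]
  if (!nrow(rec)) stop("nothing to plot for this series/level")
  i <- seq_len(nrow(rec))
  col <- ifelse(rec$call == "increased", "firebrick",
                ifelse(rec$call == "decreased", "dodgerblue3", "grey55"))
  ylim <- range(c(rec$ci_low, rec$ci_high, rec$band_low, rec$band_high),
                finite = TRUE)
  graphics::plot(i, rec$center, pch = 16, col = col, ylim = ylim,
                 xlab = "metabolite annotation", ylab = "fold change",
                 main = paste0(series, " (level ", level, ")"), ...)
  graphics::segments(i, rec$ci_low, i, rec$ci_high, col = col)
  graphics::abline(h = 1, col = "black")
  graphics::abline(h = c(rec$band_low[1], rec$band_high[1]), lty = 2)
  invisible(rec)
}
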