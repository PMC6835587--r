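#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' computed over all included samples of a run. For spiked stable
#' isotope-labelled compounds this quantifies the purely technical
#' variability of the analysis.
#'
#' @param x Numeric vector of intensities, length >= 2, mean > 0.
#' @return Dimensionless CV.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 0.5
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least two values to compute a CV")
  m <- mean(x)
  if (m == 0) stop("CV undefined: mean intensity is zero")
  stats::sd(x) / m
}

#' Median absolute variation of fold changes across pools
#'
#' The analysis-variability scale for fold changes, computed in four steps:
#' (1) per-pool fold change, extreme-condition intensity over reference
#' intensity; (2) subtract 1; (3) take absolute values; (4) take the median
#' across pools. Pools with a zero or missing reference are excluded with a
#' warning; if no pool remains the result is `NA` with a warning.
#'
#' @param extreme Per-pool intensities at the most extreme storage
#'   condition.
#' @param reference Per-pool reference intensities, paired with `extreme`.
#' @return Dimensionless median absolute variation (>= 0), or `NA_real_` if
#'   undefined.
#' @examples
#' median_absolute_variation(c(1.2, 0.9, 1.05), c(1, 1, 1)) # 0.1
#' @export
median_absolute_variation <- function(extreme, reference) {
  stopifnot(length(extreme) == length(reference))
  bad <- is.na(reference) | reference <= 0 | is.na(extreme)
  if (any(bad)) {
    warning(sum(bad), " pool(s) excluded from the median absolute variation ",
            "(zero or missing reference)")
  }
  if (all(bad)) {
    warning("median absolute variation undefined: no pool with a usable reference")
    return(NA_real_)
  }
  stats::median(abs(extreme[!bad] / reference[!bad] - 1))
}

#' Quantile summary of per-compound QC values
#'
#' Summarises a set of per-compound QC values (CVs or median absolute
#' variations) at the 5th percentile, median and 95th percentile by
#' default. The quantile method is configurable because published
#' percentiles are sensitive to the interpolation rule; the median is
#' rule-independent for odd-length input.
#'
#' @param values Non-empty numeric vector.
#' @param probs Probabilities in (0, 1); default `c(0.05, 0.5, 0.95)`.
#' @param type Quantile algorithm passed to [stats::quantile()]; default 7
#'   (linear interpolation of order statistics).
#' @return Named numeric vector of quantiles.
#' @export
qc_summary <- function(values, probs = c(0.05, 0.5, 0.95), type = 7) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarise")
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)")
  stats::quantile(values, probs = probs, type = type, names = TRUE)
}

#' Analysis-variability band around fold change 1
#'
#' The fold-change interval `1 - mav` to `1 + mav` attributed to technical
#' variability; a metabolite counts as affected by a storage condition only
#' when its fold-change confidence interval lies entirely outside this band.
#'
#' @param mav Median absolute variation (>= 0); vectorised.
#' @return A data frame with columns `band_low`, `band_high`.
#' @examples
#' variability_band(0.072) # 0.928 to 1.072
#' @export
variability_band <- function(mav) {
  stopifnot(all(mav >= 0, na.rm = TRUE))
  data.frame(band_low = 1 - mav, band_high = 1 + mav)
}

#' Internal-standard QC metrics for an annotated run
#'
#' For every spiked stable isotope-labelled compound in the library:
#' the coefficient of variation over all included (non-excluded) samples,
#' and, for the most extreme level of each storage series, the median
#' absolute variation across pools. Summary rows give the 5th percentile,
#' median and 95th percentile over compounds.
#'
#' @param am An `annotated_matrix` whose library contains sILC entries.
#' @param quantile_type Quantile algorithm for the summary rows.
#' @return A list of class `silc_qc` with `per_compound` (one row per sILC:
#'   `compound`, `cv`, one `mav_<series>` column per non-reference series),
#'   `summary` (quantile rows over compounds) and `mav` (named vector of
#'   per-series median-over-compounds MAV, the band scale used by the
#'   stability classifier).
#' @export
silc_qc <- function(am, quantile_type = 7) {
  lib <- am$library
  silc <- lib$name[lib$is_silc]
  if (!length(silc)) stop("library contains no sILC entries")
  samples <- am$samples
  included <- samples[!samples$excluded, , drop = FALSE]
  series <- setdiff(unique(samples$series), "reference")

  per <- data.frame(compound = silc, cv = NA_real_, stringsAsFactors = FALSE)
  for (s in series) per[[paste0("mav_", s)]] <- NA_real_

  for (i in seq_along(silc)) {
    x <- am$intensity[silc[i], included$sample_id]
    per$cv[i] <- coefficient_of_variation(x)
    for (s in series) {
      lv <- samples$level[samples$series == s]
      extreme_level <- max(lv)
      pools <- sort(unique(samples$pool))
      ex <- re <- rep(NA_real_, length(pools))
      for (p in seq_along(pools)) {
        ex_row <- included$sample_id[included$series == s &
                                       included$level == extreme_level &
                                       included$pool == pools[p]]
        re_row <- included$sample_id[included$is_reference &
                                       included$pool == pools[p]]
        if (length(ex_row) == 1 && length(re_row) == 1) {
          ex[p] <- am$intensity[silc[i], ex_row]
          re[p] <- am$intensity[silc[i], re_row]
        }
      }
      usable <- !is.na(ex) & !is.na(re)
      per[[paste0("mav_", s)]][i] <- if (any(usable)) {
        suppressWarnings(median_absolute_variation(ex[usable], re[usable]))
      } else NA_real_
    }
  }

  value_cols <- setdiff(names(per), "compound")
  summary <- do.call(rbind, lapply(value_cols, function(cl) {
    q <- qc_summary(per[[cl]], type = quantile_type)
    data.frame(metric = cl, p05 = q[[1]], median = q[[2]], p95 = q[[3]])
  }))
  mav <- vapply(series, function(s) {
    stats::median(per[[paste0("mav_", s)]], na.rm = TRUE)
  }, numeric(1))
  structure(list(per_compound = per, summary = summary, mav = mav),
            class = "silc_qc")
}

#' @export
print.silc_qc <- function(x, ...) {
  cat("sILC QC over", nrow(x$per_compound), "internal standards\n")
  cat("  median CV:", format(stats::median(x$per_compound$cv), digits = 3), "\n")
  cat("  per-series MAV (band half-width):\n")
  for (s in names(x$mav)) {
    cat("   ", s, "=", format(x$mav[[s]], digits = 3), "\n")
  }
  invisible(x)
}
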