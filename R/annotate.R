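#' Match measured peaks to library metabolites within a ppm tolerance
#'
#' A peak at m/z \eqn{x} matches the adduct channel with theoretical m/z
#' \eqn{t} iff \eqn{|x - t|/t \times 10^6 \le} `tol_ppm` (boundary
#' inclusive). Every metabolite is screened across the five default adduct
#' channels; a peak may match several metabolites (isomers or accidental
#' collisions) and all matches are retained. If the peak table carries a
#' `polarity` column, peaks only match channels of the same polarity.
#' Peaks outside the instrument scan window are dropped first, with a
#' message reporting the count.
#'
#' @param peaks A `peak_table` data frame (`sample_id`, `replicate`, `mz`,
#'   `intensity`, optional `polarity`).
#' @param library A [metabolite_library()]. Unreachable entries are screened
#'   like any other (they simply never match in-window peaks).
#' @param tol_ppm Matching tolerance in parts per million (> 0); default 2.
#' @param rules Adduct table, default [adduct_rules()].
#' @param scan_window m/z ingestion window, default `c(70, 600)`.
#' @return A data frame of class `peak_matches` with one row per (peak,
#'   matched channel): `sample_id`, `replicate`, `mz`, `intensity`,
#'   `metabolite`, `adduct`, `theoretical_mz`, `ppm_error`.
#' @export
match_peaks <- function(peaks, library, tol_ppm = 2, rules = adduct_rules(),
                        scan_window = c(70, 600)) {
  stopifnot(tol_ppm >= 0)
  empty <- data.frame(sample_id = character(0), replicate = integer(0),
                      mz = numeric(0), intensity = numeric(0),
                      metabolite = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("peak_matches", "data.frame")
  if (nrow(peaks) == 0 || nrow(library) == 0) return(empty)

  out_of_window <- peaks$mz < scan_window[1] | peaks$mz > scan_window[2]
  if (any(out_of_window)) {
    message("dropping ", sum(out_of_window), " peak(s) outside the ",
            scan_window[1], "-", scan_window[2], " m/z scan window")
    peaks <- peaks[!out_of_window, , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(empty)

  channels <- data.frame(
    metabolite = rep(library$name, each = nrow(rules)),
    adduct = rep(rules$adduct, nrow(library)),
    polarity = rep(rules$polarity, nrow(library)),
    theoretical_mz = rep(library$monoisotopic_mass, each = nrow(rules)) +
      rep(rules$shift, nrow(library)),
    stringsAsFactors = FALSE
  )

  has_polarity <- "polarity" %in% names(peaks)
  eps <- tol_ppm * 1e-6
  pieces <- lapply(unique(channels$polarity), function(pol) {
    ch <- channels[channels$polarity == pol, , drop = FALSE]
    ch <- ch[order(ch$theoretical_mz), , drop = FALSE]
    pk <- if (has_polarity) peaks[peaks$polarity == pol, , drop = FALSE] else peaks
    if (nrow(pk) == 0 || nrow(ch) == 0) return(NULL)
    lo <- pk$mz / (1 + eps)
    hi <- pk$mz / (1 - eps)
    first <- findInterval(lo, ch$theoretical_mz, left.open = TRUE) + 1L
    last <- findInterval(hi, ch$theoretical_mz)
    n_hit <- pmax(last - first + 1L, 0L)
    if (sum(n_hit) == 0) return(NULL)
    peak_idx <- rep(seq_len(nrow(pk)), n_hit)
    chan_idx <- sequence(n_hit, from = first)
    res <- data.frame(
      sample_id = pk$sample_id[peak_idx],
      replicate = pk$replicate[peak_idx],
      mz = pk$mz[peak_idx],
      intensity = pk$intensity[peak_idx],
      metabolite = ch$metabolite[chan_idx],
      adduct = ch$adduct[chan_idx],
      theoretical_mz = ch$theoretical_mz[chan_idx],
      stringsAsFactors = FALSE
    )
    res$ppm_error <- (res$mz - res$theoretical_mz) / res$theoretical_mz * 1e6
    res[abs(res$ppm_error) <= tol_ppm, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0) return(empty)
  rownames(out) <- NULL
  class(out) <- c("peak_matches", "data.frame")
  out
}

#' Sum matched adduct intensities into one value per metabolite and sample
#'
#' For each metabolite and sample replicate, the intensities of all matched
#' peaks across the five adduct channels are added together (multiple peaks
#' in one channel are summed too; absent channels contribute zero). The
#' technical replicates of a sample are then collapsed to a single value
#' with `replicate_fun` (the arithmetic mean by default), giving one
#' intensity per metabolite annotation per design sample.
#'
#' @param matches A `peak_matches` data frame from [match_peaks()].
#' @param library A [metabolite_library()]; all entries appear as rows even
#'   when never detected.
#' @param design A `study_design`; all samples appear as columns, excluded
#'   ones included (they are skipped downstream, not here).
#' @param replicate_fun `"mean"` (default) or `"median"` collapse over
#'   technical replicates.
#' @return An object of class `annotated_matrix`: a list with `intensity`
#'   (metabolites x samples matrix), `detected` (logical matrix), `samples`
#'   (sample-level design), `library`, `by_adduct` (per-channel,
#'   per-replicate contribution breakdown) and `replicate_fun`.
#' @export
summed_intensities <- function(matches, library, design,
                               replicate_fun = c("mean", "median")) {
  replicate_fun <- match.arg(replicate_fun)
  unknown <- setdiff(unique(matches$sample_id), design$sample_id)
  if (length(unknown)) {
    stop("matches reference sample(s) absent from the design: ",
         paste(unknown, collapse = ", "))
  }
  samples <- unique(design[, setdiff(names(design), "replicate"), drop = FALSE])
  samples <- samples[!duplicated(samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  rep_key_all <- paste(design$sample_id, design$replicate, sep = "\r")
  rep_levels <- unique(rep_key_all)
  met_f <- factor(matches$metabolite, levels = library$name)
  rep_f <- factor(paste(matches$sample_id, matches$replicate, sep = "\r"),
                  levels = rep_levels)
  per_rep <- stats::xtabs(intensity ~ met_f + rep_f,
                          data = data.frame(intensity = matches$intensity,
                                            met_f = met_f, rep_f = rep_f))
  per_rep <- matrix(as.numeric(per_rep), nrow = nrow(library),
                    dimnames = list(library$name, rep_levels))
  rep_sample <- sub("\r.*$", "", rep_levels)

  collapse <- if (replicate_fun == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  intensity <- vapply(samples$sample_id, function(s) {
    collapse(per_rep[, rep_sample == s, drop = FALSE])
  }, numeric(nrow(library)))
  dimnames(intensity) <- list(library$name, samples$sample_id)

  hit <- stats::xtabs(~ met_f + rep_f)
  hit <- matrix(as.numeric(hit), nrow = nrow(library))
  detected <- vapply(samples$sample_id, function(s) {
    rowSums(hit[, rep_sample == s, drop = FALSE]) > 0
  }, logical(nrow(library)))
  dimnames(detected) <- dimnames(intensity)

  by_adduct <- if (nrow(matches)) {
    stats::aggregate(intensity ~ metabolite + adduct + sample_id + replicate,
                     data = matches, FUN = sum)
  } else {
    data.frame(metabolite = character(0), adduct = character(0),
               sample_id = character(0), replicate = integer(0),
               intensity = numeric(0))
  }

  structure(list(intensity = intensity, detected = detected,
                 samples = samples, library = library, by_adduct = by_adduct,
                 replicate_fun = replicate_fun),
            class = "annotated_matrix")
}

#' Annotate a peak table end to end
#'
#' Convenience wrapper: [match_peaks()] then [summed_intensities()].
#'
#' @inheritParams match_peaks
#' @inheritParams summed_intensities
#' @return An `annotated_matrix`.
#' @export
annotate_peaks <- function(peaks, library, design, tol_ppm = 2,
                           rules = adduct_rules(), scan_window = c(70, 600),
                           replicate_fun = c("mean", "median")) {
  matches <- match_peaks(peaks, library, tol_ppm = tol_ppm, rules = rules,
                         scan_window = scan_window)
  summed_intensities(matches, library, design,
                     replicate_fun = match.arg(replicate_fun))
}

#' @export
print.annotated_matrix <- function(x, ...) {
  cat("annotated_matrix:", nrow(x$intensity), "metabolite annotations x",
      ncol(x$intensity), "samples\n")
  cat("  detected cells:", sum(x$detected), "of", length(x$detected), "\n")
  cat("  replicate collapse:", x$replicate_fun, "\n")
  invisible(x)
}

#' Write an annotated matrix as wide CSV plus a provenance JSON
#'
#' @param am An `annotated_matrix`.
#' @param csv_path Output CSV path (metabolites x samples).
#' @param json_path Optional path for the per-cell adduct contribution
#'   breakdown.
#' @return `csv_path` invisibly.
#' @export
write_annotated_matrix <- function(am, csv_path, json_path = NULL) {
  out <- data.frame(metabolite = rownames(am$intensity), am$intensity,
                    check.names = FALSE)
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(am$by_adduct, json_path, dataframe = "rows",
                         digits = NA)
  }
  invisible(csv_path)
}
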