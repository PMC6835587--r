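#' Specify injected storage effects and technical noise for the simulator
#'
#' An effect specification states the "true" world for a synthetic run:
#' multiplicative storage drifts for chosen metabolites at chosen conditions,
#' global per-pool scale factors, and the standard deviation of the
#' multiplicative (lognormal) technical noise. Spiked internal standards are
#' never allowed to drift: their variation must reflect analysis variability
#' only.
#'
#' @param drifts `NULL` (no storage effect anywhere) or a data frame with
#'   columns `metabolite`, `series`, `level`, `fc`. `fc` is the true fold
#'   change (> 0) relative to the reference sample; `level = NA` applies the
#'   drift to every level of the series.
#' @param pool_factors Numeric vector of per-pool global scale factors
#'   (recycled over pools).
#' @param noise_sigma Standard deviation of the log-intensity technical
#'   noise added independently per replicate infusion. The implied
#'   intensity-scale coefficient of variation of a single infusion is
#'   `sqrt(exp(sigma^2) - 1)`. The default 0.29 is calibrated so that the
#'   cross-sample CV of triplicate-averaged internal-standard intensities
#'   lands near 0.17, the scale reported for direct-infusion CSF runs.
#' @param baseline_range Range of metabolite baseline intensities (arbitrary
#'   units); baselines are drawn log-uniformly over it.
#' @param mz_jitter_ppm Half-width of the uniform ppm mass error applied to
#'   each simulated peak; must stay below the matching tolerance.
#' @param adduct_dropout Probability that an individual adduct peak is
#'   missing from a replicate's peak list.
#' @param seed Integer seed driving all randomness in the simulator.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(drifts = NULL, pool_factors = 1, noise_sigma = 0.29,
                        baseline_range = c(1e4, 1e6), mz_jitter_ppm = 0.5,
                        adduct_dropout = 0, seed = 1L) {
  if (!is.null(drifts)) {
    stopifnot(is.data.frame(drifts),
              all(c("metabolite", "series", "level", "fc") %in% names(drifts)))
    if (any(!is.finite(drifts$fc) | drifts$fc <= 0)) {
      stop("all drift fold changes must be positive")
    }
  }
  stopifnot(noise_sigma >= 0, all(pool_factors > 0),
            adduct_dropout >= 0, adduct_dropout < 1,
            baseline_range[1] > 0, baseline_range[1] <= baseline_range[2])
  structure(list(drifts = drifts, pool_factors = pool_factors,
                 noise_sigma = noise_sigma, baseline_range = baseline_range,
                 mz_jitter_ppm = mz_jitter_ppm, adduct_dropout = adduct_dropout,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

# True fold change for one metabolite x (series, level), given the drift table.
.lookup_drift <- function(drifts, metabolite, series, level) {
  if (is.null(drifts)) return(rep(1, length(metabolite)))
  fc <- rep(1, length(metabolite))
  for (i in seq_len(nrow(drifts))) {
    hit <- metabolite == drifts$metabolite[i] & series == drifts$series[i] &
      (is.na(drifts$level[i]) | level == drifts$level[i])
    fc[hit] <- fc[hit] * drifts$fc[i]
  }
  fc
}

#' Simulate peak tables for a study design
#'
#' Generates one called peak list per sample and technical replicate. Each
#' library metabolite contributes peaks at its five adduct m/z values; the
#' summed intensity over adducts equals
#' `baseline * pool_factor * drift(series, level) * exp(eps)` with
#' `eps ~ Normal(0, noise_sigma^2)` drawn independently per replicate
#' infusion. Reference samples always have drift 1, as do spiked internal
#' standards everywhere. Adduct abundances split the total according to
#' fixed per-metabolite weights; small uniform ppm mass errors and optional
#' per-adduct dropout emulate instrument imperfections.
#'
#' @param library A [metabolite_library()]; must be non-empty.
#' @param design A `study_design` from [generate_design()].
#' @param effects An [effect_spec()].
#' @return A data frame of class `peak_table` with columns `sample_id`,
#'   `replicate`, `polarity`, `mz`, `intensity`, one row per simulated peak
#'   (all design rows, excluded ones included). The attribute `truth` holds
#'   the noise-free per-metabolite intended total intensity per sample and
#'   the per-replicate realised totals, for parameter-recovery checks.
#' @examples
#' lib <- generate_library(10, c(70, 550), n_silc = 2, seed = 1)
#' des <- generate_design(2, default_condition_grid()[1:3, ], replicates = 2)
#' pk <- simulate_peak_tables(lib, des, effect_spec(noise_sigma = 0.05, seed = 9))
#' @export
simulate_peak_tables <- function(library, design, effects = effect_spec()) {
  stopifnot(inherits(effects, "effect_spec"))
  if (nrow(library) == 0) stop("library must be non-empty")
  if (!is.null(effects$drifts)) {
    unknown <- setdiff(effects$drifts$metabolite, library$name)
    if (length(unknown)) {
      stop("effect spec references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    silc_hit <- intersect(effects$drifts$metabolite,
                          library$name[library$is_silc])
    if (length(silc_hit)) {
      stop("sILC entries cannot drift (their variation must be technical only): ",
           paste(silc_hit, collapse = ", "))
    }
  }

  rules <- adduct_rules()
  n_met <- nrow(library)
  n_add <- nrow(rules)
  pool_factors <- rep_len(effects$pool_factors, max(design$pool))

  withr::with_seed(effects$seed, {
    log_range <- log(effects$baseline_range)
    baseline <- exp(stats::runif(n_met, log_range[1], log_range[2]))
    # fixed per-metabolite adduct abundance pattern, rows sum to 1
    w <- matrix(stats::runif(n_met * n_add, 0.05, 1), n_met, n_add)
    w <- w / rowSums(w)

    n_rows <- nrow(design)
    drift <- vapply(seq_len(n_met), function(j) {
      .lookup_drift(effects$drifts, rep(library$name[j], n_rows),
                    design$series, design$level)
    }, numeric(n_rows))            # design rows x metabolites
    eps <- matrix(stats::rnorm(n_rows * n_met, 0, effects$noise_sigma),
                  n_rows, n_met)
    total <- outer(pool_factors[design$pool], baseline) * drift * exp(eps)

    # long table: one row per design row x metabolite x adduct
    peak <- expand.grid(row = seq_len(n_rows), met = seq_len(n_met),
                        add = seq_len(n_add))
    theo <- library$monoisotopic_mass[peak$met] + rules$shift[peak$add]
    jitter <- stats::runif(nrow(peak), -1, 1) * effects$mz_jitter_ppm
    keep <- rep(TRUE, nrow(peak))
    if (effects$adduct_dropout > 0) {
      keep <- stats::runif(nrow(peak)) >= effects$adduct_dropout
    }
    out <- data.frame(
      sample_id = design$sample_id[peak$row],
      replicate = design$replicate[peak$row],
      polarity = rules$polarity[peak$add],
      mz = theo * (1 + jitter * 1e-6),
      intensity = total[cbind(peak$row, peak$met)] * w[cbind(peak$met, peak$add)],
      stringsAsFactors = FALSE
    )[keep, ]
    rownames(out) <- NULL

    truth <- data.frame(
      sample_id = design$sample_id[peak$row[peak$add == 1]],
      replicate = design$replicate[peak$row[peak$add == 1]],
      metabolite = library$name[peak$met[peak$add == 1]],
      true_fc = drift[cbind(peak$row, peak$met)][peak$add == 1],
      realised_total = total[cbind(peak$row, peak$met)][peak$add == 1],
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- truth
    class(out) <- c("peak_table", "data.frame")
    out
  })
}

#' Read or write peak tables as long-format CSV
#'
#' Columns: `sample_id`, `replicate`, `polarity` (optional), `mz`,
#' `intensity`.
#'
#' @param path File path.
#' @param peaks A `peak_table` data frame.
#' @return `read_peaks()` returns a `peak_table`; `write_peaks()` returns
#'   `path` invisibly.
#' @export
read_peaks <- function(path) {
  peaks <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "replicate", "mz", "intensity")
  if (!all(required %in% names(peaks))) {
    stop("peak file must have columns: ", paste(required, collapse = ", "))
  }
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
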