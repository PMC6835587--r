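#' Build a run configuration
#'
#' Collects every knob of the pipeline into one validated list that can be
#' serialised to JSON and re-run reproducibly. The library can be a file, a
#' synthetic one, or the bundled CSF panel; the design is generated from a
#' condition grid or read from file; peaks are simulated (with an effect
#' specification) or read from CSV.
#'
#' @param seed Integer seed used for every source of randomness.
#' @param pools,replicates Study dimensions when generating the design.
#' @param grid Condition grid data frame or `NULL` for
#'   [default_condition_grid()].
#' @param library A list: `source = "generate"` (with `n_metabolites`,
#'   `n_silc`, `mass_range`), `source = "panel"` (bundled CSF panel), or
#'   `source = "file"` (with `path`).
#' @param design_path Optional design TSV; otherwise generated.
#' @param exclude Sample ids to mark excluded (failed infusions).
#' @param peaks_path Optional peak-table CSV; otherwise simulated.
#' @param effects Named list of [effect_spec()] arguments (without `seed`).
#' @param tol_ppm Annotation tolerance in ppm.
#' @param ci_method `"t"` or `"minmax"` fold-change interval.
#' @param conf_level Confidence level for fold-change intervals.
#' @param quantile_type Quantile algorithm for QC summaries.
#' @param replicate_fun `"mean"` or `"median"` replicate collapse.
#' @param out_dir Output directory; created if missing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, pools = 3L, replicates = 3L, grid = NULL,
                       library = list(source = "generate", n_metabolites = 120,
                                      n_silc = 17, mass_range = c(70, 600)),
                       design_path = NULL, exclude = character(0),
                       peaks_path = NULL, effects = list(),
                       tol_ppm = 2, ci_method = c("t", "minmax"),
                       conf_level = 0.95, quantile_type = 7,
                       replicate_fun = c("mean", "median"), out_dir = NULL) {
  stopifnot(tol_ppm > 0, conf_level > 0, conf_level < 1)
  cfg <- list(seed = as.integer(seed), pools = pools, replicates = replicates,
              grid = grid, library = library, design_path = design_path,
              exclude = exclude, peaks_path = peaks_path, effects = effects,
              tol_ppm = tol_ppm, ci_method = match.arg(ci_method),
              conf_level = conf_level, quantile_type = quantile_type,
              replicate_fun = match.arg(replicate_fun), out_dir = out_dir)
  for (p in c(cfg$design_path, cfg$peaks_path,
              if (identical(library$source, "file")) library$path)) {
    if (!is.null(p) && !file.exists(p)) stop("path not resolvable: ", p)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read or write a run configuration as JSON
#'
#' @param path File path.
#' @param config A `run_config`.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$grid)) raw$grid <- as.data.frame(raw$grid)
  if (!is.null(raw$effects$drifts)) {
    raw$effects$drifts <- as.data.frame(raw$effects$drifts)
  }
  do.call(run_config, raw[setdiff(names(raw), character(0))])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Checks the structural preconditions of a run without throwing: exactly
#' one non-excluded reference per pool, strictly increasing unique levels
#' within each series, positive metabolite masses and unique names, peak
#' m/z within the scan window and non-negative intensities.
#'
#' @param library A [metabolite_library()] (or `NULL` to skip).
#' @param design A `study_design` (or `NULL` to skip).
#' @param peaks A `peak_table` (or `NULL` to skip).
#' @param scan_window m/z window, default `c(70, 600)`.
#' @return A data frame with columns `issue` and `detail`; zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(library = NULL, design = NULL, peaks = NULL,
                            scan_window = c(70, 600)) {
  issues <- list()
  add <- function(issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(issue = issue, detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  if (!is.null(library)) {
    if (any(library$monoisotopic_mass <= 0, na.rm = TRUE)) {
      add("nonpositive_mass",
          paste(library$name[library$monoisotopic_mass <= 0], collapse = ","))
    }
    dup <- unique(library$name[duplicated(library$name)])
    if (length(dup)) add("duplicate_name", paste(dup, collapse = ","))
    if (any(!library$reachable)) {
      add("unreachable_entry",
          paste(library$name[!library$reachable], collapse = ","))
    }
  }
  if (!is.null(design)) {
    for (p in sort(unique(design$pool))) {
      n_ref <- length(unique(design$sample_id[design$is_reference &
                                                !design$excluded &
                                                design$pool == p]))
      if (n_ref == 0) add("missing_reference", paste0("pool=", p))
      if (n_ref > 1) add("multiple_references", paste0("pool=", p))
    }
    cond <- unique(design[!design$is_reference,
                          c("sample_id", "pool", "series", "level")])
    for (key in split(cond, list(cond$pool, cond$series), drop = TRUE)) {
      if (anyDuplicated(key$level)) {
        add("duplicate_level",
            paste0("pool=", key$pool[1], ",series=", key$series[1]))
      }
    }
  }
  if (!is.null(peaks)) {
    n_out <- sum(peaks$mz < scan_window[1] | peaks$mz > scan_window[2])
    if (n_out) add("peak_outside_scan_window", paste0("n=", n_out))
    if (any(peaks$intensity < 0)) {
      add("negative_intensity", paste0("n=", sum(peaks$intensity < 0)))
    }
  }
  if (!length(issues)) {
    return(data.frame(issue = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Run the stability pipeline end to end
#'
#' Resolves the inputs named by the configuration (generating synthetic
#' ones where no files are given), annotates the peak tables, computes
#' internal-standard QC metrics, classifies per-condition fold changes
#' against the analysis-variability band, runs the per-feature statistical
#' battery and a sample PCA, and (when `out_dir` is set) writes every
#' result table as headered CSV plus a JSON run manifest. Deterministic for
#' a fixed configuration and seed. A pool without a usable reference sample
#' is a hard failure; excluded samples are skipped with a logged tally.
#'
#' @param config A `run_config` (or a path to a JSON one).
#' @param out_dir Overrides `config$out_dir` when given.
#' @return A list of class `stability_run`: `config`, `library`, `design`,
#'   `peaks`, `annotated` (the `annotated_matrix`), `qc` (`silc_qc` or
#'   `NULL`), `records` (`stability_records`), `affected` and
#'   `affected_panel` (count tables), `tests` (per-series
#'   `feature_tests`), `pca`, `validation` (issue list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$out_dir

  lib_spec <- config$library
  library <- switch(
    lib_spec$source,
    generate = generate_library(lib_spec$n_metabolites,
                                mass_range = lib_spec$mass_range %||% c(70, 600),
                                n_silc = lib_spec$n_silc %||% 0,
                                seed = config$seed),
    panel = csf_panel_library(),
    file = read_library(lib_spec$path),
    stop("unknown library source: ", lib_spec$source)
  )
  grid <- if (is.null(config$grid)) default_condition_grid() else config$grid
  design <- if (is.null(config$design_path)) {
    generate_design(config$pools, grid, config$replicates)
  } else {
    read_design(config$design_path)
  }
  if (length(config$exclude)) design <- exclude_samples(design, config$exclude)
  message("design: ", length(unique(design$sample_id)), " samples, ",
          sum(design$excluded), " replicate row(s) excluded")

  peaks <- if (is.null(config$peaks_path)) {
    effects <- do.call(effect_spec, c(config$effects, list(seed = config$seed)))
    simulate_peak_tables(library, design, effects)
  } else {
    read_peaks(config$peaks_path)
  }
  message("peaks read: ", nrow(peaks))

  validation <- validate_inputs(library, design, peaks)
  ref_missing <- validation$detail[validation$issue == "missing_reference"]
  if (length(ref_missing)) {
    stop("reference sample missing for ", paste(ref_missing, collapse = ", "),
         "; every pool needs a usable reference")
  }

  matches <- match_peaks(peaks, library, tol_ppm = config$tol_ppm)
  message("peaks matched: ", nrow(matches))
  am <- summed_intensities(matches, library, design,
                           replicate_fun = config$replicate_fun)
  message("metabolite annotations summed: ", nrow(am$intensity))

  qc <- NULL
  if (any(library$is_silc)) {
    qc <- silc_qc(am, quantile_type = config$quantile_type)
    mav <- qc$mav
  } else {
    stop("library has no sILC entries: cannot calibrate the analysis-",
         "variability band")
  }

  records <- stability_records(am, mav, conf_level = config$conf_level,
                               ci_method = config$ci_method)
  affected <- count_affected(records, "all")
  affected_panel <- count_affected(records, "panel")
  message("affected calls (all features): ",
          paste(affected$series, affected$n_affected, collapse = ", "))

  series <- setdiff(unique(design$series), "reference")
  tests <- lapply(stats::setNames(series, series), function(s) {
    suppressMessages(feature_tests(am, s))
  })
  pca <- pca_samples(am)

  run <- structure(list(config = config, library = library, design = design,
                        peaks = peaks, annotated = am, qc = qc,
                        records = records, affected = affected,
                        affected_panel = affected_panel, tests = tests,
                        pca = pca, validation = validation),
                   class = "stability_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline run to disk
#'
#' Emits headered CSVs for every stage plus `manifest.json` holding the
#' package version, the seed and the full configuration, from which the
#' bundle can be regenerated with [run_pipeline()].
#'
#' @param run A `stability_run`.
#' @param out_dir Output directory, created if needed.
#' @return The output directory, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  write_library(run$library, pth("library.tsv"))
  write_design(run$design, pth("design.tsv"))
  write_annotated_matrix(run$annotated, pth("annotated_matrix.csv"),
                         pth("annotation_provenance.json"))
  if (!is.null(run$qc)) {
    utils::write.csv(run$qc$per_compound, pth("silc_qc.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(run$qc$summary, pth("silc_qc_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(as.data.frame(run$records), pth("stability_records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$affected, pth("affected_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(run$affected_panel, pth("affected_counts_panel.csv"),
                   row.names = FALSE, quote = FALSE)
  for (s in names(run$tests)) {
    utils::write.csv(as.data.frame(run$tests[[s]]),
                     pth(paste0("feature_tests_", s, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(data.frame(sample_id = rownames(run$pca$scores),
                              run$pca$scores[, seq_len(min(5, ncol(run$pca$scores))),
                                             drop = FALSE]),
                   pth("pca_scores.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(package = "dimstab",
                   version = as.character(utils::packageVersion("dimstab")),
                   seed = run$config$seed, config = unclass(run$config))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.stability_run <- function(x, ...) {
  cat("stability_run:", nrow(x$annotated$intensity), "annotations x",
      ncol(x$annotated$intensity), "samples\n")
  print(x$affected)
  invisible(x)
}
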