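#' Default storage-condition grid
#'
#' The default grid covers four storage series applied to aliquots before
#' final storage at -80 C: up to seven freeze/thaw cycles, up to four months
#' at -20 C, up to a week refrigerated (5-8 C) and up to a week at room
#' temperature (18-22 C) -- 22 conditions in total. The grid is fully
#' configurable; any data frame with columns `series`, `level`, `unit` is
#' accepted by [generate_design()].
#'
#' @return Data frame with columns `series` (one of `freeze_thaw`,
#'   `minus20`, `fridge`, `room`), `level` (numeric, strictly increasing
#'   within a series) and `unit`.
#' @export
default_condition_grid <- function() {
  rbind(
    data.frame(series = "freeze_thaw", level = 1:7, unit = "cycles"),
    data.frame(series = "minus20", level = 1:4, unit = "months"),
    data.frame(series = "fridge", level = c(8, 24, 48, 72, 168), unit = "hours"),
    data.frame(series = "room", level = c(2, 8, 24, 48, 72, 168), unit = "hours")
  )
}

#' Generate a storage-stability study design
#'
#' Builds the sample sheet for a pooled-biofluid stability experiment: for
#' each pool, one reference sample (stored at -80 C at time zero) plus one
#' sample per storage condition, each measured in `replicates` technical
#' replicates (repeated infusions of one preparation).
#'
#' @param pools Number of biofluid pools (>= 1).
#' @param grid Condition grid as from [default_condition_grid()]; may be
#'   empty (reference samples only).
#' @param replicates Technical replicates per sample (>= 1).
#' @return A data frame of class `study_design` with one row per
#'   (sample, replicate): columns `sample_id`, `pool`, `series`, `level`,
#'   `unit`, `replicate`, `is_reference`, `excluded`. The number of rows is
#'   `pools * (1 + nrow(grid)) * replicates`.
#' @examples
#' d <- generate_design(3, default_condition_grid(), replicates = 1)
#' nrow(d) # 69
#' @export
generate_design <- function(pools, grid = default_condition_grid(),
                            replicates = 3) {
  stopifnot(replicates >= 1)
  if (pools < 1) stop("at least one pool is required")
  if (nrow(grid) > 0) {
    if (!all(c("series", "level") %in% names(grid))) {
      stop("grid must have columns 'series' and 'level'")
    }
    for (s in unique(grid$series)) {
      lv <- grid$level[grid$series == s]
      if (anyDuplicated(lv)) stop("duplicate levels in series '", s, "'")
      if (is.unsorted(lv, strictly = TRUE)) {
        stop("levels in series '", s, "' must be strictly increasing")
      }
    }
  }
  if (!"unit" %in% names(grid)) grid$unit <- NA_character_

  per_pool <- rbind(
    data.frame(series = "reference", level = 0, unit = NA_character_),
    grid[, c("series", "level", "unit")]
  )
  base <- do.call(rbind, lapply(seq_len(pools), function(p) {
    cbind(pool = p, per_pool)
  }))
  base$is_reference <- base$series == "reference"
  base$sample_id <- ifelse(
    base$is_reference,
    sprintf("P%d_reference", base$pool),
    sprintf("P%d_%s_%g", base$pool, base$series, base$level)
  )
  design <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    cbind(base, replicate = r)
  }))
  design$excluded <- FALSE
  design <- design[order(design$pool, match(design$series, unique(per_pool$series)),
                         design$level, design$replicate), ]
  rownames(design) <- NULL
  design <- design[, c("sample_id", "pool", "series", "level", "unit",
                       "replicate", "is_reference", "excluded")]
  class(design) <- c("study_design", "data.frame")
  design
}

#' Mark design rows as excluded
#'
#' Mimics samples lost to failed infusions: excluded rows stay in the sheet
#' but are skipped by every downstream statistic.
#'
#' @param design A `study_design`.
#' @param sample_ids Sample ids to exclude (all their replicates).
#' @return The design with `excluded` set.
#' @export
exclude_samples <- function(design, sample_ids) {
  missing <- setdiff(sample_ids, design$sample_id)
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  design$excluded <- design$excluded | design$sample_id %in% sample_ids
  design
}

#' Read or write a study design as TSV
#'
#' @param path File path.
#' @param design A `study_design`.
#' @return `read_design()` returns a `study_design`; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "pool", "series", "level", "replicate")
  if (!all(required %in% names(design))) {
    stop("design file must have columns: ", paste(required, collapse = ", "))
  }
  if (!"is_reference" %in% names(design)) {
    design$is_reference <- design$series == "reference"
  }
  if (!"excluded" %in% names(design)) design$excluded <- FALSE
  if (!"unit" %in% names(design)) design$unit <- NA_character_
  class(design) <- c("study_design", "data.frame")
  design
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
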