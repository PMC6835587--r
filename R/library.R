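#' Construct a metabolite mass library
#'
#' A metabolite library is the annotation target: one row per neutral
#' metabolite with its monoisotopic mass, an optional group label, panel
#' membership and a flag for spiked stable isotope-labelled compounds (sILC).
#' Each entry is checked for reachability: at least one of the five default
#' adduct m/z values must fall inside the instrument scan window, otherwise
#' the entry can never be observed and is flagged.
#'
#' @param name Unique metabolite names.
#' @param monoisotopic_mass Neutral monoisotopic masses in Da (> 0).
#' @param group Optional group labels (recycled; `NA` allowed).
#' @param in_neuro_panel Logical; membership of the neurometabolic reporting
#'   panel.
#' @param is_silc Logical; `TRUE` for spiked stable isotope-labelled
#'   compounds, whose variation reflects purely technical (analysis)
#'   variability.
#' @param scan_window m/z window of the instrument, default `c(70, 600)`.
#' @return A data frame of class `metabolite_library` with columns `name`,
#'   `monoisotopic_mass`, `group`, `in_neuro_panel`, `is_silc`, `reachable`.
#' @export
metabolite_library <- function(name, monoisotopic_mass, group = NA_character_,
                               in_neuro_panel = FALSE, is_silc = FALSE,
                               scan_window = c(70, 600)) {
  n <- length(name)
  stopifnot(length(monoisotopic_mass) == n)
  if (n > 0 && anyDuplicated(name)) {
    stop("metabolite names must be unique")
  }
  if (n > 0 && any(!is.finite(monoisotopic_mass) | monoisotopic_mass <= 0)) {
    stop("all monoisotopic masses must be positive and finite")
  }
  lib <- data.frame(
    name = as.character(name),
    monoisotopic_mass = as.numeric(monoisotopic_mass),
    group = rep_len(as.character(group), n),
    in_neuro_panel = rep_len(as.logical(in_neuro_panel), n),
    is_silc = rep_len(as.logical(is_silc), n),
    stringsAsFactors = FALSE
  )
  rules <- adduct_rules()
  lib$reachable <- vapply(lib$monoisotopic_mass, function(m) {
    mz <- m + rules$shift
    any(mz >= scan_window[1] & mz <= scan_window[2])
  }, logical(1))
  class(lib) <- c("metabolite_library", "data.frame")
  lib
}

#' Generate a synthetic metabolite library
#'
#' Draws metabolite masses uniformly over a mass range, enforcing that every
#' adduct m/z channel is separated from every other channel of the same
#' polarity by more than `min_separation_ppm`, so that synthetic peak
#' matching at the default 2 ppm tolerance is unambiguous. The last `n_silc`
#' entries are flagged as spiked stable isotope-labelled compounds.
#'
#' @param n_metabolites Number of library entries (>= 0), sILCs included.
#' @param mass_range Two-element numeric interval inside (50, 600) Da.
#' @param n_silc Number of entries flagged as sILC (<= `n_metabolites`).
#' @param seed Integer seed; the result is deterministic for a fixed seed.
#' @param min_separation_ppm Minimum pairwise channel separation, default
#'   4 ppm (twice the default matching tolerance).
#' @return A [metabolite_library()].
#' @examples
#' lib <- generate_library(20, c(70, 600), n_silc = 4, seed = 1)
#' @export
generate_library <- function(n_metabolites, mass_range = c(70, 600), n_silc = 0,
                             seed = 1L, min_separation_ppm = 4) {
  stopifnot(n_metabolites >= 0, length(mass_range) == 2)
  if (!(mass_range[1] < mass_range[2])) stop("empty mass range")
  if (mass_range[1] <= 50 || mass_range[2] > 600) {
    stop("mass_range must lie within (50, 600) Da")
  }
  if (n_silc > n_metabolites) stop("n_silc cannot exceed n_metabolites")
  if (n_metabolites == 0) {
    return(metabolite_library(character(0), numeric(0)))
  }

  rules <- adduct_rules()
  masses <- withr::with_seed(seed, {
    accepted <- numeric(0)
    # accepted channel m/z per polarity, kept sorted for the separation check
    chan <- list(positive = numeric(0), negative = numeric(0))
    tries <- 0L
    while (length(accepted) < n_metabolites) {
      tries <- tries + 1L
      if (tries > 1000L * n_metabolites) {
        stop("could not place ", n_metabolites,
             " metabolites with the requested channel separation")
      }
      m <- stats::runif(1, mass_range[1], mass_range[2])
      ok <- TRUE
      for (pol in c("positive", "negative")) {
        mz <- m + rules$shift[rules$polarity == pol]
        existing <- chan[[pol]]
        if (length(existing)) {
          i <- findInterval(mz, existing)
          near <- cbind(existing[pmax(i, 1)], existing[pmin(i + 1, length(existing))])
          sep <- abs(mz - near) / mz * 1e6
          if (any(sep <= min_separation_ppm)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        accepted <- c(accepted, m)
        for (pol in c("positive", "negative")) {
          mz <- m + rules$shift[rules$polarity == pol]
          chan[[pol]] <- sort(c(chan[[pol]], mz))
        }
      }
    }
    accepted
  })

  n_plain <- n_metabolites - n_silc
  name <- c(sprintf("MET%04d", seq_len(n_plain)),
            if (n_silc > 0) sprintf("SILC%02d", seq_len(n_silc)))
  metabolite_library(
    name = name,
    monoisotopic_mass = masses,
    group = c(rep(NA_character_, n_plain), rep("silc", n_silc)),
    in_neuro_panel = FALSE,
    is_silc = c(rep(FALSE, n_plain), rep(TRUE, n_silc))
  )
}

#' Bundled cerebrospinal-fluid panel library
#'
#' A curated library of neurometabolic panel metabolites (grouped as amino
#' acids, neurotransmitters, purines/pyrimidines, organic acids, creatine
#' metabolism, vitamers, pterines, vitamin B6 vitamers, methyl donors) plus
#' the 17 spiked stable isotope-labelled compounds used as internal
#' standards. Masses are computed from molecular formulas with
#' [monoisotopic_mass()], including the isotope-label shifts of the sILCs.
#'
#' @return A [metabolite_library()].
#' @export
csf_panel_library <- function() {
  path <- system.file("extdata", "csf_panel.tsv", package = "dimstab",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  metabolite_library(
    name = raw$name,
    monoisotopic_mass = monoisotopic_mass(raw$formula, n_2h = raw$n_2h,
                                          n_13c = raw$n_13c, n_15n = raw$n_15n),
    group = raw$group,
    in_neuro_panel = raw$panel,
    is_silc = raw$silc
  )
}

#' Published-style QC reference values for the spiked internal standards
#'
#' Per-compound coefficient of variation over a full run, and the
#' per-compound median absolute variation at the most extreme level of each
#' storage series (freeze/thaw cycle 7; four months at -20 C; 168 h at
#' 5-8 C; 168 h at 18-22 C), for the 17 spiked stable isotope-labelled
#' compounds of a pooled-CSF stability experiment. Useful as input to
#' [qc_summary()] and [variability_band()] without re-running an instrument.
#'
#' @return A data frame with columns `compound`, `cv`, `mav_freeze_thaw`,
#'   `mav_minus20`, `mav_fridge`, `mav_room`.
#' @export
silc_qc_reference <- function() {
  path <- system.file("extdata", "silc_qc_reference.tsv", package = "dimstab",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read or write a metabolite library as TSV
#'
#' The interchange format has columns `name`, `mass`, `group`, `panel`,
#' `silc`; any mass list in this shape can be used as an annotation target.
#'
#' @param path File path.
#' @param library A [metabolite_library()].
#' @return `read_library()` returns a [metabolite_library()];
#'   `write_library()` returns `path` invisibly.
#' @export
read_library <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "mass")
  if (!all(required %in% names(raw))) {
    stop("library file must have columns: ", paste(required, collapse = ", "))
  }
  metabolite_library(
    name = raw$name,
    monoisotopic_mass = raw$mass,
    group = if ("group" %in% names(raw)) raw$group else NA_character_,
    in_neuro_panel = if ("panel" %in% names(raw)) raw$panel else FALSE,
    is_silc = if ("silc" %in% names(raw)) raw$silc else FALSE
  )
}

#' @rdname read_library
#' @export
write_library <- function(library, path) {
  out <- data.frame(name = library$name, mass = library$monoisotopic_mass,
                    group = library$group, panel = library$in_neuro_panel,
                    silc = library$is_silc)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
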