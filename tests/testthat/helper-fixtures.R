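# Small builders shared across test files.

# A tiny unambiguous library with exactly known masses.
tiny_library <- function(n = 6, n_silc = 2, seed = 11) {
  generate_library(n, mass_range = c(80, 550), n_silc = n_silc, seed = seed)
}

# Single-series grid: freeze/thaw cycles up to `n_levels`.
ft_grid <- function(n_levels = 7) {
  data.frame(series = "freeze_thaw", level = seq_len(n_levels), unit = "cycles")
}

# Brute-force all-pairs ppm matcher used as the annotation oracle.
brute_force_matches <- function(peaks, library, tol_ppm = 2,
                                rules = adduct_rules(),
                                scan_window = c(70, 600)) {
  peaks <- peaks[peaks$mz >= scan_window[1] & peaks$mz <= scan_window[2], ,
                 drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(library))) {
      for (k in seq_len(nrow(rules))) {
        if ("polarity" %in% names(peaks) &&
            peaks$polarity[i] != rules$polarity[k]) next
        t <- library$monoisotopic_mass[j] + rules$shift[k]
        ppm <- (peaks$mz[i] - t) / t * 1e6
        if (abs(ppm) <= tol_ppm) {
          out[[length(out) + 1L]] <- data.frame(
            sample_id = peaks$sample_id[i], replicate = peaks$replicate[i],
            mz = peaks$mz[i], intensity = peaks$intensity[i],
            metabolite = library$name[j], adduct = rules$adduct[k],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Canonical key for comparing match sets regardless of row order.
match_key <- function(m) {
  sort(paste(m$sample_id, m$replicate, signif(m$mz, 12), m$metabolite,
             m$adduct, sep = "|"))
}
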