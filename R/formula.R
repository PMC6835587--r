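# Monoisotopic atomic masses (CODATA/AME values, Da). Restricted to elements
# that occur in the small-molecule metabolome covered here.
.element_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069,
  Cl = 34.96885271,
  Na = 22.98976928,
  K = 38.9637064864
)

# Mass increments for common stable-isotope labels relative to the light
# isotope: 2H for 1H, 13C for 12C, 15N for 14N.
.label_shifts <- c(
  `2H` = 1.00627675,
  `13C` = 1.0033548378,
  `15N` = 0.9970349
)

#' Monoisotopic mass from a molecular formula
#'
#' Computes the neutral monoisotopic mass of a molecular formula such as
#' `"C6H12O6"`, optionally with stable-isotope labels (`n_2h` deuteriums,
#' `n_13c` carbon-13 and `n_15n` nitrogen-15 substitutions) as used for
#' spiked internal standards.
#'
#' @param formula Character vector of Hill-style molecular formulas
#'   (element symbols each followed by an optional count).
#' @param n_2h,n_13c,n_15n Number of 2H / 13C / 15N substitutions (recycled).
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C2H5NO2")                 # glycine, 75.032028
#' monoisotopic_mass("C2H5NO2", n_13c = 2, n_15n = 1) # labelled glycine
#' @export
monoisotopic_mass <- function(formula, n_2h = 0L, n_13c = 0L, n_15n = 0L) {
  stopifnot(is.character(formula))
  n <- length(formula)
  args <- data.frame(n_2h = rep_len(n_2h, n), n_13c = rep_len(n_13c, n),
                     n_15n = rep_len(n_15n, n))
  vapply(seq_len(n), function(i) {
    f <- formula[[i]]
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (!nzchar(f) || paste(tokens, collapse = "") != f) {
      stop("cannot parse molecular formula: '", f, "'")
    }
    elems <- sub("[0-9]*$", "", tokens)
    counts <- as.integer(sub("^[A-Za-z]+", "", tokens))
    counts[is.na(counts)] <- 1L
    unknown <- setdiff(elems, names(.element_masses))
    if (length(unknown)) {
      stop("formula '", f, "' contains unsupported element(s): ",
           paste(unknown, collapse = ", "))
    }
    mass <- sum(.element_masses[elems] * counts)
    mass +
      args$n_2h[i] * .label_shifts[["2H"]] +
      args$n_13c[i] * .label_shifts[["13C"]] +
      args$n_15n[i] * .label_shifts[["15N"]]
  }, numeric(1))
}
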