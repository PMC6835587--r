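#' Default adduct rules for singly charged small-molecule ions
#'
#' Direct-infusion metabolomics annotation in this package considers five ion
#' species per neutral metabolite: deprotonated and protonated molecular ions
#' (\eqn{[M-H]^-}, \eqn{[M+H]^+}) and the sodium, potassium and chloride
#' adducts (\eqn{[M+Na]^+}, \eqn{[M+K]^+}, \eqn{[M+Cl]^-}). Mass shifts are
#' monoisotopic and include the electron mass, so the observed m/z of a singly
#' charged ion is the neutral monoisotopic mass plus the shift.
#'
#' @return A data frame with columns `adduct` (label), `shift` (Da, signed)
#'   and `polarity` (`"positive"` or `"negative"`).
#' @examples
#' adduct_rules()
#' @export
adduct_rules <- function() {
  data.frame(
    adduct   = c("[M+H]+", "[M-H]-", "[M+Na]+", "[M+K]+", "[M+Cl]-"),
    shift    = c(1.007276, -1.007276, 22.989222, 38.963158, 34.969401),
    polarity = c("positive", "negative", "positive", "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of a metabolite under an adduct rule
#'
#' @param monoisotopic_mass Neutral monoisotopic mass in Da; must be positive.
#' @param adduct Adduct label, one of the labels in [adduct_rules()], or a
#'   single row of an adduct-rule data frame.
#' @param rules Adduct rule table; defaults to [adduct_rules()].
#' @return Theoretical m/z in Da (singly charged assumed). Vectorised over
#'   `monoisotopic_mass`.
#' @examples
#' compute_adduct_mz(75.032028, "[M+H]+") # glycine, protonated
#' @export
compute_adduct_mz <- function(monoisotopic_mass, adduct, rules = adduct_rules()) {
  stopifnot(is.numeric(monoisotopic_mass), all(monoisotopic_mass > 0))
  if (is.data.frame(adduct)) {
    shift <- adduct$shift
  } else {
    idx <- match(adduct, rules$adduct)
    if (anyNA(idx)) {
      stop("unknown adduct label: ", paste(adduct[is.na(idx)], collapse = ", "))
    }
    shift <- rules$shift[idx]
  }
  monoisotopic_mass + shift
}
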