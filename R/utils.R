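#' Round half away from zero
#'
#' Decimal rounding where ties go up (0.05 -> 0.1), matching the convention
#' used in the published per-family percentage tables. Base R's `round()`
#' rounds half to even, which disagrees with printed values such as
#' 3/359 = 0.8357... -> 0.8 but 6/359 = 1.6713... -> 1.7.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' The twelve plant lectin families
#'
#' Canonical family labels, alphabetical: ABA, amaranthin, CRA, cyanovirin,
#' EUL, GNA, hevein, jacalin, legume, LysM, Nictaba, ricin B. Families are
#' defined by their carbohydrate recognition domain (CRD).
#'
#' @return character vector of length 12.
#' @export
lectin_family_names <- function() {
  c("ABA", "amaranthin", "CRA", "cyanovirin", "EUL", "GNA",
    "hevein", "jacalin", "legume", "LysM", "Nictaba", "ricin B")
}

# collapse a character vector for an error message, capped
.id_list <- function(x, max = 5) {
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
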