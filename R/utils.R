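#' Canonical amino-acid alphabet
#'
#' The twenty one-letter amino-acid codes, in alphabetical order. All
#' sequences, profiles and scoring matrices in the package are defined over
#' this alphabet; `-` is accepted only as an alignment gap.
#'
#' @return A character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

PHOS_ACCEPTORS <- c("S", "T", "Y")

is_canonical_aa <- function(x) x %in% aa_alphabet()

#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed percentages in variant
#' reports conventionally round half up (13.0890 -> 13.09 at two decimals).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# lower-median convention: for even counts take the lower of the two middle
# order statistics, so the result is always an observed value (deterministic)
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[[floor((n + 1) / 2)]]
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

abort_phos <- function(msg, class) {
  rlang::abort(msg, class = c(class, "phosimpact_error"))
}
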