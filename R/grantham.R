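# Published physico-chemical side-chain properties (composition c,
# polarity p, molecular volume v) underlying the Grantham distance.
grantham_properties <- function() {
  data.frame(
    aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0.00, 0.39, 0.71, 0.00, 0.00, 0.74, 0.00, 0.00,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0.00, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE
  )
}

GRANTHAM_ALPHA <- 1.833
GRANTHAM_BETA <- 0.1018
GRANTHAM_GAMMA <- 0.000399
GRANTHAM_RHO <- 50.723

grantham_metric <- function(dc, dp, dv) {
  GRANTHAM_RHO * sqrt(GRANTHAM_ALPHA * dc^2 + GRANTHAM_BETA * dp^2 +
                        GRANTHAM_GAMMA * dv^2)
}

#' Grantham distance between two residues
#'
#' The classical biochemical distance
#' \deqn{D = \rho\,[\alpha (c_a-c_b)^2 + \beta (p_a-p_b)^2 +
#'   \gamma (v_a-v_b)^2]^{1/2}}
#' over side-chain composition, polarity and volume, with the published
#' constants (\eqn{\alpha=1.833}, \eqn{\beta=0.1018},
#' \eqn{\gamma=0.000399}, \eqn{\rho=50.723}). Symmetric, zero on the
#' diagonal; the unrounded value is returned (the familiar table rounds to
#' integers, e.g. L–I = 5, R–K = 26).
#'
#' @param a,b character vectors of canonical one-letter residues (recycled).
#' @return Numeric vector of distances.
#' @examples
#' round(grantham_distance("L", "I"))
#' @export
grantham_distance <- function(a, b) {
  props <- grantham_properties()
  ia <- match(a, props$aa)
  ib <- match(b, props$aa)
  if (anyNA(ia) || anyNA(ib)) {
    abort_phos("non-canonical residue in grantham_distance", "phos_validation_error")
  }
  grantham_metric(props$c[ia] - props$c[ib],
                  props$p[ia] - props$p[ib],
                  props$v[ia] - props$v[ib])
}

#' Grantham variation and deviation for an alignment column
#'
#' `gv` measures the biochemical spread of the residues observed at an
#' alignment position: the Grantham-style metric applied to the ranges
#' (max minus min) of composition, polarity and volume across the observed
#' residues. `gd` measures how far the variant residue falls outside that
#' observed range box: zero when each of its components lies within the
#' observed range (in particular whenever the variant residue itself occurs
#' in the column), otherwise the Grantham-style distance from the variant
#' to the nearest point of the box.
#'
#' @param msa a `phos_msa` from [read_msa()] or [make_msa()].
#' @param column alignment column index.
#' @param alt variant residue (one letter).
#' @return A list with numeric elements `gv` and `gd`.
#' @export
gv_gd <- function(msa, column, alt) {
  obs <- msa_column(msa, column)
  obs <- obs[obs != "-"]
  if (!length(obs)) abort_phos("all-gap column", "phos_degenerate_column")
  props <- grantham_properties()
  io <- match(obs, props$aa)
  if (anyNA(io)) abort_phos("non-canonical residue in column", "phos_validation_error")
  ia <- match(alt, props$aa)
  if (is.na(ia)) abort_phos("non-canonical alt residue", "phos_validation_error")
  rng <- function(x) range(x)
  cr <- rng(props$c[io]); pr <- rng(props$p[io]); vr <- rng(props$v[io])
  gv <- grantham_metric(diff(cr), diff(pr), diff(vr))
  dist_to <- function(x, r) max(r[1] - x, 0, x - r[2])
  gd <- grantham_metric(dist_to(props$c[ia], cr),
                        dist_to(props$p[ia], pr),
                        dist_to(props$v[ia], vr))
  list(gv = gv, gd = gd)
}

#' Assign an A-GVGD class from (GV, GD)
#'
#' Classes C0 (neutral) through C65 (likely deleterious) from a decision
#' grid over Grantham variation and deviation. With the default grid, at an
#' invariant position (gv = 0) the class is the highest `Ck` whose GD
#' cutoff `k` is reached; observed variation attenuates the call (effective
#' GD is reduced by the GV excess over `gv_soft`), and a highly varied
#' position (`gv > gv_max`) is always C0. The class is therefore
#' non-decreasing in GD and non-increasing in GV.
#'
#' @param gv,gd non-negative numerics (vectorized).
#' @param thresholds grid as in [default_agvgd_thresholds()].
#' @return Character vector of classes.
#' @examples
#' agvgd_class(0, 70)
#' @export
agvgd_class <- function(gv, gd, thresholds = default_agvgd_thresholds()) {
  stopifnot(all(gv >= 0), all(gd >= 0))
  cutoffs <- sort(thresholds$gd_cutoffs)
  mapply(function(v, d) {
    if (v > thresholds$gv_max) return("C0")
    eff <- d - max(v - thresholds$gv_soft, 0)
    hit <- names(cutoffs)[eff >= cutoffs]
    if (length(hit)) hit[[length(hit)]] else "C0"
  }, gv, gd, USE.NAMES = FALSE)
}

#' Harmonize two conservation callers into one label
#'
#' Maps a tolerance-style call (`damaging` / `tolerated`) and a
#' PolyPhen-style call (`probably_damaging` / `possibly_damaging` /
#' `benign`) onto one label: both on the damaging side gives `damaging`;
#' both on the benign side gives `benign`; one of each gives
#' `likely_damaging`; a missing input on either side gives
#' `not_informative`. Both damaging-side second-caller grades are treated
#' identically.
#'
#' @param call_a character vector: `"damaging"`, `"tolerated"` or
#'   `"missing"` (`NA` is treated as missing).
#' @param call_b character vector: `"probably_damaging"`,
#'   `"possibly_damaging"`, `"benign"` or `"missing"`.
#' @return Character vector of harmonized labels.
#' @export
harmonize <- function(call_a, call_b) {
  call_a[is.na(call_a)] <- "missing"
  call_b[is.na(call_b)] <- "missing"
  stopifnot(all(call_a %in% c("damaging", "tolerated", "missing")),
            all(call_b %in% c("probably_damaging", "possibly_damaging",
                              "benign", "missing")))
  a_dmg <- call_a == "damaging"
  b_dmg <- call_b %in% c("probably_damaging", "possibly_damaging")
  out <- rep("not_informative", length(a_dmg))
  known <- call_a != "missing" & call_b != "missing"
  out[known & a_dmg & b_dmg] <- "damaging"
  out[known & !a_dmg & !b_dmg] <- "benign"
  out[known & (a_dmg != b_dmg)] <- "likely_damaging"
  out
}
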