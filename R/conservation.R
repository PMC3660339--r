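#' Read a multiple sequence alignment from aligned FASTA
#'
#' Rows must all have the same aligned length; residues are upper-cased and
#' `-` is the only gap character accepted. The reference row (the query
#' protein the variant coordinates refer to) is identified by name or
#' index.
#'
#' @param path aligned FASTA path.
#' @param reference reference row: an id or a 1-based index (default 1).
#' @return An object of class `phos_msa`: character matrix `rows`
#'   (sequences by columns), `ids`, `reference_index`, `ncol`.
#' @export
read_msa <- function(path, reference = 1L) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  new_msa(seqs, ids, reference)
}

new_msa <- function(seqs, ids = paste0("seq", seq_along(seqs)), reference = 1L) {
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    abort_phos("alignment rows differ in length", "phos_msa_error")
  }
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  ok <- mat %in% c(aa_alphabet(), "-")
  if (!all(ok)) {
    abort_phos("alignment contains characters outside the alphabet plus '-'",
               "phos_msa_error")
  }
  ref <- if (is.character(reference)) match(reference, ids) else as.integer(reference)
  if (is.na(ref) || ref < 1L || ref > nrow(mat)) {
    abort_phos("reference row not found in alignment", "phos_msa_error")
  }
  structure(list(rows = mat, ids = ids, reference_index = ref,
                 ncol = ncol(mat)),
            class = "phos_msa")
}

#' @export
print.phos_msa <- function(x, ...) {
  cat(sprintf("<phos_msa> %d sequences x %d columns (reference: %s)\n",
              nrow(x$rows), x$ncol, x$ids[[x$reference_index]]))
  invisible(x)
}

msa_column <- function(msa, column) {
  if (column < 1L || column > msa$ncol) {
    abort_phos("alignment column out of range", "phos_range_error")
  }
  msa$rows[, column]
}

#' Map a 1-based residue position to its alignment column
#'
#' Positions count non-gap residues of the reference row.
#'
#' @param msa a `phos_msa`.
#' @param position residue position in the ungapped reference sequence.
#' @return The alignment column index.
#' @export
msa_column_of_position <- function(msa, position) {
  ref <- msa$rows[msa$reference_index, ]
  nongap <- which(ref != "-")
  if (position < 1L || position > length(nongap)) {
    abort_phos("position beyond ungapped reference length", "phos_range_error")
  }
  nongap[[position]]
}

#' Residue frequency profile of an alignment column
#'
#' `p(aa) = (count(aa) + pseudocount) / (non-gap count + 20 * pseudocount)`;
#' gaps are excluded from the counts. The vector sums to 1. An all-gap
#' column is a degenerate-column error.
#'
#' @param msa a `phos_msa`.
#' @param column column index.
#' @param pseudocount non-negative pseudocount.
#' @return A named probability vector over the 20 residues.
#' @export
column_profile <- function(msa, column, pseudocount = 0.1) {
  col <- msa_column(msa, column)
  col <- col[col != "-"]
  if (!length(col)) abort_phos("all-gap column", "phos_degenerate_column")
  counts <- table(factor(col, levels = aa_alphabet()))
  p <- (as.numeric(counts) + pseudocount) / (length(col) + 20 * pseudocount)
  stats::setNames(p, aa_alphabet())
}

#' Tolerance call for a substitution
#'
#' The alternate residue's column probability is normalized by the column
#' maximum; a substitution is called `damaging` when this normalized
#' probability falls below `config$tolerance_cutoff`. This is a plain
#' pseudocount-profile caller in the spirit of alignment-tolerance tools
#' such as SIFT (which uses richer Dirichlet-mixture regularizers); it is a
#' transparent stand-in, and recorded calls can be replayed instead where
#' exact published output matters.
#'
#' @param msa a `phos_msa`.
#' @param variant one-row variant tibble (position, alt_aa).
#' @param config a [pipeline_config()].
#' @return A list: `call` (`"damaging"` / `"tolerated"`),
#'   `normalized_probability`, `column`.
#' @export
tolerance_call <- function(msa, variant, config = pipeline_config()) {
  column <- msa_column_of_position(msa, variant$position[[1]])
  p <- column_profile(msa, column, config$pseudocount)
  np <- p[[variant$alt_aa[[1]]]] / max(p)
  list(call = if (np < config$tolerance_cutoff) "damaging" else "tolerated",
       normalized_probability = np,
       column = column)
}

#' Per-column information content and median conservation
#'
#' Each non-all-gap column's information content is
#' `R = log2(20) - H` where `H` is the Shannon entropy of the column
#' profile; `R` ranges from 0 (uniform column) to `log2 20 ~ 4.32` bits
#' (invariant column, zero pseudocount). The alignment's median
#' conservation is the lower median of `R` over those columns, and the
#' alignment is `informative` when the median lies inside
#' `config$median_conservation_range` — tolerance calls from alignments
#' outside that window are flagged unreliable.
#'
#' @param msa a `phos_msa` with at least two rows.
#' @param config a [pipeline_config()].
#' @param pseudocount profile pseudocount; defaults to the config value.
#' @return A list: `score` (median bits), `informative`, `per_column`
#'   (numeric vector of R values, NA for all-gap columns).
#' @export
median_conservation <- function(msa, config = pipeline_config(),
                                pseudocount = config$pseudocount) {
  if (nrow(msa$rows) < 2L) {
    abort_phos("conservation undefined for a single-row alignment",
               "phos_msa_error")
  }
  per_col <- vapply(seq_len(msa$ncol), function(j) {
    col <- msa$rows[, j]
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    counts <- table(factor(col, levels = aa_alphabet()))
    p <- (as.numeric(counts) + pseudocount) / (length(col) + 20 * pseudocount)
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    log2(20) - h
  }, numeric(1))
  score <- lower_median(per_col[!is.na(per_col)])
  rng <- config$median_conservation_range
  list(score = score,
       informative = !is.na(score) && score >= rng[1] && score <= rng[2],
       per_column = per_col)
}

#' Full conservation work-up for a set of variants
#'
#' For each variant: the tolerance call and normalized probability, the
#' alignment's median conservation and informativeness, Grantham GV/GD at
#' the variant's column, the A-GVGD class, and the harmonized label. The
#' second caller slot takes either recorded calls (a named character vector
#' of PolyPhen-style calls by token) or, when `second_caller = "gd_proxy"`,
#' a clearly synthetic proxy that grades `gd >= 65` as probably damaging —
#' intended only for generated data, never a substitute for a real
#' structure-based predictor. Columns with fewer than
#' `config$min_column_residues` non-gap residues yield `not_informative`.
#'
#' @param msa a `phos_msa`.
#' @param variants variant tibble.
#' @param config a [pipeline_config()].
#' @param second_caller `"none"`, `"gd_proxy"`, or a named character vector
#'   of recorded calls keyed by variant token.
#' @return A tibble with one row per variant: `token`, `tolerance_call`,
#'   `normalized_probability`, `median_conservation`, `informative`, `gv`,
#'   `gd`, `agvgd_class`, `second_call`, `harmonized`.
#' @export
conservation_profile <- function(msa, variants, config = pipeline_config(),
                                 second_caller = "none") {
  med <- median_conservation(msa, config)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    column <- msa_column_of_position(msa, v$position[[1]])
    col <- msa_column(msa, column)
    n_obs <- sum(col != "-")
    tol <- tolerance_call(msa, v, config)
    gg <- gv_gd(msa, column, v$alt_aa[[1]])
    cls <- agvgd_class(gg$gv, gg$gd, config$agvgd_thresholds)
    second <- if (is.character(second_caller) && length(second_caller) == 1 &&
                  second_caller %in% c("none", "gd_proxy")) {
      if (second_caller == "gd_proxy") {
        if (gg$gd >= 65) "probably_damaging" else "benign"
      } else "missing"
    } else {
      sc <- second_caller[[v$token]]
      if (is.null(sc) || is.na(sc)) "missing" else sc
    }
    call_a <- if (!med$informative || n_obs < config$min_column_residues)
      "missing" else tol$call
    tibble::tibble(
      token = v$token,
      tolerance_call = tol$call,
      normalized_probability = tol$normalized_probability,
      median_conservation = med$score,
      informative = med$informative && n_obs >= config$min_column_residues,
      gv = gg$gv, gd = gg$gd,
      agvgd_class = cls,
      second_call = second,
      harmonized = harmonize(call_a, second)
    )
  })
  dplyr::bind_rows(rows)
}

#' Read recorded conservation calls (fixture replay)
#'
#' TSV with columns `variant`, `sift_call`, `polyphen_call`, `harmonized`,
#' `agvgd_class`; per-caller columns may be reconstructions consistent with
#' a published harmonized label (the file header should say so).
#'
#' @param path TSV file path.
#' @return A tibble keyed by `token`.
#' @export
read_conservation_fixture <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  tibble::tibble(
    token = as.character(raw$variant),
    sift_call = as.character(raw$sift_call),
    polyphen_call = as.character(raw$polyphen_call),
    harmonized = as.character(raw$harmonized),
    agvgd_class = as.character(raw$agvgd_class)
  )
}
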