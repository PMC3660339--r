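ALTERING_CATEGORIES <- c("abolishing", "abolishing_and_creating", "creating")

#' Summarize verdicts into the stratified report
#'
#' Counts distinct variants whose category is abolishing, abolishing and
#' creating, or creating ("altering"); rescued variants and unaffected
#' variants are excluded. Counts are stratified into variants affecting
#' biologically characterized sites versus uncharacterized ones (a variant
#' with no abolished characterized site falls in the uncharacterized
#' stratum). Percentages are `100 * count / n_analyzed`, reported at full
#' precision and rounded half-up at `config$percent_decimals`. When a
#' conservation table is supplied (columns `token`, `harmonized`,
#' `agvgd_class`), per-stratum tallies of harmonized labels and of A-GVGD
#' classes above C0 are added for the altering variants.
#'
#' @param verdicts a `phos_verdicts` tibble (or the re-read per-variant
#'   report with columns `protein`/`protein_id`, `mutation`/`token`,
#'   `category`, `direct_acceptor_hit`, `affects_characterized`).
#' @param conservation optional conservation tibble aligned by token.
#' @param totals named integer vector: the number of variants analysed per
#'   protein (the denominator); defaults to the distinct variants present.
#' @param config a [pipeline_config()].
#' @return A list of class `phos_summary` with elements `per_protein`
#'   (tibble), `strata` (tibble), `conservation` (tibble or NULL),
#'   `totals`.
#' @export
summarize_verdicts <- function(verdicts, conservation = NULL, totals = NULL,
                               config = pipeline_config()) {
  v <- as_verdict_frame(verdicts)
  proteins <- sort(unique(c(names(totals), v$protein_id)))
  if (is.null(totals)) {
    totals <- vapply(proteins, function(p) sum(v$protein_id == p), integer(1))
  }
  d <- config$percent_decimals
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

  per_protein <- dplyr::bind_rows(lapply(proteins, function(p) {
    vp <- v[v$protein_id == p, ]
    alt <- vp[vp$category %in% ALTERING_CATEGORIES, ]
    n_total <- if (p %in% names(totals)) totals[[p]] else nrow(vp)
    tibble::tibble(
      protein = p,
      n_analyzed = as.integer(n_total),
      n_altering = nrow(alt),
      pct_altering = pct(nrow(alt), n_total),
      pct_altering_printed = round_half_up(pct(nrow(alt), n_total), d),
      n_characterized_altering = sum(alt$affects_characterized),
      n_uncharacterized_altering = sum(!alt$affects_characterized),
      n_rescued = sum(vp$category == "rescued"),
      n_abolishing = sum(vp$category == "abolishing"),
      n_abolishing_and_creating = sum(vp$category == "abolishing_and_creating"),
      n_creating = sum(vp$category == "creating"),
      n_none = as.integer(n_total) - nrow(vp) + sum(vp$category == "none"),
      direct_acceptor_hits = sum(alt$direct_acceptor_hit)
    )
  }))

  strata <- v |>
    dplyr::filter(.data$category %in% ALTERING_CATEGORIES) |>
    dplyr::mutate(stratum = ifelse(.data$affects_characterized,
                                   "characterized", "uncharacterized")) |>
    dplyr::group_by(.data$protein_id, .data$stratum) |>
    dplyr::summarise(
      n_altering = dplyr::n(),
      direct_acceptor_hits = sum(.data$direct_acceptor_hit),
      .groups = "drop"
    ) |>
    dplyr::rename(protein = "protein_id")

  cons_tally <- NULL
  if (!is.null(conservation)) {
    cons_tally <- v |>
      dplyr::filter(.data$category %in% ALTERING_CATEGORIES) |>
      dplyr::mutate(stratum = ifelse(.data$affects_characterized,
                                     "characterized", "uncharacterized")) |>
      dplyr::inner_join(conservation, by = "token") |>
      dplyr::group_by(.data$protein_id, .data$stratum) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_damaging_side = sum(.data$harmonized %in%
                                c("damaging", "likely_damaging")),
        n_benign = sum(.data$harmonized == "benign"),
        n_above_c0 = sum(.data$agvgd_class != "C0"),
        n_c0 = sum(.data$agvgd_class == "C0"),
        pct_damaging_side = pct(.data$n_damaging_side, .data$n),
        pct_above_c0 = pct(.data$n_above_c0, .data$n),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        pct_damaging_side_printed = round_half_up(.data$pct_damaging_side, d),
        pct_above_c0_printed = round_half_up(.data$pct_above_c0, d)
      ) |>
      dplyr::rename(protein = "protein_id")
  }

  structure(list(per_protein = per_protein, strata = strata,
                 conservation = cons_tally,
                 totals = stats::setNames(as.integer(totals), proteins)),
            class = "phos_summary")
}

# accept either live verdicts or the flat re-read report
as_verdict_frame <- function(verdicts) {
  v <- tibble::as_tibble(verdicts)
  if (!"protein_id" %in% names(v) && "protein" %in% names(v)) {
    v$protein_id <- v$protein
  }
  if (!"token" %in% names(v) && "mutation" %in% names(v)) {
    v$token <- v$mutation
  }
  needed <- c("protein_id", "token", "category", "direct_acceptor_hit",
              "affects_characterized")
  missing <- setdiff(needed, names(v))
  if (length(missing)) {
    abort_phos(paste0("verdict table missing column(s): ",
                      paste(missing, collapse = ", ")), "phos_usage_error")
  }
  v
}

#' @export
print.phos_summary <- function(x, ...) {
  cat("<phos_summary>\n")
  print(x$per_protein)
  invisible(x)
}

#' Count variants that directly substitute a phosphoacceptor
#'
#' Distinct variants whose position coincides with a catalogued site
#' position, optionally restricted to altering variants of one stratum.
#'
#' @param verdicts a `phos_verdicts` tibble.
#' @param characterized `TRUE` / `FALSE` to restrict to the
#'   (un)characterized stratum, or `NULL` for all.
#' @param altering_only count only altering-category variants (default).
#' @return Integer count.
#' @export
count_direct_acceptor_hits <- function(verdicts, characterized = NULL,
                                       altering_only = TRUE) {
  v <- as_verdict_frame(verdicts)
  if (altering_only) v <- v[v$category %in% ALTERING_CATEGORIES, ]
  if (!is.null(characterized)) {
    v <- v[v$affects_characterized == characterized, ]
  }
  sum(v$direct_acceptor_hit)
}

#' Count variants abolishing binding of given kinases
#'
#' Distinct variants with at least one site comparison whose lost kinase
#' set intersects `kinase_names`.
#'
#' @param verdicts a `phos_verdicts` tibble (live, or flat with a
#'   semicolon-joined `lost_kinases` column).
#' @param kinase_names character vector of kinase names.
#' @return Integer count.
#' @export
count_kinase_abolitions <- function(verdicts, kinase_names) {
  if (!length(kinase_names)) return(0L)
  v <- tibble::as_tibble(verdicts)
  lost <- if ("deltas" %in% names(v)) {
    lapply(v$deltas, function(d) unique(unlist(d$lost)))
  } else {
    strsplit(dplyr::coalesce(v$lost_kinases, ""), ";", fixed = TRUE)
  }
  sum(vapply(lost, function(k) any(k %in% kinase_names), logical(1)))
}

#' Write the summary and per-variant reports
#'
#' Writes `summary.tsv` (one row per protein and stratum: count,
#' denominator, full-precision and printed-precision percentage) and
#' `variants.tsv` (the [write_verdicts()] schema) under `dir`.
#' Byte-deterministic for identical inputs and configuration.
#'
#' @param summary a `phos_summary`.
#' @param verdicts the `phos_verdicts` behind it.
#' @param dir output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(summary, verdicts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_rows <- summary$per_protein |>
    dplyr::transmute(
      protein = .data$protein,
      stratum = "all",
      count = .data$n_altering,
      denominator = .data$n_analyzed,
      percent_full = .data$pct_altering,
      percent_printed = .data$pct_altering_printed
    )
  strata_rows <- summary$strata |>
    dplyr::left_join(summary$per_protein[, c("protein", "n_analyzed")],
                     by = "protein") |>
    dplyr::transmute(
      protein = .data$protein,
      stratum = .data$stratum,
      count = .data$n_altering,
      denominator = .data$n_analyzed,
      percent_full = 100 * .data$count / .data$denominator,
      percent_printed = round_half_up(.data$percent_full, 2)
    )
  summary_path <- file.path(dir, "summary.tsv")
  variants_path <- file.path(dir, "variants.tsv")
  readr::write_tsv(dplyr::bind_rows(summary_rows, strata_rows), summary_path,
                   progress = FALSE)
  write_verdicts(verdicts, variants_path)
  invisible(c(summary = summary_path, variants = variants_path))
}

#' Read back a per-variant report
#'
#' Reads the `variants.tsv` written by [write_report()] /
#' [write_verdicts()]; the result can be fed to [summarize_verdicts()]
#' again.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_verdict_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
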