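#' Read a recorded-prediction (replay) table
#'
#' The replay backend substitutes recorded kinase predictions for live
#' motif scoring, so analyses that were originally run through an external
#' predictor can be reproduced exactly. The TSV has columns `protein`,
#' `variant` (p.-style token), `state` (`wt` or `mut`), `site` (1-based
#' position: the catalogued site, or the altered residue for created
#' sites), `kinase`, and `bound` (`TRUE` for a reliable prediction, `FALSE`
#' for a prediction recorded as having fallen below the reliability
#' threshold). Wild-type and mutant predictions are recorded in the context
#' of each variant query, mirroring how per-variant predictor output is
#' matched against the corresponding wild-type run.
#'
#' @param path TSV file path.
#' @return A tibble of class `phos_replay`.
#' @export
read_replay_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  needed <- c("protein", "variant", "state", "site", "kinase", "bound")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort_phos(paste0("replay table missing column(s): ",
                      paste(missing, collapse = ", ")), "phos_parse_error")
  }
  out <- tibble::tibble(
    protein = as.character(raw$protein),
    variant = as.character(raw$variant),
    state = tolower(as.character(raw$state)),
    site = as.integer(raw$site),
    kinase = as.character(raw$kinase),
    bound = as.logical(raw$bound)
  )
  if (!all(out$state %in% c("wt", "mut"))) {
    abort_phos("replay state must be 'wt' or 'mut'", "phos_parse_error")
  }
  class(out) <- c("phos_replay", class(out))
  out
}

#' Look up recorded predictions for a variant context
#'
#' Returns the kinases recorded for the given protein state at a site, with
#' nominal scores: `score_threshold + 1` for bound predictions and
#' `score_threshold - 1` for predictions recorded as sub-threshold. The
#' nominal scores are a declared convention of the replay backend, not
#' measured values. Querying a variant token absent from the table is a
#' lookup error; a known variant with nothing recorded at a site yields an
#' empty prediction set (no change was recorded there).
#'
#' @param replay a `phos_replay` table.
#' @param protein protein identifier.
#' @param variant variant token giving the query context.
#' @param state `"wt"` or `"mut"`.
#' @param site 1-based site position.
#' @param config a [pipeline_config()].
#' @return A tibble with columns `kinase`, `site_position`, `score`.
#' @export
replay_predictions <- function(replay, protein, variant, state, site,
                               config = pipeline_config()) {
  state <- match.arg(state, c("wt", "mut"))
  known <- replay$variant[replay$protein == protein]
  if (!variant %in% known) {
    abort_phos(paste0("no recorded predictions for ", protein, " ", variant),
               "phos_lookup_error")
  }
  rows <- replay[replay$protein == protein & replay$variant == variant &
                   replay$state == state & replay$site == site, ]
  thr <- config$score_threshold
  out <- tibble::tibble(
    kinase = rows$kinase,
    site_position = as.integer(rep(site, nrow(rows))),
    score = ifelse(rows$bound, thr + 1, thr - 1)
  )
  dplyr::arrange(out, dplyr::desc(.data$score), .data$kinase)
}
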