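#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the analysis conventions the pipeline implements: an
#' eleven-residue scoring window (five residues either side of the
#' phosphoacceptor), variants analysed when they fall in or within ten
#' residues of a catalogued site, a reliable-binding score cutoff of 5,
#' abolition of at least 80% of wild-type kinase binding equated with
#' complete loss of the motif, a 0.05 tolerance cutoff for damaging calls,
#' and a median-conservation reliability window of [2.75, 3.25] bits
#' around the 3.00 target.
#'
#' @param window_up residues upstream of the acceptor in the motif window.
#' @param window_down residues downstream of the acceptor.
#' @param selection_radius residues around a site within which a variant is
#'   analysed (inclusive distance).
#' @param score_threshold minimum reliable binding score (bits).
#' @param abolition_fraction fraction of lost wild-type kinases equated with
#'   complete abolition of the motif; in (0, 1].
#' @param tolerance_cutoff normalized-probability cutoff below which a
#'   substitution is called damaging.
#' @param median_conservation_target target median column information
#'   content (bits).
#' @param median_conservation_range closed interval of median conservation
#'   within which a tolerance call is considered informative.
#' @param pseudocount pseudocount added to profiles and matrix weights.
#' @param min_column_residues minimum non-gap residues for an informative
#'   alignment column.
#' @param agvgd_thresholds named list describing the (GV, GD) decision grid;
#'   see [agvgd_class()].
#' @param percent_decimals decimals for printed percentages.
#' @param family_rescue if `TRUE`, rescue may be satisfied by a kinase of the
#'   same family (requires `families`); default off, rescue requires the
#'   identical kinase name.
#' @param families optional named character vector mapping kinase name to
#'   family, used only when `family_rescue` is `TRUE`.
#'
#' @return A list of class `phos_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$abolition_fraction
#' @export
pipeline_config <- function(window_up = 5L,
                            window_down = 5L,
                            selection_radius = 10L,
                            score_threshold = 5,
                            abolition_fraction = 0.8,
                            tolerance_cutoff = 0.05,
                            median_conservation_target = 3.00,
                            median_conservation_range = c(2.75, 3.25),
                            pseudocount = 0.1,
                            min_column_residues = 3L,
                            agvgd_thresholds = default_agvgd_thresholds(),
                            percent_decimals = 2L,
                            family_rescue = FALSE,
                            families = NULL) {
  stopifnot(
    window_up >= 1, window_down >= 1, selection_radius >= 1,
    is.finite(score_threshold),
    abolition_fraction > 0, abolition_fraction <= 1,
    length(median_conservation_range) == 2,
    median_conservation_range[1] <= median_conservation_target,
    median_conservation_target <= median_conservation_range[2],
    pseudocount >= 0
  )
  structure(
    list(
      window_up = as.integer(window_up),
      window_down = as.integer(window_down),
      selection_radius = as.integer(selection_radius),
      score_threshold = score_threshold,
      abolition_fraction = abolition_fraction,
      tolerance_cutoff = tolerance_cutoff,
      median_conservation_target = median_conservation_target,
      median_conservation_range = as.numeric(median_conservation_range),
      pseudocount = pseudocount,
      min_column_residues = as.integer(min_column_residues),
      agvgd_thresholds = agvgd_thresholds,
      percent_decimals = as.integer(percent_decimals),
      family_rescue = isTRUE(family_rescue),
      families = families
    ),
    class = "phos_config"
  )
}

#' Default A-GVGD decision grid
#'
#' GD cutoffs for classes C15..C65, with a GV attenuation: above
#' `gv_soft` the effective GD is reduced by the GV excess, and above
#' `gv_max` (a highly varied position) every variant is classed C0. The grid
#' is deliberately plain data so alternative published grids can be supplied
#' through [pipeline_config()].
#'
#' @return A named list with elements `gd_cutoffs`, `gv_soft`, `gv_max`.
#' @export
default_agvgd_thresholds <- function() {
  list(
    gd_cutoffs = c(C15 = 15, C25 = 25, C35 = 35, C45 = 45, C55 = 55, C65 = 65),
    gv_soft = 61.3,
    gv_max = 122.4
  )
}

#' Read a pipeline configuration from a flat key: value file
#'
#' Lines are `key: value`; keys mirror [pipeline_config()] arguments
#' (`median_conservation_range` as two comma-separated numbers). `#` lines
#' and blank lines are ignored; unknown keys are an error.
#'
#' @param path file path.
#' @return A `phos_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), character(1))
  numeric_keys <- c(
    "window_up", "window_down", "selection_radius", "score_threshold",
    "abolition_fraction", "tolerance_cutoff", "median_conservation_target",
    "pseudocount", "min_column_residues", "percent_decimals"
  )
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[[i]]
    v <- vals[[i]]
    if (k %in% numeric_keys) {
      args[[k]] <- as.numeric(v)
    } else if (k == "median_conservation_range") {
      args[[k]] <- as.numeric(strsplit(v, ",")[[1]])
    } else if (k == "family_rescue") {
      args[[k]] <- toupper(v) %in% c("TRUE", "YES", "1")
    } else if (k == "predictor") {
      # carried through as an attribute; not a scoring parameter
      next
    } else {
      abort_phos(paste0("unknown configuration key: ", k), "phos_config_error")
    }
  }
  cfg <- do.call(pipeline_config, args)
  pred <- vals[keys == "predictor"]
  if (length(pred)) attr(cfg, "predictor") <- pred
  cfg
}

#' @export
print.phos_config <- function(x, ...) {
  cat("<phos_config>\n")
  for (k in setdiff(names(x), "agvgd_thresholds")) {
    v <- x[[k]]
    if (is.null(v)) next
    cat(sprintf("  %s: %s\n", k, paste(format(v), collapse = ", ")))
  }
  cat(sprintf("  agvgd gd cutoffs: %s (gv_soft %.1f, gv_max %.1f)\n",
              paste(x$agvgd_thresholds$gd_cutoffs, collapse = "/"),
              x$agvgd_thresholds$gv_soft, x$agvgd_thresholds$gv_max))
  invisible(x)
}
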