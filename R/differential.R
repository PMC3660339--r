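#' Compare wild-type and mutant predictions at one site
#'
#' Kinase sets are compared by name at the reliability threshold: a kinase
#' bound in the wild type whose mutant score falls below the threshold (or
#' disappears) counts as lost — loss is threshold-crossing, not
#' disappearance. The site's motif is called `abolished` when the lost
#' fraction of wild-type-bound kinases reaches `config$abolition_fraction`
#' (at least, not strictly greater); `weakened` when some but not enough are
#' lost; `strengthened` when nothing is lost and new kinases bind;
#' `unchanged` otherwise. New binders at the original site never compensate
#' for the loss of different kinases.
#'
#' @param wt,mut prediction tibbles (`kinase`, `score`) for the same site.
#' @param site one-row tibble with at least `position`; `characterized` and
#'   `acceptor` are carried through when present.
#' @param config a [pipeline_config()].
#' @return A one-row tibble: `site_position`, `site_characterized`,
#'   `n_wt_bound`, `lost`, `gained`, `retained` (list-columns of kinase
#'   names), `abolished_fraction`, `status`.
#' @export
compare_site <- function(wt, mut, site, config = pipeline_config()) {
  thr <- config$score_threshold
  wt_bound <- unique(wt$kinase[wt$score >= thr])
  mut_bound <- unique(mut$kinase[mut$score >= thr])
  lost <- setdiff(wt_bound, mut_bound)
  retained <- intersect(wt_bound, mut_bound)
  gained <- setdiff(mut_bound, wt_bound)
  frac <- if (length(wt_bound)) length(lost) / length(wt_bound) else NA_real_
  status <- if (!is.na(frac) && frac >= config$abolition_fraction) {
    "abolished"
  } else if (length(lost)) {
    "weakened"
  } else if (length(gained)) {
    "strengthened"
  } else {
    "unchanged"
  }
  tibble::tibble(
    site_position = as.integer(site$position[[1]]),
    site_characterized = if ("characterized" %in% names(site))
      isTRUE(site$characterized[[1]]) else NA,
    n_wt_bound = length(wt_bound),
    lost = list(sort(lost)),
    gained = list(sort(gained)),
    retained = list(sort(retained)),
    abolished_fraction = frac,
    status = status
  )
}

#' Find kinase sites created at the altered residue
#'
#' A substitution can itself introduce a phosphoacceptor. The mutant
#' protein is scanned at the variant position; a created site is emitted
#' iff the alternate residue is S, T or Y and at least one kinase scores at
#' or above the reliability threshold there.
#'
#' @param mut_protein one-row protein tibble carrying the substitution.
#' @param variant one-row variant tibble.
#' @param models list of [kinase_model()] objects.
#' @param config a [pipeline_config()].
#' @return A tibble (`position`, `residue`, `kinases` list-column), zero
#'   rows when nothing is created.
#' @export
find_created_sites <- function(mut_protein, variant, models,
                               config = pipeline_config()) {
  empty <- tibble::tibble(position = integer(), residue = character(),
                          kinases = list())
  alt <- variant$alt_aa[[1]]
  if (!alt %in% PHOS_ACCEPTORS) return(empty)
  preds <- scan_site(mut_protein, variant$position[[1]], models, config)
  if (!nrow(preds)) return(empty)
  tibble::tibble(position = variant$position[[1]], residue = alt,
                 kinases = list(sort(unique(preds$kinase))))
}

#' Assign a variant its final category
#'
#' Categories partition the outcome space:
#' * `rescued` — at least one abolished site, and every abolished site's
#'   entire lost kinase set re-binds (same kinase names, or same family when
#'   `config$family_rescue` is on) at a site created at the altered residue.
#' * `abolishing` — at least one abolished site and no created site.
#' * `abolishing_and_creating` — abolished site(s) plus created site(s)
#'   whose kinases do not cover the lost set.
#' * `creating` — created site(s), nothing abolished.
#' * `none` — otherwise.
#'
#' @param deltas tibble of site comparisons from [compare_site()].
#' @param created tibble from [find_created_sites()].
#' @param config a [pipeline_config()].
#' @return A single category string.
#' @export
classify_variant <- function(deltas, created, config = pipeline_config()) {
  abolished <- if (nrow(deltas)) deltas[deltas$status == "abolished", ] else deltas
  any_abolished <- nrow(abolished) > 0
  any_created <- nrow(created) > 0
  created_kin <- if (any_created) unique(unlist(created$kinases)) else character()
  as_family <- function(k) {
    if (config$family_rescue && !is.null(config$families)) {
      fam <- config$families[k]
      ifelse(is.na(fam), k, fam)
    } else k
  }
  covers <- function(lost) all(as_family(lost) %in% as_family(created_kin))
  if (any_abolished && any_created &&
      all(vapply(abolished$lost, covers, logical(1)))) {
    return("rescued")
  }
  if (any_abolished && !any_created) return("abolishing")
  if (any_abolished && any_created) return("abolishing_and_creating")
  if (any_created) return("creating")
  "none"
}

#' Run the wild-type vs mutant differential over a variant set
#'
#' For each distinct substitution (repeat reports collapsed, frequencies
#' summed), compares predictions at every catalogued phosphosite within the
#' selection radius, scans the altered residue for created sites, and
#' assigns the final category. Two predictor backends are available:
#' `pssm` scores motif windows live against a kinase model library and
#' requires `protein` and `models`; `replay` looks recorded predictions up
#' in a [read_replay_table()] fixture and needs no sequence.
#'
#' With `keep_unpaired = TRUE` (the default for replay), variants with no
#' catalogued site within the radius are still processed — their site
#' comparisons are empty but a created site can still be found. This
#' matters when only a partial site catalog is available; with the `pssm`
#' backend the stated selection rule applies and unpaired variants are
#' dropped.
#'
#' @param variants variant tibble.
#' @param sites phosphosite tibble.
#' @param predictor `"pssm"` or `"replay"`.
#' @param config a [pipeline_config()].
#' @param protein one-row protein tibble (pssm backend).
#' @param models list of kinase models (pssm backend).
#' @param replay replay table (replay backend).
#' @param keep_unpaired keep variants with no site within the radius.
#' @return A tibble of class `phos_verdicts`, one row per distinct variant,
#'   ordered by protein, position, alternate residue: identity columns,
#'   `n_sites`, list-columns `deltas` and `created`, flattened
#'   `lost_kinases` / `created_kinases` (semicolon-joined),
#'   `max_abolished_fraction`, `direct_acceptor_hit`,
#'   `affects_characterized`, `category`.
#' @export
run_differential <- function(variants, sites,
                             predictor = c("pssm", "replay"),
                             config = pipeline_config(),
                             protein = NULL, models = NULL, replay = NULL,
                             keep_unpaired = NULL) {
  predictor <- match.arg(predictor)
  if (predictor == "pssm" && (is.null(protein) || is.null(models))) {
    abort_phos("pssm backend needs `protein` and `models`", "phos_usage_error")
  }
  if (predictor == "replay" && is.null(replay)) {
    abort_phos("replay backend needs a `replay` table", "phos_usage_error")
  }
  if (is.null(keep_unpaired)) keep_unpaired <- predictor == "replay"

  dv <- distinct_variants(variants)
  verdict_rows <- lapply(seq_len(nrow(dv)), function(i) {
    v <- dv[i, ]
    s <- sites[sites$protein_id == v$protein_id, ]
    near <- s[abs(s$position - v$position) <= config$selection_radius, ]
    if (!nrow(near) && !keep_unpaired) return(NULL)

    predict_at <- function(state, pos) {
      if (predictor == "replay") {
        replay_predictions(replay, v$protein_id, v$token, state, pos, config)
      } else {
        prot <- if (state == "wt") protein else apply_variant(protein, v)
        scan_site(prot, pos, models, config)
      }
    }

    empty_delta <- tibble::tibble(
      site_position = integer(), site_characterized = logical(),
      n_wt_bound = integer(), lost = list(), gained = list(),
      retained = list(), abolished_fraction = numeric(), status = character())
    deltas <- dplyr::bind_rows(c(list(empty_delta),
                                 lapply(seq_len(nrow(near)), function(j) {
      tryCatch(
        compare_site(predict_at("wt", near$position[[j]]),
                     predict_at("mut", near$position[[j]]),
                     near[j, ], config),
        phos_lookup_error = function(e) {
          abort_phos(paste0("for variant ", v$token, ": ", conditionMessage(e)),
                     "phos_lookup_error")
        }
      )
    })))

    created <- tibble::tibble(position = integer(), residue = character(),
                              kinases = list())
    if (v$alt_aa %in% PHOS_ACCEPTORS && !v$position %in% s$position) {
      if (predictor == "replay") {
        preds <- replay_predictions(replay, v$protein_id, v$token, "mut",
                                    v$position, config)
        preds <- preds[preds$score >= config$score_threshold, ]
        if (nrow(preds)) {
          created <- tibble::tibble(position = v$position, residue = v$alt_aa,
                                    kinases = list(sort(unique(preds$kinase))))
        }
      } else {
        created <- find_created_sites(apply_variant(protein, v), v, models, config)
      }
    }

    deltas_tbl <- deltas
    created_tbl <- created
    abol <- if (nrow(deltas_tbl)) {
      deltas_tbl[deltas_tbl$status == "abolished", ]
    } else deltas_tbl
    lost_all <- sort(unique(unlist(
      if (nrow(deltas_tbl)) deltas_tbl$lost else list())))
    max_frac <- if (nrow(deltas_tbl) &&
                    any(!is.na(deltas_tbl$abolished_fraction))) {
      max(deltas_tbl$abolished_fraction, na.rm = TRUE)
    } else NA_real_
    extra <- tibble::tibble(
      n_sites = nrow(near),
      deltas = list(deltas_tbl),
      created = list(created_tbl),
      lost_kinases = paste(lost_all, collapse = ";"),
      created_kinases = paste(sort(unique(unlist(created_tbl$kinases))),
                              collapse = ";"),
      max_abolished_fraction = max_frac,
      direct_acceptor_hit = v$position %in% s$position,
      affects_characterized = nrow(abol) > 0 &&
        any(abol$site_characterized %in% TRUE),
      category = classify_variant(deltas_tbl, created_tbl, config)
    )
    dplyr::bind_cols(v, extra)
  })
  template <- tibble::tibble(
    protein_id = character(), token = character(), ref_aa = character(),
    position = integer(), alt_aa = character(), cdna_label = character(),
    snp_id = character(), frequency = integer(), source = character(),
    n_sites = integer(), deltas = list(), created = list(),
    lost_kinases = character(), created_kinases = character(),
    max_abolished_fraction = numeric(), direct_acceptor_hit = logical(),
    affects_characterized = logical(), category = character())
  out <- dplyr::bind_rows(c(list(template), verdict_rows))
  out <- dplyr::arrange(out, .data$protein_id, .data$position, .data$alt_aa)
  class(out) <- c("phos_verdicts", class(out))
  out
}

#' Write the per-variant verdict table (TSV)
#'
#' One row per variant: token, affected sites, lost/gained kinase lists
#' (semicolon-joined), maximum abolished fraction, category, flags.
#' Byte-deterministic given identical inputs and configuration.
#'
#' @param verdicts a `phos_verdicts` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  flat <- tibble::tibble(
    protein = verdicts$protein_id,
    mutation = verdicts$token,
    frequency = verdicts$frequency,
    sites = vapply(verdicts$deltas, function(d)
      paste(d$site_position, collapse = ";"), character(1)),
    lost_kinases = verdicts$lost_kinases,
    gained_kinases = vapply(verdicts$deltas, function(d)
      paste(sort(unique(unlist(d$gained))), collapse = ";"), character(1)),
    created_kinases = verdicts$created_kinases,
    abolished_fraction = verdicts$max_abolished_fraction,
    category = verdicts$category,
    direct_acceptor_hit = verdicts$direct_acceptor_hit,
    affects_characterized = verdicts$affects_characterized
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
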