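#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a verdict set
#'
#' One row per (variant, affected site) with the comparison unpacked;
#' variants with no site comparison keep a single row with NA site fields.
#'
#' @param x a `phos_verdicts` tibble.
#' @param ... unused.
#' @return A long tibble.
#' @export
tidy.phos_verdicts <- function(x, ...) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    d <- x$deltas[[i]]
    base <- tibble::tibble(
      protein = x$protein_id[[i]], mutation = x$token[[i]],
      category = x$category[[i]],
      direct_acceptor_hit = x$direct_acceptor_hit[[i]]
    )
    if (is.null(d) || nrow(d) == 0) {
      dplyr::mutate(base, site_position = NA_integer_, status = NA_character_,
                    abolished_fraction = NA_real_,
                    lost = NA_character_, gained = NA_character_)
    } else {
      dplyr::bind_cols(
        base[rep(1L, nrow(d)), ],
        tibble::tibble(
          site_position = d$site_position,
          status = d$status,
          abolished_fraction = d$abolished_fraction,
          lost = vapply(d$lost, paste, character(1), collapse = ";"),
          gained = vapply(d$gained, paste, character(1), collapse = ";")
        )
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' One-row overview of a verdict set
#'
#' @param x a `phos_verdicts` tibble.
#' @param ... unused.
#' @return A one-row tibble: totals per category.
#' @export
glance.phos_verdicts <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_abolishing = sum(x$category == "abolishing"),
    n_abolishing_and_creating = sum(x$category == "abolishing_and_creating"),
    n_creating = sum(x$category == "creating"),
    n_rescued = sum(x$category == "rescued"),
    n_none = sum(x$category == "none"),
    n_altering = sum(x$category %in% ALTERING_CATEGORIES)
  )
}

#' Tidy a summary report
#'
#' @param x a `phos_summary`.
#' @param ... unused.
#' @return The per-protein tibble.
#' @export
tidy.phos_summary <- function(x, ...) x$per_protein

#' One-row overview of a summary report
#'
#' @param x a `phos_summary`.
#' @param ... unused.
#' @return A one-row tibble with overall counts.
#' @export
glance.phos_summary <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$per_protein),
    n_analyzed = sum(x$per_protein$n_analyzed),
    n_altering = sum(x$per_protein$n_altering),
    pct_altering = 100 * sum(x$per_protein$n_altering) /
      sum(x$per_protein$n_analyzed)
  )
}
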