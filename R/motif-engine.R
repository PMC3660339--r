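#' Construct a kinase recognition-motif model
#'
#' A kinase model is a position-specific probability matrix over a
#' contiguous offset range around the phosphoacceptor (offset 0), plus a
#' background distribution and the set of acceptor residues the kinase
#' phosphorylates. Scoring is log2 odds against the background, so a model
#' identical to its background scores 0 everywhere.
#'
#' @param name kinase name.
#' @param acceptors subset of `c("S","T","Y")`.
#' @param weights numeric matrix, rows = offsets (rownames are the integer
#'   offsets, must include 0, contiguous), columns = the 20 residues in
#'   [aa_alphabet()] order; each row a probability vector.
#' @param background probability vector over the 20 residues (default
#'   uniform 0.05).
#' @param family optional kinase family tag.
#' @param pseudocount added (scaled by the background) to any row containing
#'   a zero, then renormalized, so log-odds stay finite.
#' @return An object of class `kinase_model`.
#' @export
kinase_model <- function(name, acceptors, weights,
                         background = rep(1 / 20, 20),
                         family = NA_character_, pseudocount = 0.1) {
  aa <- aa_alphabet()
  stopifnot(is.matrix(weights), ncol(weights) == 20,
            all(acceptors %in% PHOS_ACCEPTORS), length(acceptors) >= 1)
  offsets <- as.integer(rownames(weights))
  if (anyNA(offsets) || !0L %in% offsets ||
      !identical(offsets, seq(min(offsets), max(offsets)))) {
    abort_phos("model offsets must be contiguous integers including 0",
               "phos_model_error")
  }
  colnames(weights) <- aa
  names(background) <- aa
  background <- background / sum(background)
  fix_row <- function(w) {
    if (any(w <= 0)) w <- w + pseudocount * background
    s <- sum(w)
    if (abs(s - 1) > 1e-6) {
      warning(sprintf("model '%s': row renormalized (sum %.8f)", name, s),
              call. = FALSE)
    }
    w / s
  }
  weights <- t(apply(weights, 1, fix_row))
  rownames(weights) <- offsets
  structure(
    list(name = name, family = family, acceptors = sort(acceptors),
         offsets = offsets, weights = weights, background = background),
    class = "kinase_model"
  )
}

#' @export
print.kinase_model <- function(x, ...) {
  cat(sprintf("<kinase_model %s> acceptors %s, offsets %d..%d\n",
              x$name, paste(x$acceptors, collapse = "/"),
              min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Extract the motif window around a position
#'
#' Returns the residues from `position - window_up` to
#' `position + window_down`, clipped at the protein termini;
#' `offsets` records which offsets survived clipping (the centre, offset 0,
#' is always present).
#'
#' @param protein one-row protein tibble.
#' @param position 1-based residue index.
#' @param config a [pipeline_config()].
#' @return An object of class `phos_window`: list with `center`, `residues`,
#'   `offsets`.
#' @export
extract_window <- function(protein, position, config = pipeline_config()) {
  len <- protein$length[[1]]
  if (position < 1L || position > len) {
    abort_phos(sprintf("position %d out of range 1..%d", position, len),
               "phos_range_error")
  }
  lo <- max(1L, position - config$window_up)
  hi <- min(len, position + config$window_down)
  structure(
    list(center = as.integer(position),
         residues = substring(protein$sequence[[1]], lo, hi),
         offsets = seq.int(lo - position, hi - position)),
    class = "phos_window"
  )
}

#' Apply a missense substitution to a protein
#'
#' Returns a copy of the protein whose sequence differs from the input at
#' exactly the variant position, holding the alternate residue there; the
#' input is not modified. The reference residue is re-checked so a mismatch
#' surfaces here even for unvalidated inputs.
#'
#' @param protein one-row protein tibble.
#' @param variant one-row variant tibble.
#' @return A one-row protein tibble carrying the substitution.
#' @export
apply_variant <- function(protein, variant) {
  stopifnot(nrow(variant) == 1L)
  pos <- variant$position[[1]]
  if (pos < 1L || pos > protein$length[[1]]) {
    abort_phos(sprintf("variant position %d beyond protein length %d",
                       pos, protein$length[[1]]), "phos_range_error")
  }
  found <- substring(protein$sequence[[1]], pos, pos)
  if (found != variant$ref_aa[[1]]) {
    abort_phos(sprintf("reference mismatch at %d: expected %s, found %s",
                       pos, variant$ref_aa[[1]], found),
               "phos_reference_mismatch")
  }
  mut <- protein
  s <- mut$sequence[[1]]
  substring(s, pos, pos) <- variant$alt_aa[[1]]
  mut$sequence[[1]] <- s
  mut
}

#' Score a motif window against a kinase model
#'
#' The score is the sum over offsets present in both the window and the
#' model of `log2(weight[offset, residue] / background[residue])`, in bits.
#' Offsets clipped by a terminus contribute zero (no padding residue is
#' invented), keeping scores comparable near termini. If the window's
#' centre residue is not one of the model's acceptors the function returns
#' `NA_real_` — a not-an-acceptor signal distinct from any low score.
#'
#' @param window a `phos_window` from [extract_window()].
#' @param model a [kinase_model()].
#' @return The log-odds score in bits, or `NA_real_` for a non-acceptor
#'   centre.
#' @export
score_window <- function(window, model) {
  res <- seq_chars(window$residues)
  center <- res[[match(0L, window$offsets)]]
  if (!center %in% model$acceptors) return(NA_real_)
  shared <- intersect(window$offsets, model$offsets)
  if (!length(shared)) return(0)
  ri <- match(shared, window$offsets)
  mi <- match(shared, model$offsets)
  aa_idx <- match(res[ri], colnames(model$weights))
  w <- model$weights[cbind(mi, aa_idx)]
  b <- model$background[aa_idx]
  sum(log2(w / b))
}

#' Scan one site against a library of kinase models
#'
#' Scores the window centred on `site_position` against every model whose
#' acceptor set contains the residue there, and keeps predictions at or
#' above `config$score_threshold`. Output is sorted by descending score,
#' ties broken by kinase name, so results are deterministic.
#'
#' @param protein one-row protein tibble.
#' @param site_position 1-based position.
#' @param models list of [kinase_model()] objects.
#' @param config a [pipeline_config()].
#' @return A tibble with columns `kinase`, `site_position`, `score` (possibly
#'   zero rows).
#' @export
scan_site <- function(protein, site_position, models, config = pipeline_config()) {
  win <- extract_window(protein, site_position, config)
  scores <- vapply(models, function(m) score_window(win, m), numeric(1))
  names(scores) <- vapply(models, `[[`, "", "name")
  keep <- !is.na(scores) & scores >= config$score_threshold
  out <- tibble::tibble(kinase = names(scores)[keep],
                        site_position = as.integer(site_position),
                        score = unname(scores[keep]))
  dplyr::arrange(out, dplyr::desc(.data$score), .data$kinase)
}

#' Read a kinase model library from structured text
#'
#' One block per kinase: a header line
#' `>NAME acceptors=S,T family=FAM` followed by one line per offset holding
#' the offset and 20 probabilities in [aa_alphabet()] order. Blank lines and
#' `#` comments are ignored. Rows off unit sum by more than 1e-6 are
#' renormalized with a warning; zeros receive the configured pseudocount.
#'
#' @param path file path.
#' @param config a [pipeline_config()] (supplies the pseudocount).
#' @return A named list of `kinase_model` objects.
#' @export
read_kinase_models <- function(path, config = pipeline_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!grepl("^(#|$)", lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) abort_phos("no kinase model blocks found", "phos_model_error")
  ends <- c(starts[-1] - 1L, length(lines))
  models <- lapply(seq_along(starts), function(i) {
    hdr <- lines[[starts[[i]]]]
    body <- lines[seq(starts[[i]] + 1L, ends[[i]])]
    name <- sub("^>(\\S+).*$", "\\1", hdr)
    get_attr <- function(key) {
      m <- regmatches(hdr, regexec(paste0(key, "=(\\S+)"), hdr))[[1]]
      if (length(m) == 2) m[[2]] else NA_character_
    }
    acceptors <- strsplit(get_attr("acceptors"), ",", fixed = TRUE)[[1]]
    family <- get_attr("family")
    fields <- strsplit(body, "\\s+")
    offs <- vapply(fields, function(f) as.integer(f[[1]]), integer(1))
    w <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(20)))
    ord <- order(offs)
    w <- w[ord, , drop = FALSE]
    rownames(w) <- offs[ord]
    kinase_model(name, acceptors, w, family = family,
                 pseudocount = config$pseudocount)
  })
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Write a kinase model library
#'
#' Inverse of [read_kinase_models()].
#'
#' @param models named list of `kinase_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinase_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    fam <- if (is.na(m$family)) "" else paste0(" family=", m$family)
    writeLines(sprintf(">%s acceptors=%s%s", m$name,
                       paste(m$acceptors, collapse = ","), fam), con)
    for (i in seq_along(m$offsets)) {
      writeLines(paste(c(m$offsets[[i]],
                         format(m$weights[i, ], digits = 12, trim = TRUE)),
                       collapse = " "), con)
    }
  }
  invisible(path)
}
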