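#' Read protein sequences from FASTA
#'
#' Reads single- or multi-record FASTA into a protein table. Sequences are
#' upper-cased and validated against the canonical 20-letter alphabet.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @export
read_proteins <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  out <- tibble::tibble(id = ids, sequence = unname(seqs),
                        length = nchar(unname(seqs)))
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), out$sequence)
  if (any(bad)) {
    abort_phos(paste0("non-canonical residues in sequence(s): ",
                      paste(out$id[bad], collapse = ", ")),
               "phos_sequence_error")
  }
  if (any(out$id == "")) abort_phos("empty FASTA identifier", "phos_sequence_error")
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins tibble with `id` and `sequence` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse HGVS-style protein substitution tokens
#'
#' Accepts one-letter tokens with or without the `p.` prefix
#' (`p.K309T`, `S632N`). Anything else — missing alternate residue,
#' non-canonical residue, zero or negative position — is a parse error
#' naming the offending token.
#'
#' @param token character vector of tokens.
#' @return A tibble with columns `token`, `ref_aa`, `position`, `alt_aa`.
#' @examples
#' parse_protein_variant(c("p.K309T", "S632N"))
#' @export
parse_protein_variant <- function(token) {
  if (length(token) == 0) {
    return(tibble::tibble(token = character(), ref_aa = character(),
                          position = integer(), alt_aa = character()))
  }
  stripped <- sub("^p\\.", "", token)
  m <- regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", stripped)
  parts <- regmatches(stripped, m)
  bad <- lengths(parts) != 4L
  ref <- alt <- rep(NA_character_, length(token))
  pos <- rep(NA_integer_, length(token))
  ok <- which(!bad)
  if (length(ok)) {
    ref[ok] <- toupper(vapply(parts[ok], `[[`, "", 2L))
    pos[ok] <- as.integer(vapply(parts[ok], `[[`, "", 3L))
    alt[ok] <- toupper(vapply(parts[ok], `[[`, "", 4L))
  }
  bad <- bad | !is_canonical_aa(ref) | !is_canonical_aa(alt) |
    is.na(pos) | pos < 1L | (!is.na(ref) & !is.na(alt) & ref == alt)
  if (any(bad)) {
    abort_phos(paste0("malformed protein variant token(s): ",
                      paste(unique(token[bad]), collapse = ", ")),
               "phos_parse_error")
  }
  tibble::tibble(token = paste0("p.", ref, pos, alt),
                 ref_aa = ref, position = pos, alt_aa = alt)
}

#' Format a substitution as a p.-prefixed token
#'
#' Exact inverse of [parse_protein_variant()] over canonical residues.
#'
#' @param ref_aa,position,alt_aa substitution components.
#' @return Character vector of tokens such as `"p.K309T"`.
#' @export
format_protein_variant <- function(ref_aa, position, alt_aa) {
  paste0("p.", ref_aa, position, alt_aa)
}

#' Read a missense variant table (TSV)
#'
#' Tab-separated, UTF-8, `#` comment lines ignored, header required. The
#' mutation column (named `mutation` or `token`) is mandatory; recognised
#' optional columns are `protein` / `protein_id`, `cdna` / `nucleotide_change`,
#' `snp_id`, `exon`, `frequency` / `bic_freq`, `source`. Frequency defaults
#' to 1 when absent. Row order is preserved; a row whose mutation token
#' fails to parse is reported with its row number.
#'
#' @param path TSV file path.
#' @param source tag recorded in the `source` column when the file has none.
#' @return A tibble of variant records: `protein_id`, `token`, `ref_aa`,
#'   `position`, `alt_aa`, `cdna_label`, `snp_id`, `frequency`, `source`.
#' @export
read_variant_table <- function(path, source = basename(path)) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  tok_col <- intersect(c("mutation", "token"), names(raw))
  if (!length(tok_col)) {
    abort_phos("variant table must name a 'mutation' (or 'token') column",
               "phos_parse_error")
  }
  tokens <- as.character(raw[[tok_col[[1]]]])
  parsed <- tryCatch(parse_protein_variant(tokens), error = function(e) e)
  if (inherits(parsed, "error")) {
    reparse <- vapply(tokens, function(t) {
      inherits(tryCatch(parse_protein_variant(t), error = function(e) e), "error")
    }, logical(1))
    abort_phos(paste0("unparseable mutation token at row(s) ",
                      paste(which(reparse), collapse = ", "), ": ",
                      paste(tokens[reparse], collapse = ", ")),
               "phos_parse_error")
  }
  pick <- function(...) {
    col <- intersect(c(...), names(raw))
    if (length(col)) as.character(raw[[col[[1]]]]) else NA_character_
  }
  freq_col <- intersect(c("frequency", "bic_freq", "freq"), names(raw))
  freq <- if (length(freq_col)) {
    f <- suppressWarnings(as.integer(raw[[freq_col[[1]]]]))
    dplyr::coalesce(f, 1L)
  } else {
    rep(1L, nrow(raw))
  }
  if (any(freq < 0)) abort_phos("negative variant frequency", "phos_parse_error")
  src_col <- pick("source")
  tibble::tibble(
    protein_id = dplyr::coalesce(pick("protein", "protein_id"), "unknown"),
    token = parsed$token,
    ref_aa = parsed$ref_aa,
    position = parsed$position,
    alt_aa = parsed$alt_aa,
    cdna_label = pick("cdna", "nucleotide_change", "cdna_label"),
    snp_id = pick("snp_id", "snpid"),
    frequency = freq,
    source = dplyr::coalesce(src_col, source)
  )
}

#' Write a variant table (TSV)
#'
#' Writes the schema read by [read_variant_table()]; reading the result back
#' reproduces identical records.
#'
#' @param variants variant tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- tibble::tibble(
    protein = variants$protein_id,
    mutation = variants$token,
    cdna = variants$cdna_label,
    snp_id = variants$snp_id,
    frequency = variants$frequency,
    source = variants$source
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Collapse repeated reports of the same substitution
#'
#' Repeat rows for one distinct substitution (same protein, position, alt)
#' are collapsed to a single record with frequencies summed, mirroring
#' report-count semantics of variant databases.
#'
#' @param variants variant tibble.
#' @return One row per distinct substitution, ordered by protein, position,
#'   alternate residue.
#' @export
distinct_variants <- function(variants) {
  variants |>
    dplyr::group_by(.data$protein_id, .data$token, .data$ref_aa,
                    .data$position, .data$alt_aa) |>
    dplyr::summarise(
      cdna_label = dplyr::first(.data$cdna_label),
      snp_id = dplyr::first(.data$snp_id),
      frequency = sum(.data$frequency),
      source = dplyr::first(.data$source),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_id, .data$position, .data$alt_aa)
}

#' Read a phosphosite catalog (TSV)
#'
#' Columns: `protein_id`, `position`, `acceptor`, `characterized`,
#' `known_kinases` (semicolon-joined, may be empty), `note`. Sites are
#' returned sorted by (protein, position); a duplicated (protein, position)
#' or a non-S/T/Y acceptor is an error.
#'
#' @param path TSV file path.
#' @return A tibble of phosphosites with `known_kinases` as a list-column.
#' @export
read_phosphosite_catalog <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  needed <- c("protein_id", "position", "acceptor", "characterized")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort_phos(paste0("phosphosite catalog missing column(s): ",
                      paste(missing, collapse = ", ")), "phos_parse_error")
  }
  acceptor <- toupper(as.character(raw$acceptor))
  bad <- !acceptor %in% PHOS_ACCEPTORS
  if (any(bad)) {
    abort_phos(paste0("acceptor must be S, T or Y; found ",
                      paste(unique(acceptor[bad]), collapse = ", "),
                      " at position(s) ",
                      paste(raw$position[bad], collapse = ", ")),
               "phos_validation_error")
  }
  key <- paste(raw$protein_id, raw$position)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    abort_phos(paste0("duplicate phosphosite row(s): ",
                      paste(unique(dup), collapse = "; ")),
               "phos_validation_error")
  }
  kin <- if ("known_kinases" %in% names(raw)) as.character(raw$known_kinases) else ""
  kin[is.na(kin)] <- ""
  tibble::tibble(
    protein_id = as.character(raw$protein_id),
    position = as.integer(raw$position),
    acceptor = acceptor,
    characterized = as.logical(raw$characterized),
    known_kinases = lapply(strsplit(kin, ";", fixed = TRUE), trimws),
    note = if ("note" %in% names(raw)) as.character(raw$note) else NA_character_
  ) |>
    dplyr::arrange(.data$protein_id, .data$position)
}

#' Validate variants against a protein sequence
#'
#' Confirms, for every variant, that the reference residue at its 1-based
#' position matches the protein sequence. A position beyond the protein is a
#' range error; a residue mismatch is a reference-mismatch error reporting
#' expected vs found, downgraded to a warning when `lenient = TRUE` (useful
#' when only isolated motif windows of a protein are available).
#'
#' @param variants variant tibble (one protein).
#' @param protein a one-row protein tibble from [read_proteins()].
#' @param lenient downgrade reference mismatches to warnings.
#' @return The variant tibble, unchanged, invisibly validated.
#' @export
validate_variants <- function(variants, protein, lenient = FALSE) {
  stopifnot(nrow(protein) == 1L)
  mism <- variants$protein_id != protein$id
  if (any(mism)) {
    abort_phos(paste0("variant protein_id does not match protein: ",
                      paste(unique(variants$protein_id[mism]), collapse = ", ")),
               "phos_validation_error")
  }
  beyond <- variants$position > protein$length
  if (any(beyond)) {
    abort_phos(paste0("variant position beyond protein length ",
                      protein$length, ": ",
                      paste(variants$token[beyond], collapse = ", ")),
               "phos_range_error")
  }
  found <- substring(protein$sequence, variants$position, variants$position)
  bad <- found != variants$ref_aa
  if (any(bad)) {
    msg <- paste0("reference mismatch for ",
                  paste(sprintf("%s (expected %s, found %s)",
                                variants$token[bad], variants$ref_aa[bad],
                                found[bad]), collapse = "; "))
    if (lenient) warning(msg, call. = FALSE)
    else abort_phos(msg, "phos_reference_mismatch")
  }
  variants
}

#' Pair variants with nearby phosphosites
#'
#' A variant is kept iff it lies in or within `selection_radius` residues of
#' at least one catalogued site (inclusive distance); each kept variant is
#' paired with every such site.
#'
#' @param variants variant tibble.
#' @param sites phosphosite tibble from [read_phosphosite_catalog()].
#' @param config a [pipeline_config()].
#' @return A tibble with one row per (variant, site) pair; variant columns
#'   plus `site_position`, `site_acceptor`, `site_characterized`.
#' @export
select_variants_near_sites <- function(variants, sites, config = pipeline_config()) {
  pairs <- pair_variants_with_sites(variants, sites, config)
  dplyr::filter(pairs, !is.na(.data$site_position))
}

# full pairing, keeping variants with no site within radius (site columns NA);
# the replay/fixture path needs these because creating-only variants may sit
# far from every transcribed site
pair_variants_with_sites <- function(variants, sites, config = pipeline_config()) {
  r <- config$selection_radius
  sites_by_protein <- split(sites, sites$protein_id)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    s <- sites_by_protein[[v$protein_id]]
    near <- if (is.null(s)) s[0, ] else s[abs(s$position - v$position) <= r, ]
    if (is.null(near) || nrow(near) == 0L) {
      dplyr::mutate(v, site_position = NA_integer_,
                    site_acceptor = NA_character_, site_characterized = NA)
    } else {
      dplyr::bind_cols(
        v[rep(1L, nrow(near)), ],
        tibble::tibble(
          site_position = near$position,
          site_acceptor = near$acceptor,
          site_characterized = near$characterized
        )
      )
    }
  })
  dplyr::bind_rows(rows)
}
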