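# run code under a temporary RNG state; sub-streams are derived from one
# global seed so adding a generator does not perturb existing fixtures
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

#' Build a synthetic kinase model from a consensus string
#'
#' The consensus covers the full window span (`window_up + window_down + 1`
#' characters) with the acceptor at offset 0; `.` marks an uninformative
#' offset. Informative offsets give the consensus residue probability
#' `sharpness`, spreading the remainder uniformly over the other 19
#' residues; uninformative offsets equal the uniform 0.05 background, so
#' they contribute exactly 0 bits to any score. The model is a
#' deterministic function of its arguments.
#'
#' @param consensus character string, e.g. `".....SP...."`.
#' @param sharpness consensus-residue probability at informative offsets,
#'   in (0, 1].
#' @param name kinase name.
#' @param config a [pipeline_config()] (window geometry).
#' @param acceptors acceptor set; defaults to the offset-0 consensus
#'   residue.
#' @return A [kinase_model()].
#' @export
make_kinase_model <- function(consensus, sharpness, name = "SYNKIN",
                              config = pipeline_config(),
                              acceptors = NULL) {
  span <- config$window_up + config$window_down + 1L
  chars <- seq_chars(consensus)
  if (length(chars) != span) {
    abort_phos(sprintf("consensus length %d != window span %d",
                       length(chars), span), "phos_model_error")
  }
  stopifnot(sharpness > 0, sharpness <= 1)
  offsets <- seq.int(-config$window_up, config$window_down)
  anchor <- chars[[config$window_up + 1L]]
  if (!anchor %in% PHOS_ACCEPTORS) {
    abort_phos("consensus residue at offset 0 must be S, T or Y",
               "phos_model_error")
  }
  if (is.null(acceptors)) acceptors <- anchor
  aa <- aa_alphabet()
  w <- matrix(1 / 20, nrow = span, ncol = 20, dimnames = list(offsets, aa))
  for (i in seq_len(span)) {
    ch <- chars[[i]]
    if (ch == ".") next
    if (!is_canonical_aa(ch)) {
      abort_phos(paste0("invalid consensus residue: ", ch), "phos_model_error")
    }
    row <- rep((1 - sharpness) / 19, 20)
    row[match(ch, aa)] <- sharpness
    w[i, ] <- row
  }
  m <- kinase_model(name, acceptors, w, pseudocount = config$pseudocount)
  m$consensus <- consensus
  m
}

#' Default kinase models for synthetic scenarios
#'
#' Four models with one informative non-anchor offset each (+1), distinct
#' specificity residues, uniform background. With sharpness 0.9 a perfect
#' match scores about 8.34 bits and a single informative-offset mismatch
#' drops it to about 0.92 bits, crossing the default reliability threshold
#' of 5 — so one substitution can abolish, create, or (moved by one
#' residue) rescue a site.
#'
#' @param sharpness consensus probability (default 0.9).
#' @param config a [pipeline_config()].
#' @return A named list of four [kinase_model()]s.
#' @export
default_scenario_models <- function(sharpness = 0.9, config = pipeline_config()) {
  recipes <- list(
    KINP = c("S", "P"), KINE = c("S", "E"),
    KINR = c("T", "R"), KIND = c("S", "D")
  )
  models <- lapply(names(recipes), function(nm) {
    anchor <- recipes[[nm]][[1]]
    partner <- recipes[[nm]][[2]]
    cons <- paste0(strrep(".", config$window_up), anchor, partner,
                   strrep(".", config$window_down - 1L))
    make_kinase_model(cons, sharpness, name = nm, config = config)
  })
  stats::setNames(models, names(recipes))
}

informative_offsets <- function(model) {
  chars <- seq_chars(model$consensus)
  offs <- model$offsets
  offs[chars != "."]
}

#' Generate a protein with planted phosphosites and truth labels
#'
#' Background residues are drawn uniformly from the 20-letter alphabet;
#' non-overlapping consensus motifs are planted at evenly spaced centres
#' (spacing `window span + 3`), each assigned a model round-robin. Next to
#' each site the generator also plants: a shift-by-one rescue support (the
#' informative consensus residues repeated one position downstream, so
#' moving the acceptor one residue downstream recreates a scoring site)
#' and a latent creation slot 8 residues downstream of the centre — a
#' non-acceptor residue whose downstream context already matches the
#' consensus, so substituting in the acceptor creates a site. Planting is
#' verified — each planted site binds exactly its model at or above the
#' threshold, and no other S/T/Y position in the background scores reliably
#' for any model — and the background is resampled up to `max_attempts`
#' times before erroring, so no silently non-conforming scenario is
#' returned.
#'
#' @param length protein length in residues.
#' @param n_sites number of planted sites.
#' @param models named list of models from [default_scenario_models()].
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param config a [pipeline_config()].
#' @param max_attempts resampling cap.
#' @return A list of class `phos_scenario`: `protein` (one-row tibble),
#'   `sites` (phosphosite tibble), `latent` (tibble of creation slots),
#'   `models`, `config`, `seed`.
#' @export
make_protein_with_sites <- function(length, n_sites, models, seed,
                                    config = pipeline_config(),
                                    max_attempts = 1000L) {
  span <- config$window_up + config$window_down + 1L
  spacing <- span + 3L
  first <- config$window_up + 1L
  latent_off <- config$window_down + 3L
  if (n_sites > 0 &&
      first + (n_sites - 1L) * spacing + latent_off + 1L > length) {
    abort_phos("infeasible packing: too many sites for protein length",
               "phos_infeasible_error")
  }
  centers <- if (n_sites > 0) first + (seq_len(n_sites) - 1L) * spacing else integer()
  model_for <- if (n_sites > 0) rep(seq_along(models), length.out = n_sites) else integer()
  aa <- aa_alphabet()
  non_acceptor <- setdiff(aa, PHOS_ACCEPTORS)

  build <- function(attempt) {
    with_seed(sub_seed(seed, attempt), {
      s <- sample(aa, length, replace = TRUE)
      if (n_sites > 0) {
        for (i in seq_len(n_sites)) {
          m <- models[[model_for[[i]]]]
          chars <- seq_chars(m$consensus)
          p <- centers[[i]]
          info <- which(chars != ".")
          offs <- m$offsets[info]
          s[p + offs] <- chars[info]
          # shift-by-one rescue support for positive informative offsets
          pos_offs <- offs[offs > 0]
          s[p + 1L + pos_offs] <- chars[info][offs > 0]
          # latent creation slot: consensus context without its acceptor
          q <- p + latent_off
          s[q] <- sample(setdiff(non_acceptor, chars[info][offs > 0]), 1)
          s[q + pos_offs] <- chars[info][offs > 0]
        }
      }
      paste(s, collapse = "")
    })
  }

  thr <- config$score_threshold
  for (attempt in seq_len(max_attempts)) {
    sequence <- build(attempt)
    protein <- tibble::tibble(id = sprintf("SYNPROT_%d", seed),
                              sequence = sequence, length = nchar(sequence))
    ok <- TRUE
    if (n_sites > 0) {
      for (i in seq_len(n_sites)) {
        preds <- scan_site(protein, centers[[i]], models, config)
        if (!identical(preds$kinase, models[[model_for[[i]]]]$name)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      # reject backgrounds with accidental scoring motifs so planted sites
      # are the only reliable predictions in the scenario
      chars <- seq_chars(sequence)
      sty <- setdiff(which(chars %in% PHOS_ACCEPTORS), centers)
      for (p in sty) {
        if (nrow(scan_site(protein, p, models, config))) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      sites <- tibble::tibble(
        protein_id = protein$id,
        position = as.integer(centers),
        acceptor = vapply(model_for, function(k)
          seq_chars(models[[k]]$consensus)[[config$window_up + 1L]], character(1)),
        characterized = rep(TRUE, n_sites),
        known_kinases = lapply(model_for, function(k) models[[k]]$name),
        note = rep("planted", n_sites)
      )
      latent <- tibble::tibble(
        protein_id = protein$id,
        position = as.integer(centers + latent_off),
        kinase = vapply(model_for, function(k) models[[k]]$name, character(1)),
        acceptor = sites$acceptor,
        near_site = as.integer(centers)
      )
      return(structure(list(protein = protein, sites = sites, latent = latent,
                            models = models, config = config, seed = seed),
                       class = "phos_scenario"))
    }
  }
  abort_phos(sprintf("planting failed after %d attempts", max_attempts),
             "phos_infeasible_error")
}

#' @export
print.phos_scenario <- function(x, ...) {
  cat(sprintf("<phos_scenario> %d-residue protein, %d planted sites, %d models (seed %d)\n",
              x$protein$length, nrow(x$sites), length(x$models), x$seed))
  invisible(x)
}

#' Generate variants of a requested truth label
#'
#' * `abolishing` — substitutes the informative non-anchor consensus
#'   residue of a planted site with a non-acceptor, dropping the site's
#'   score below threshold.
#' * `rescued` — substitutes that same residue with the model's acceptor,
#'   killing the original site while the planted shift-by-one support
#'   recreates the same kinase's site at the altered residue.
#' * `creating` — fills a latent slot's acceptor, creating a scoring site
#'   within the selection radius of a planted site.
#' * `neutral` — substitutes an uninformative offset of a site window with
#'   a non-acceptor (zero score change by construction), or a residue
#'   beyond the selection radius of every site.
#'
#' Every generated variant is verified against the live scoring engine
#' (mutant site score below threshold for abolishing/rescued, created-site
#' score at or above it for creating/rescued); an unverifiable request is
#' an error rather than a silently wrong label.
#'
#' @param scenario a `phos_scenario`.
#' @param kind label to generate.
#' @param n number of distinct variants.
#' @param seed integer seed.
#' @return A variant tibble with an extra `label` column.
#' @export
make_variants <- function(scenario, kind = c("abolishing", "creating",
                                             "rescued", "neutral"),
                          n, seed) {
  kind <- match.arg(kind)
  cfg <- scenario$config
  protein <- scenario$protein
  models <- scenario$models
  sites <- scenario$sites
  aa <- aa_alphabet()
  non_acceptor <- setdiff(aa, PHOS_ACCEPTORS)
  res_at <- function(p) substring(protein$sequence, p, p)
  model_of_site <- function(i) models[[sites$known_kinases[[i]][[1]]]]

  mk <- function(pos, alt) {
    ref <- res_at(pos)
    tibble::tibble(protein_id = protein$id,
                   token = format_protein_variant(ref, pos, alt),
                   ref_aa = ref, position = as.integer(pos), alt_aa = alt,
                   cdna_label = NA_character_, snp_id = NA_character_,
                   frequency = 1L, source = "synthetic", label = kind)
  }

  out <- with_seed(sub_seed(seed, match(kind, c("abolishing", "creating",
                                                "rescued", "neutral"))), {
    rows <- list()
    if (kind %in% c("abolishing", "rescued")) {
      if (n > nrow(sites)) {
        abort_phos(sprintf("%s: need %d sites, have %d", kind, n, nrow(sites)),
                   "phos_infeasible_error")
      }
      for (i in seq_len(n)) {
        m <- model_of_site(i)
        k <- min(setdiff(informative_offsets(m), 0L))
        pos <- sites$position[[i]] + k
        alt <- if (kind == "rescued") m$acceptors[[1]]
               else sample(setdiff(non_acceptor, res_at(pos)), 1)
        rows[[i]] <- mk(pos, alt)
      }
    } else if (kind == "creating") {
      latent <- scenario$latent
      if (n > nrow(latent)) {
        abort_phos("creating: not enough latent slots", "phos_infeasible_error")
      }
      for (i in seq_len(n)) {
        rows[[i]] <- mk(latent$position[[i]], latent$acceptor[[i]])
      }
    } else {
      half <- n %/% 2
      # uninformative-offset controls
      for (i in seq_len(half)) {
        j <- ((i - 1) %% nrow(sites)) + 1
        m <- model_of_site(j)
        uninf <- setdiff(m$offsets, informative_offsets(m))
        pos <- sites$position[[j]] - 3L + ((i - 1) %/% nrow(sites))
        stopifnot(-3L %in% uninf)
        rows[[i]] <- mk(pos, sample(setdiff(non_acceptor, res_at(pos)), 1))
      }
      # beyond-radius controls
      tail_start <- max(sites$position) + cfg$selection_radius + 1L
      tail_pos <- seq.int(tail_start, protein$length)
      if (length(tail_pos) < n - half) {
        abort_phos("neutral: protein tail too short for distance controls",
                   "phos_infeasible_error")
      }
      for (i in seq_len(n - half)) {
        pos <- tail_pos[[i]]
        rows[[half + i]] <- mk(pos, sample(setdiff(non_acceptor, res_at(pos)), 1))
      }
    }
    dplyr::bind_rows(rows)
  })

  verify_variants(out, scenario, kind)
  out
}

# label verification against the live scoring engine
verify_variants <- function(variants, scenario, kind) {
  cfg <- scenario$config
  models <- scenario$models
  thr <- cfg$score_threshold
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    mut <- apply_variant(scenario$protein, v)
    near <- scenario$sites[abs(scenario$sites$position - v$position) <=
                             cfg$selection_radius, ]
    if (kind %in% c("abolishing", "rescued")) {
      lost <- vapply(seq_len(nrow(near)), function(j) {
        kin <- near$known_kinases[[j]][[1]]
        preds <- scan_site(mut, near$position[[j]], models, cfg)
        !kin %in% preds$kinase
      }, logical(1))
      if (!any(lost)) {
        abort_phos(paste0(kind, " variant failed verification: ", v$token),
                   "phos_infeasible_error")
      }
    }
    if (kind %in% c("creating", "rescued")) {
      preds <- scan_site(mut, v$position, models, cfg)
      if (!nrow(preds)) {
        abort_phos(paste0(kind, " variant creates nothing: ", v$token),
                   "phos_infeasible_error")
      }
    }
    if (kind == "neutral") {
      changed <- vapply(seq_len(nrow(near)), function(j) {
        wt <- scan_site(scenario$protein, near$position[[j]], models, cfg)
        mu <- scan_site(mut, near$position[[j]], models, cfg)
        !identical(wt, mu)
      }, logical(1))
      if (any(changed)) {
        abort_phos(paste0("neutral variant perturbs a site: ", v$token),
                   "phos_infeasible_error")
      }
    }
  }
  invisible(TRUE)
}

#' Sample a synthetic multiple sequence alignment
#'
#' The reference row is the input protein; in every other row each column
#' holds the reference residue with probability `conservation` and
#' otherwise a residue drawn uniformly from the 19 alternatives (so
#' `conservation = 0.05` is the uniform distribution over all 20 and
#' `conservation = 1` makes all rows identical). Expected per-column
#' information content is a strictly increasing function of
#' `conservation`; see [calibrate_msa_conservation()].
#'
#' @param protein one-row protein tibble.
#' @param n_rows total rows, at least 2.
#' @param conservation per-column reference-residue probability in [0, 1].
#' @param seed integer seed.
#' @return A `phos_msa`.
#' @export
make_msa <- function(protein, n_rows, conservation, seed) {
  stopifnot(n_rows >= 2, conservation >= 0, conservation <= 1)
  aa <- aa_alphabet()
  ref <- seq_chars(protein$sequence[[1]])
  len <- length(ref)
  with_seed(sub_seed(seed, 5L), {
    rows <- c(protein$sequence[[1]],
              vapply(seq_len(n_rows - 1L), function(r) {
                keep <- stats::runif(len) < conservation
                other <- vapply(ref, function(a) sample(setdiff(aa, a), 1),
                                character(1))
                paste(ifelse(keep, ref, other), collapse = "")
              }, character(1)))
    new_msa(rows, ids = c(protein$id[[1]],
                          sprintf("homolog%03d", seq_len(n_rows - 1L))),
            reference = 1L)
  })
}

#' Closed-form expected column information content
#'
#' For the [make_msa()] sampling model the population column distribution
#' is `p(ref) = c`, `p(other) = (1 - c) / 19`, giving
#' `R(c) = log2(20) + c log2 c + (1 - c) log2((1 - c) / 19)` bits.
#'
#' @param conservation probability in [0, 1].
#' @return Expected information content in bits.
#' @export
expected_column_information <- function(conservation) {
  c_ <- conservation
  h <- vapply(c_, function(ci) {
    terms <- c(ci, rep((1 - ci) / 19, 19))
    -sum(ifelse(terms > 0, terms * log2(terms), 0))
  }, numeric(1))
  log2(20) - h
}

#' Calibrate the MSA conservation level for a target median
#'
#' Bisection on the closed-form [expected_column_information()] to find
#' the conservation level whose expected per-column information content
#' equals `target` bits (default 3.00, the centre of the reliability
#' window).
#'
#' @param target bits.
#' @param tol bisection tolerance on the information content.
#' @return The calibrated conservation probability.
#' @export
calibrate_msa_conservation <- function(target = 3.00, tol = 1e-9) {
  lo <- 1 / 20
  hi <- 1 - 1e-12
  stopifnot(target > 0, target < log2(20))
  while (expected_column_information(hi) < target) hi <- 1 - (1 - hi) / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_column_information(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Write a complete synthetic scenario to a directory
#'
#' Emits protein FASTA, phosphosite TSV, variant TSV (with truth labels in
#' a separate truth TSV), the kinase model library, and an MSA calibrated
#' to the informative median-conservation window.
#'
#' @param dir output directory.
#' @param n_sites planted sites.
#' @param n_per_label variants per truth label.
#' @param length protein length.
#' @param sharpness model sharpness.
#' @param msa_rows MSA rows.
#' @param seed integer seed.
#' @param config a [pipeline_config()].
#' @return Named vector of written paths, invisibly.
#' @export
simulate_scenario <- function(dir, n_sites = 20L, n_per_label = 20L,
                              length = 300L, sharpness = 0.9,
                              msa_rows = 60L, seed = 1L,
                              config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- default_scenario_models(sharpness, config)
  scen <- make_protein_with_sites(length, n_sites, models, seed, config)
  labels <- c("abolishing", "creating", "rescued", "neutral")
  variants <- dplyr::bind_rows(lapply(labels, function(k)
    make_variants(scen, k, n_per_label, seed)))
  cons <- calibrate_msa_conservation(config$median_conservation_target)
  msa <- make_msa(scen$protein, msa_rows, cons, seed)

  paths <- c(
    protein = file.path(dir, "protein.fasta"),
    sites = file.path(dir, "sites.tsv"),
    variants = file.path(dir, "variants.tsv"),
    truth = file.path(dir, "truth.tsv"),
    models = file.path(dir, "kinase_models.txt"),
    msa = file.path(dir, "msa.fasta")
  )
  write_proteins(scen$protein, paths[["protein"]])
  readr::write_tsv(tibble::tibble(
    protein_id = scen$sites$protein_id,
    position = scen$sites$position,
    acceptor = scen$sites$acceptor,
    characterized = scen$sites$characterized,
    known_kinases = vapply(scen$sites$known_kinases, paste, character(1),
                           collapse = ";"),
    note = scen$sites$note
  ), paths[["sites"]], progress = FALSE)
  write_variant_table(variants, paths[["variants"]])
  readr::write_tsv(variants[, c("token", "label")], paths[["truth"]],
                   progress = FALSE)
  write_kinase_models(models, paths[["models"]])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(
      apply(msa$rows, 1, paste, collapse = ""), msa$ids)),
    paths[["msa"]])
  invisible(paths)
}
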