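# Shared builders for test fixtures; everything is generated in code.

toy_protein <- function(sequence, id = "TOY") {
  tibble::tibble(id = id, sequence = sequence, length = nchar(sequence))
}

toy_variant <- function(token, protein_id = "TOY", frequency = 1L) {
  p <- parse_protein_variant(token)
  tibble::tibble(protein_id = protein_id, token = p$token, ref_aa = p$ref_aa,
                 position = p$position, alt_aa = p$alt_aa,
                 cdna_label = NA_character_, snp_id = NA_character_,
                 frequency = as.integer(frequency), source = "test")
}

toy_site <- function(position, acceptor = "S", characterized = TRUE,
                     protein_id = "TOY", kinases = character()) {
  tibble::tibble(protein_id = protein_id, position = as.integer(position),
                 acceptor = acceptor, characterized = characterized,
                 known_kinases = list(kinases), note = NA_character_)
}

# nominal prediction tibble at the default threshold
preds <- function(kinases, score = 6, site = 1L) {
  tibble::tibble(kinase = kinases, site_position = as.integer(site),
                 score = rep_len(score, length(kinases)))
}

# a uniform-background model over the default +/-5 window, with chosen
# residues forced at chosen offsets
toy_model <- function(name = "KIN", acceptors = "S",
                      informative = list(), sharpness = 0.9) {
  cons <- rep(".", 11)
  cons[6] <- acceptors[[1]]
  for (off in names(informative)) cons[as.integer(off) + 6] <- informative[[off]]
  make_kinase_model(paste(cons, collapse = ""), sharpness, name = name,
                    acceptors = acceptors)
}

# one cached synthetic scenario reused across test files
scenario_cache <- new.env(parent = emptyenv())
default_scenario <- function() {
  if (is.null(scenario_cache$scen)) {
    cfg <- pipeline_config()
    models <- default_scenario_models(0.9, cfg)
    scen <- make_protein_with_sites(300, 20, models, seed = 20260901, cfg)
    labels <- c("abolishing", "creating", "rescued", "neutral")
    variants <- dplyr::bind_rows(lapply(labels, function(k)
      make_variants(scen, k, 20, seed = 20260901)))
    scenario_cache$scen <- list(scen = scen, variants = variants,
                                models = models, cfg = cfg)
  }
  scenario_cache$scen
}

brca_cache <- new.env(parent = emptyenv())
brca_results <- function() {
  if (is.null(brca_cache$res)) brca_cache$res <- run_brca_replay()
  brca_cache$res
}
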