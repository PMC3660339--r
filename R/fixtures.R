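#' Packaged BRCA1/BRCA2 analysis fixtures
#'
#' Loads the tables shipped with the package: the phosphosite catalog, the
#' variant list with BIC report frequencies, the recorded kinase
#' predictions (replay backend), the recorded conservation annotation, and
#' the per-gene analysis denominators.
#'
#' @return A list: `variants`, `sites`, `replay`, `conservation`, `totals`
#'   (named integer vector of analysed variants per gene).
#' @export
brca_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "phosimpact",
                                  mustWork = TRUE)
  totals_raw <- readr::read_tsv(path("brca_totals.tsv"), comment = "#",
                                show_col_types = FALSE, progress = FALSE)
  list(
    variants = read_variant_table(path("brca_variants.tsv"), source = "BIC"),
    sites = read_phosphosite_catalog(path("brca_sites.tsv")),
    replay = read_replay_table(path("brca_replay.tsv")),
    conservation = read_conservation_fixture(path("brca_conservation.tsv")),
    totals = stats::setNames(as.integer(totals_raw$n_analyzed),
                             totals_raw$protein)
  )
}

#' Reproduce the BRCA1/BRCA2 analysis from the packaged fixtures
#'
#' Runs the full differential pipeline over the packaged variant list with
#' the replay predictor, classifies every variant, and aggregates the
#' stratified summary with the recorded conservation annotation.
#' Variants with no transcribed site within the selection radius are kept
#' (the packaged catalog transcribes only the sites named in the recorded
#' predictions, not the full catalog the original selection ran against).
#'
#' @param config a [pipeline_config()].
#' @return A list: `verdicts` (a `phos_verdicts`), `summary`
#'   (a `phos_summary`), `fixture` (the loaded fixture).
#' @examples
#' res <- run_brca_replay()
#' tidy(res$summary)
#' @export
run_brca_replay <- function(config = pipeline_config()) {
  fx <- brca_fixture()
  verdicts <- run_differential(fx$variants, fx$sites, predictor = "replay",
                               config = config, replay = fx$replay,
                               keep_unpaired = TRUE)
  summary <- summarize_verdicts(verdicts, conservation = fx$conservation,
                                totals = fx$totals, config = config)
  list(verdicts = verdicts, summary = summary, fixture = fx)
}
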