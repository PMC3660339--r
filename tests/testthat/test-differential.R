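cfg <- pipeline_config()

test_that("site comparison computes lost/gained sets and the abolition call", {
  site <- toy_site(308)
  d <- compare_site(preds("STK6", site = 308), preds(character(), site = 308),
                    site, cfg)
  expect_equal(d$lost[[1]], "STK6")
  expect_equal(d$abolished_fraction, 1)
  expect_equal(d$status, "abolished")

  # the 80% rule fires at exactly 4 of 5 (>=, not >)
  wt <- preds(paste0("K", 1:5))
  d45 <- compare_site(wt, preds("K5"), toy_site(1), cfg)
  expect_equal(d45$abolished_fraction, 0.8)
  expect_equal(d45$status, "abolished")
  d35 <- compare_site(wt, preds(c("K4", "K5")), toy_site(1), cfg)
  expect_equal(d35$abolished_fraction, 0.6)
  expect_equal(d35$status, "weakened")

  # identical sets: unchanged, empty lost/gained
  du <- compare_site(wt, wt, toy_site(1), cfg)
  expect_equal(du$status, "unchanged")
  expect_equal(du$lost[[1]], character())
  expect_equal(du$gained[[1]], character())

  # threshold-crossing counts as loss even when a score is retained
  d_sub <- compare_site(preds("CK2A1", score = 6),
                        preds("CK2A1", score = 4), toy_site(1), cfg)
  expect_equal(d_sub$lost[[1]], "CK2A1")
  expect_equal(d_sub$status, "abolished")

  # gain at the site does not cancel loss of a different kinase
  d_swap <- compare_site(preds("CDK2"), preds("ATM"), toy_site(1), cfg)
  expect_equal(d_swap$status, "abolished")
  expect_equal(d_swap$gained[[1]], "ATM")
  d_gain <- compare_site(preds("CDK2"), preds(c("CDK2", "ATM")), toy_site(1), cfg)
  expect_equal(d_gain$status, "strengthened")
})

test_that("created sites require an acceptor alternate residue and a scoring kinase", {
  m <- toy_model("KIN", informative = list(`1` = "P"))
  prot <- toy_protein("AAAAANPAAAA")
  v <- toy_variant("p.N6S")
  created <- find_created_sites(apply_variant(prot, v), v, list(m), cfg)
  expect_equal(created$position, 6L)
  expect_equal(created$kinases[[1]], "KIN")

  vF <- toy_variant("p.N6F")
  protF <- toy_protein("AAAAANPAAAA")
  expect_equal(nrow(find_created_sites(apply_variant(protF, vF), vF, list(m), cfg)), 0L)

  # acceptor lands without motif context: nothing scores
  prot2 <- toy_protein("AAAAANAAAAA")
  created2 <- find_created_sites(apply_variant(prot2, v), v, list(m), cfg)
  expect_equal(nrow(created2), 0L)
})

delta_row <- function(lost, status = "abolished", characterized = TRUE) {
  tibble::tibble(site_position = 1L, site_characterized = characterized,
                 n_wt_bound = length(lost), lost = list(lost),
                 gained = list(character()), retained = list(character()),
                 abolished_fraction = 1, status = status)
}
created_row <- function(kinases, position = 2L) {
  tibble::tibble(position = position, residue = "S", kinases = list(kinases))
}
no_created <- created_row(character())[0, ]

test_that("variant categories follow the rescue and coverage logic", {
  expect_equal(classify_variant(delta_row("CDK2"), no_created, cfg),
               "abolishing")
  expect_equal(classify_variant(delta_row("CDK2"), created_row("CDK2"), cfg),
               "rescued")
  expect_equal(classify_variant(delta_row("CDK2"),
                                created_row(c("CDK2", "MAPK14")), cfg),
               "rescued")  # extra created kinases do not break coverage
  expect_equal(classify_variant(delta_row("STK6"), created_row("ATM"), cfg),
               "abolishing_and_creating")
  expect_equal(classify_variant(delta_row(character(), status = "unchanged"),
                                created_row("CK2A1"), cfg), "creating")
  expect_equal(classify_variant(delta_row(character(), status = "unchanged"),
                                no_created, cfg), "none")
  # rescue must be the same kinase name unless family rescue is enabled
  expect_equal(classify_variant(delta_row("CDK2"), created_row("CDK1"), cfg),
               "abolishing_and_creating")
  fam_cfg <- pipeline_config(family_rescue = TRUE,
                             families = c(CDK2 = "CDK", CDK1 = "CDK"))
  expect_equal(classify_variant(delta_row("CDK2"), created_row("CDK1"), fam_cfg),
               "rescued")
})

test_that("the recorded BRCA1 characterized-site variants classify as published", {
  res <- brca_results()
  v <- res$verdicts
  t1 <- v[v$protein_id == "BRCA1" & v$token %in%
            c("p.K309T", "p.S632N", "p.P633T", "p.P633S", "p.S1143F",
              "p.Q1144H", "p.Q1281P", "p.S1542C"), ]
  expect_equal(sum(t1$category == "abolishing"), 5L)
  expect_equal(sum(t1$category == "abolishing_and_creating"), 1L)
  expect_equal(sum(t1$category == "rescued"), 2L)
  expect_equal(t1$category[t1$token == "p.S632N"], "abolishing")
  expect_setequal(t1$token[t1$category == "rescued"], c("p.P633T", "p.P633S"))
  expect_equal(t1$category[t1$token == "p.K309T"], "abolishing_and_creating")
})

test_that("every verdict carries exactly one category and they partition", {
  res <- brca_results()
  cats <- c("abolishing", "abolishing_and_creating", "creating", "rescued", "none")
  expect_true(all(res$verdicts$category %in% cats))
  expect_equal(length(res$verdicts$category), nrow(res$verdicts))
})

test_that("running the differential with mutant equal to wild type yields none", {
  sc <- default_scenario()
  # a replay table where mut records equal wt records for every variant
  neutral <- sc$variants[sc$variants$label == "neutral", ][1:5, ]
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(neutral)), function(i) {
    v <- neutral[i, ]
    tibble::tibble(protein = v$protein_id, variant = v$token,
                   state = c("wt", "mut"), site = sc$scen$sites$position[[1]],
                   kinase = "KINP", bound = TRUE)
  }))
  class(rows) <- c("phos_replay", class(rows))
  verd <- run_differential(neutral, sc$scen$sites, predictor = "replay",
                           config = sc$cfg, replay = rows, keep_unpaired = TRUE)
  expect_true(all(verd$category == "none"))
})

test_that("verdict output is deterministic and order-independent", {
  fx <- brca_fixture()
  shuffled <- fx$variants[rev(seq_len(nrow(fx$variants))), ]
  a <- run_differential(fx$variants, fx$sites, predictor = "replay",
                        replay = fx$replay, keep_unpaired = TRUE)
  b <- run_differential(shuffled, fx$sites, predictor = "replay",
                        replay = fx$replay, keep_unpaired = TRUE)
  expect_equal(a, b)
})

test_that("verdict tables write deterministically and re-read", {
  res <- brca_results()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_verdicts(res$verdicts, p1)
  write_verdicts(res$verdicts, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_verdict_table(p1)
  expect_equal(nrow(back), nrow(res$verdicts))
  expect_equal(back$category, res$verdicts$category)
})
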