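test_that("window extraction clips at the termini", {
  prot <- toy_protein(paste(rep("ACDEF", 4), collapse = ""))  # 20-mer
  w <- extract_window(prot, 6)
  expect_equal(nchar(w$residues), 11L)
  expect_equal(w$offsets, -5:5)
  w2 <- extract_window(prot, 2)
  expect_equal(nchar(w2$residues), 7L)
  expect_equal(w2$offsets, -1:5)
  expect_error(extract_window(prot, 21), class = "phos_range_error")
})

test_that("applying a variant changes exactly one residue and is invertible", {
  # S at centre position 5 of the motif fragment, K at 6
  prot <- toy_protein("FCNKSKQPGL")
  v <- toy_variant("p.K6T")
  mut <- apply_variant(prot, v)
  expect_equal(mut$sequence, "FCNKSTQPGL")
  expect_equal(prot$sequence, "FCNKSKQPGL")  # input untouched
  back <- apply_variant(mut, toy_variant("p.T6K"))
  expect_equal(back$sequence, prot$sequence)

  prot2 <- toy_protein("SRNLSPPNCT")
  expect_equal(apply_variant(prot2, toy_variant("p.P6S"))$sequence,
               "SRNLSSPNCT")
  expect_error(apply_variant(prot, toy_variant("p.A6T")),
               class = "phos_reference_mismatch")
})

test_that("a model equal to its background scores zero everywhere", {
  m <- toy_model(sharpness = 1 / 20)  # uninformative offsets everywhere
  m_flat <- make_kinase_model(".....S.....", 0.9)  # only anchor informative
  prot <- toy_protein("ACDEFSACDEF")
  w <- extract_window(prot, 6)
  expect_equal(score_window(w, m), log2((1 / 20) / (1 / 20)) * 1, tolerance = 1e-12)
  # anchor-only model scores exactly the anchor term
  expect_equal(score_window(w, m_flat), log2(0.9 / 0.05))
})

test_that("a single 4x-background offset scores exactly 2 bits", {
  aa <- aa_alphabet()
  w <- matrix(1 / 20, nrow = 11, ncol = 20, dimnames = list(-5:5, aa))
  w["1", ] <- (1 - 4 / 20) / 19
  w["1", "P"] <- 4 / 20             # 4x the uniform background
  m <- kinase_model("K4X", "S", w)
  win <- extract_window(toy_protein("AAAAASPAAAA"), 6)
  expect_equal(score_window(win, m), 2, tolerance = 1e-12)
})

test_that("scores equal a brute-force per-position log-odds sum on random cases", {
  set.seed(31)
  aa <- aa_alphabet()
  for (i in 1:50) {
    # random model over a random window geometry
    up <- sample(3:5, 1); down <- sample(3:5, 1)
    cfg <- pipeline_config(window_up = up, window_down = down)
    span <- up + down + 1
    w <- matrix(stats::rexp(span * 20), nrow = span)
    w <- w / rowSums(w)
    rownames(w) <- -up:down
    bg <- stats::rexp(20); bg <- bg / sum(bg)
    m <- suppressWarnings(kinase_model("RND", c("S", "T", "Y"), w, background = bg))
    seq <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    pos <- sample(seq_len(30), 1)
    prot <- toy_protein(seq)
    s <- substring(seq, pos, pos)
    substring(seq, pos, pos) <- "S"
    prot <- toy_protein(seq)
    win <- extract_window(prot, pos, cfg)

    # independent brute force: loop offsets, naive arithmetic
    expected <- 0
    chars <- strsplit(seq, "")[[1]]
    for (k in -up:down) {
      p <- pos + k
      if (p < 1 || p > 30) next  # clipped offsets contribute nothing
      res <- chars[[p]]
      expected <- expected +
        log2(m$weights[as.character(k), res] / m$background[[res]])
    }
    expect_equal(score_window(win, m), expected, tolerance = 1e-9)
  }
})

test_that("non-acceptor centres give the distinct NA signal, not a low score", {
  m <- toy_model(acceptors = "S", informative = list(`1` = "P"))
  win <- extract_window(toy_protein("AAAAAYPAAAA"), 6)
  expect_true(is.na(score_window(win, m)))
  expect_equal(nrow(scan_site(toy_protein("AAAAAYPAAAA"), 6, list(m))), 0L)
})

test_that("scan_site applies the threshold and deterministic ordering", {
  hit <- toy_model("BKIN", informative = list(`1` = "P", `2` = "P"))
  weak <- toy_model("AKIN", informative = list(`-1` = "W"))
  prot <- toy_protein("AAAASPPAAAA")  # S at 5 with PP context
  cfg <- pipeline_config()
  out <- scan_site(prot, 5, list(weak, hit), cfg)
  expect_equal(out$kinase, "BKIN")   # weak model under threshold
  expect_true(all(out$score >= cfg$score_threshold))

  # tie-break by name at equal score
  hit2 <- toy_model("AKIN2", informative = list(`1` = "P", `2` = "P"))
  out2 <- scan_site(prot, 5, list(hit, hit2), cfg)
  expect_equal(out2$kinase, c("AKIN2", "BKIN"))

  # raising the threshold never enlarges the prediction set
  for (thr in c(0, 3, 6, 9, 12)) {
    lo <- scan_site(prot, 5, list(weak, hit, hit2),
                    pipeline_config(score_threshold = thr))
    hi <- scan_site(prot, 5, list(weak, hit, hit2),
                    pipeline_config(score_threshold = thr + 3))
    expect_true(all(hi$kinase %in% lo$kinase))
  }
})

test_that("variants outside the window leave site predictions bit-identical", {
  sc <- default_scenario()
  prot <- sc$scen$protein
  site <- sc$scen$sites$position[[3]]
  far <- toy_variant(format_protein_variant(
    substring(prot$sequence, site + 9, site + 9), site + 9, "W"),
    protein_id = prot$id)
  if (far$ref_aa == "W") far <- dplyr::mutate(far, alt_aa = "H",
    token = format_protein_variant(ref_aa, position, "H"))
  mut <- apply_variant(prot, far)
  expect_identical(scan_site(prot, site, sc$models, sc$cfg),
                   scan_site(mut, site, sc$models, sc$cfg))
})

test_that("kinase model libraries round-trip through the text format", {
  models <- default_scenario_models(0.9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_kinase_models(models, path)
  back <- read_kinase_models(path)
  expect_equal(names(back), names(models))
  for (nm in names(models)) {
    expect_equal(back[[nm]]$acceptors, models[[nm]]$acceptors)
    expect_equal(back[[nm]]$offsets, models[[nm]]$offsets)
    expect_equal(back[[nm]]$weights, models[[nm]]$weights, tolerance = 1e-9)
  }
})

test_that("replay lookups reproduce recorded cells and flag unknown queries", {
  fx <- brca_fixture()
  cfg <- pipeline_config()
  wt632 <- replay_predictions(fx$replay, "BRCA1", "p.S632N", "wt", 632, cfg)
  expect_equal(wt632$kinase, "CDK2")
  expect_true(all(wt632$score >= cfg$score_threshold))
  mut632 <- replay_predictions(fx$replay, "BRCA1", "p.S632N", "mut", 632, cfg)
  expect_equal(nrow(mut632), 0L)
  # recorded sub-threshold mutant predictions sit below the cutoff
  sub <- replay_predictions(fx$replay, "BRCA2", "p.D1923A", "mut", 1926, cfg)
  expect_setequal(sub$kinase, c("CSNK2A2", "CK2A1"))
  expect_true(all(sub$score < cfg$score_threshold))
  expect_error(
    replay_predictions(fx$replay, "BRCA1", "p.Q999X", "wt", 1, cfg),
    class = "phos_lookup_error")
})
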