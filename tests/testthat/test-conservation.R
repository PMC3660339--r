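cfg <- pipeline_config()

msa_from <- function(rows) phosimpact:::new_msa(rows)

test_that("column profiles count residues, exclude gaps, and sum to one", {
  m <- msa_from(c("SSS", "SSS", "SST", "S-T"))
  p0 <- column_profile(m, 1, pseudocount = 0)
  expect_equal(p0[["S"]], 1)
  expect_equal(sum(p0), 1)
  p3 <- column_profile(m, 3, pseudocount = 0)
  expect_equal(p3[["S"]], 0.5)
  expect_equal(p3[["T"]], 0.5)
  # gap excluded: column 2 has 3 informative residues
  p2 <- column_profile(m, 2, pseudocount = 0)
  expect_equal(p2[["S"]], 1)
  expect_error(column_profile(msa_from(c("-A", "-A")), 1),
               class = "phos_degenerate_column")
})

test_that("an invariant column makes any other substitution damaging", {
  m <- msa_from(rep(strrep("S", 10), 50))
  tc <- tolerance_call(m, tibble::tibble(position = 5L, alt_aa = "F"), cfg)
  # (0 + 0.1) / (50 + 0.1) against the consensus
  expect_equal(tc$normalized_probability, 0.1 / 50.1, tolerance = 1e-12)
  expect_equal(tc$call, "damaging")

  tc2 <- tolerance_call(m, tibble::tibble(position = 5L, alt_aa = "S"), cfg)
  expect_equal(tc2$normalized_probability, 1)
  expect_equal(tc2$call, "tolerated")
})

test_that("a 40%-frequency alternate residue is tolerated", {
  rows <- c(rep(strrep("S", 6), 30), rep(strrep("N", 6), 20))
  m <- msa_from(rows)
  tc <- tolerance_call(m, tibble::tibble(position = 3L, alt_aa = "N"), cfg)
  expect_equal(tc$normalized_probability, 20.1 / 30.1, tolerance = 1e-12)
  expect_equal(tc$call, "tolerated")
})

test_that("adding sequences carrying the alternate never lowers its probability", {
  base <- rep(strrep("S", 4), 20)
  np <- vapply(0:10, function(k) {
    m <- msa_from(c(base, rep(strrep("F", 4), k)))
    tolerance_call(m, tibble::tibble(position = 2L, alt_aa = "F"),
                   cfg)$normalized_probability
  }, numeric(1))
  expect_true(all(diff(np) >= 0))
})

test_that("median conservation hits its analytic limits", {
  ident <- msa_from(rep(strrep("ACDEFGHIKL", 3), 10))
  mc <- median_conservation(ident, cfg, pseudocount = 0)
  expect_equal(mc$score, log2(20), tolerance = 1e-12)
  expect_false(mc$informative)  # above the reliability window

  # columns uniform over all 20 residues -> zero information
  rows <- vapply(1:20, function(i)
    paste(rep(aa_alphabet()[[i]], 6), collapse = ""), character(1))
  unif <- msa_from(rows)
  mc0 <- median_conservation(unif, cfg, pseudocount = 0)
  expect_equal(mc0$score, 0, tolerance = 1e-12)
  expect_false(mc0$informative)

  expect_error(median_conservation(msa_from("SSSS")), class = "phos_msa_error")

  # per-column information is always inside [0, log2 20]
  sc <- default_scenario()
  msa <- make_msa(sc$scen$protein, 40, 0.7, seed = 3)
  per <- median_conservation(msa, cfg)$per_column
  expect_true(all(per >= 0 & per <= log2(20)))
})

test_that("the lower-median convention is deterministic for even counts", {
  # two distinct column scores; lower of the two middles must be returned
  m <- msa_from(c("SA", "SC", "SG", "ST"))  # col1 invariant, col2 uniform-4
  mc <- median_conservation(m, cfg, pseudocount = 0)
  # lower median of {log2 20 - 2, log2 20} is the smaller column score
  expect_equal(mc$score, log2(20) - 2, tolerance = 1e-12)
})

test_that("the full Grantham table matches direct formula evaluation", {
  props <- phosimpact:::grantham_properties()
  aa <- props$aa
  for (a in aa) {
    for (b in aa) {
      pa <- props[props$aa == a, ]
      pb <- props[props$aa == b, ]
      expected <- 50.723 * sqrt(1.833 * (pa$c - pb$c)^2 +
                                  0.1018 * (pa$p - pb$p)^2 +
                                  0.000399 * (pa$v - pb$v)^2)
      expect_equal(grantham_distance(a, b), expected, tolerance = 1e-9)
      expect_equal(grantham_distance(a, b), grantham_distance(b, a))
    }
    expect_equal(grantham_distance(a, a), 0)
  }
  # published rounded landmarks
  expect_equal(round(grantham_distance("L", "I")), 5)
  expect_equal(round(grantham_distance("R", "K")), 26)
  expect_error(grantham_distance("B", "A"), class = "phos_validation_error")
})

test_that("GV/GD collapse to a point for invariant columns and vanish inside the box", {
  m <- msa_from(rep(strrep("S", 4), 8))
  gg <- gv_gd(m, 2, "S")
  expect_equal(gg$gv, 0)
  expect_equal(gg$gd, 0)
  gg2 <- gv_gd(m, 2, "C")
  expect_equal(gg2$gv, 0)
  expect_equal(gg2$gd, grantham_distance("S", "C"))

  varied <- msa_from(c("SAS", "TAS", "NAS", "DAS"))
  gg3 <- gv_gd(varied, 1, "T")  # observed residue: inside the box
  expect_equal(gg3$gd, 0)
  expect_true(gg3$gv > 0)

  # widening the observed residue set never increases gd
  cols <- list(c("S"), c("S", "T"), c("S", "T", "N"), c("S", "T", "N", "D"))
  gds <- vapply(cols, function(res) {
    m <- msa_from(vapply(res, function(r) strrep(r, 2), character(1)))
    gv_gd(m, 1, "W")$gd
  }, numeric(1))
  expect_true(all(diff(gds) <= 1e-9))
})

test_that("A-GVGD classes are monotone in GD and antitone in GV", {
  expect_equal(agvgd_class(0, 0), "C0")
  expect_equal(agvgd_class(0, 65), "C65")
  expect_equal(agvgd_class(0, 200), "C65")
  expect_equal(agvgd_class(200, 200), "C0")  # highly varied position
  gvs <- c(0, 20, 50, 61.3, 80, 100, 122.4, 150)
  gds <- c(0, 10, 15, 25, 35, 45, 55, 65, 90)
  rank_of <- function(cl) match(cl, c("C0", "C15", "C25", "C35", "C45", "C55", "C65"))
  for (gv in gvs) {
    r <- rank_of(agvgd_class(rep(gv, length(gds)), gds))
    expect_true(all(diff(r) >= 0))
  }
  for (gd in gds) {
    r <- rank_of(agvgd_class(gvs, rep(gd, length(gvs))))
    expect_true(all(diff(r) <= 0))
  }
})

test_that("harmonization is total and reproduces the recorded label column", {
  a_lv <- c("damaging", "tolerated", "missing")
  b_lv <- c("probably_damaging", "possibly_damaging", "benign", "missing")
  grid <- expand.grid(a = a_lv, b = b_lv, stringsAsFactors = FALSE)
  out <- harmonize(grid$a, grid$b)
  expect_true(all(out %in% c("damaging", "likely_damaging", "benign",
                             "not_informative")))
  expect_equal(harmonize("damaging", "probably_damaging"), "damaging")
  expect_equal(harmonize("damaging", "possibly_damaging"), "damaging")
  expect_equal(harmonize("tolerated", "benign"), "benign")
  expect_equal(harmonize("damaging", "benign"), "likely_damaging")
  expect_equal(harmonize("tolerated", "probably_damaging"), "likely_damaging")
  expect_equal(harmonize("missing", "benign"), "not_informative")

  fx <- brca_fixture()
  expect_equal(harmonize(fx$conservation$sift_call, fx$conservation$polyphen_call),
               fx$conservation$harmonized)
})

test_that("conservation profiles assemble calls, GV/GD and the harmonized label", {
  sc <- default_scenario()
  msa <- make_msa(sc$scen$protein, 60,
                  calibrate_msa_conservation(cfg$median_conservation_target),
                  seed = 9)
  v <- sc$variants[sc$variants$label == "abolishing", ][1:3, ]
  prof <- conservation_profile(msa, v, cfg, second_caller = "gd_proxy")
  expect_equal(nrow(prof), 3L)
  expect_true(all(prof$informative))
  expect_true(all(prof$agvgd_class %in%
                    c("C0", "C15", "C25", "C35", "C45", "C55", "C65")))
  expect_true(all(prof$harmonized %in%
                    c("damaging", "likely_damaging", "benign", "not_informative")))
})
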