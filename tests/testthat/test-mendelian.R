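m2 <- genetic_model("model2")
m3 <- genetic_model("model3")

# pedigree with n offspring of a single sire_morph x dam_morph mating
mating_pedigree <- function(sire_morph, dam_morph, n, offspring_morph = "O") {
  pedigree(data.frame(
    id = c("s", "d", sprintf("o%d", seq_len(n))),
    sex = c("male", "female", rep("male", n)),
    generation = c("F0", "F0", rep("F1", n)),
    sire = c(NA, NA, rep("s", n)), dam = c(NA, NA, rep("d", n)),
    morph = c(sire_morph, dam_morph, rep(offspring_morph, n)),
    stringsAsFactors = FALSE))
}

test_that("expected offspring frequencies follow the mixture arithmetic", {
  eq <- zygosity_assumption("equal")
  res <- expected_offspring_frequencies(mating_pedigree("O", "G", 4), m3, eq)
  # per offspring: 0.5 * {all O} + 0.5 * {0.5 O, 0.5 G} = (0.75, 0, 0, 0.25)
  expect_equal(res$expected, c(O = 3, Y = 0, OY = 0, G = 1))
  expect_equal(sum(res$observed), 4)

  # all-grey parents: every offspring expected grey
  res <- expected_offspring_frequencies(mating_pedigree("G", "G", 3, "G"), m3, eq)
  expect_equal(res$expected, c(O = 0, Y = 0, OY = 0, G = 3))

  # expected total always equals the number of phenotyped offspring
  ped <- make_paper_like_fixture(11)
  for (sc in c("equal", "hwe", "threshold")) {
    assumption <- switch(sc,
      equal = eq,
      hwe = zygosity_assumption("hwe",
        allele_freqs = estimate_allele_frequencies(
          morph_counts(ped, function(p) is.na(p$sire)), m3)),
      threshold = zygosity_assumption("threshold"))
    res <- expected_offspring_frequencies(ped, m3, assumption)
    expect_equal(sum(res$expected), res$n, tolerance = 1e-9)
    expect_equal(sum(res$observed), res$n)
  }
})

test_that("offspring with unknown parental morph are skipped symmetrically", {
  ped <- as.data.frame(mating_pedigree("O", "G", 4))
  ped$morph[ped$id == "d"] <- NA
  ped <- pedigree(ped)
  expect_warning(
    res <- expected_offspring_frequencies(ped, m3, zygosity_assumption("equal")),
    "unknown parent morph")
  expect_equal(res$n, 0)
  expect_equal(sum(res$observed), 0)
})

test_that("expected frequencies agree with a Monte-Carlo segregation oracle", {
  set.seed(21)
  eq <- zygosity_assumption("equal")
  ped <- pedigree(data.frame(
    id = c("s1", "d1", "s2", "d2", sprintf("o%d", 1:8)),
    sex = c("male", "female", "male", "female", rep("male", 8)),
    sire = c(NA, NA, NA, NA, rep(c("s1", "s2"), each = 4)),
    dam = c(NA, NA, NA, NA, rep(c("d1", "d2"), each = 4)),
    morph = c("OY", "O", "Y", "G", rep("O", 8)), stringsAsFactors = FALSE))
  res <- expected_offspring_frequencies(ped, m3, eq)
  mc1 <- mc_cross(parental_genotype_distribution("OY", "male", m3, eq),
                  parental_genotype_distribution("O", "female", m3, eq),
                  m3, n = 2e5)
  mc2 <- mc_cross(parental_genotype_distribution("Y", "male", m3, eq),
                  parental_genotype_distribution("G", "female", m3, eq),
                  m3, n = 2e5)
  mc_expected <- 4 * (mc1["male", ] + mc2["male", ])
  expect_equal(unname(res$expected), unname(mc_expected), tolerance = 0.05)
})

test_that("g_test implements the likelihood-ratio statistic", {
  o <- c(O = 21, Y = 13, OY = 12, G = 12)
  expect_equal(g_test(o, o)$G, 0)
  expect_equal(g_test(o, o)$p, 1)

  e <- c(O = 18, Y = 21, OY = 14.63, G = 4.38)
  gt <- g_test(o, e)
  manual <- 2 * sum(o * log(o / e))
  expect_equal(gt$G, manual, tolerance = 1e-12)
  expect_identical(gt$df, 3)
  expect_equal(gt$p, pchisq(manual, 3, lower.tail = FALSE))

  # category order is irrelevant
  perm <- c("G", "OY", "O", "Y")
  expect_equal(g_test(o[perm], e[perm])$G, gt$G)

  # zero observed contributes nothing; zero expected with observed flags
  expect_equal(g_test(c(O = 0, Y = 5, OY = 0, G = 5),
                      c(O = 2, Y = 4, OY = 1, G = 3))$G,
               2 * (5 * log(5 / 4) + 5 * log(5 / 3)), tolerance = 1e-12)
  inc <- g_test(c(O = 1, Y = 5, OY = 0, G = 4), c(O = 0, Y = 5, OY = 1, G = 4))
  expect_true(inc$incompatible)
  expect_identical(inc$G, Inf)
})

test_that("fit_all_models produces the six-row comparison with error paths", {
  ped <- make_paper_like_fixture(5)
  fits <- fit_all_models(ped)
  expect_identical(nrow(fits), 6L)
  expect_setequal(fits$model, c("model2", "model3"))
  expect_identical(sum(fits$best), 1L)
  ok <- fits$evaluable & is.finite(fits$G)
  expect_equal(which.max(ifelse(ok, fits$p, -1)), which(fits$best))
  expect_true(all(fits$G[ok] >= 0))

  # a pedigree without grey anywhere: model2 HWE is not evaluable
  ped2 <- as.data.frame(ped)
  ped2$morph[ped2$morph == "G"] <- "O"
  fits2 <- fit_all_models(pedigree(ped2))
  bad <- fits2[fits2$model == "model2" & fits2$scheme == "hwe", ]
  expect_false(bad$evaluable)
  expect_match(bad$note, "zero grey")
  expect_true(all(fits2$evaluable[!(fits2$model == "model2" &
                                      fits2$scheme == "hwe")]))
})

test_that("model1 exclusion counts offspring matching neither parent", {
  expect_identical(
    model1_exclusion(mating_pedigree("O", "G", 1, "OY"))$n_incompatible, 1L)
  expect_identical(
    model1_exclusion(mating_pedigree("O", "G", 1, "G"))$n_incompatible, 0L)

  # daughters must match their father under Z linkage
  ped <- pedigree(data.frame(
    id = c("s", "d", "f1", "f2"), sex = c("male", "female", "female", "female"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"),
    morph = c("O", "Y", "O", "Y"), stringsAsFactors = FALSE))
  zl <- model1_exclusion(ped, "z_linked")
  expect_identical(zl$n_checked, 2L)
  expect_identical(zl$offending, "f2")

  # data simulated under model1 (homozygous founders) are fully compatible
  set.seed(9)
  cfg <- simulation_config(
    model = genetic_model("model1", dominance = c("O", "OY", "Y", "G")),
    founder_scheme = "homozygous", seed = 99)
  sim <- simulate_pedigree(cfg)
  expect_identical(model1_exclusion(sim$pedigree)$n_incompatible, 0L)
})

test_that("zlinked_exclusion applies the per-model forbidden combinations", {
  dtr <- function(fm, dm) pedigree(data.frame(
    id = c("s", "d", "x"), sex = c("male", "female", "female"),
    sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
    morph = c(fm, "G", dm), stringsAsFactors = FALSE))

  # model3: grey father, non-grey daughter
  expect_identical(zlinked_exclusion(dtr("G", "O"), m3)$n_incompatible, 1L)
  # model3: yellow father cannot give orange-expressing daughters
  expect_identical(zlinked_exclusion(dtr("Y", "OY"), m3)$n_incompatible, 1L)
  expect_identical(zlinked_exclusion(dtr("Y", "Y"), m3)$n_incompatible, 0L)
  # model3: orange father cannot give yellow-expressing daughters
  expect_identical(zlinked_exclusion(dtr("O", "Y"), m3)$n_incompatible, 1L)
  # model2: OY daughters are impossible regardless of the father
  expect_identical(zlinked_exclusion(dtr("OY", "OY"), m2)$n_incompatible, 1L)
  expect_identical(zlinked_exclusion(dtr("O", "G"), m2)$n_incompatible, 0L)
  # per-rule tallies are reported
  rep_ <- zlinked_exclusion(dtr("G", "O"), m3)
  expect_true(is.data.frame(rep_$rules))
  expect_identical(sum(rep_$rules$n_incompatible), 1L)
})
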