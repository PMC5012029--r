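# config for an all-orange world (every individual is O morph and expresses
# orange) with independent family structure: one clutch per dam
family_config <- function(n_fam, h2_orange, h2_yellow = 0.5, seed = NULL) {
  simulation_config(
    model = genetic_model("model3"),
    allele_freqs = list(orange = c(O = 1, o = 0), yellow = c(Y = 1, y = 0)),
    n_sires = n_fam, n_dams = n_fam, n_clutches = n_fam,
    n_offspring = 4 * n_fam,
    h2 = c(orange = h2_orange, yellow = h2_yellow),
    sex_scaling = c(orange = 1, yellow = 1), sex_ratio = 0.5, seed = seed)
}

test_that("midparent_pairs averages parents and pooled expressing offspring", {
  ped <- pedigree(data.frame(
    id = c("s", "d", "o1", "o2"), sex = c("male", "female", "male", "male"),
    clutch = c(NA, NA, "C1", "C2"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"),
    stringsAsFactors = FALSE))
  tt <- data.frame(id = c("s", "d", "o1", "o2"), trait = "orange",
                   raw = 1, effective = 1,
                   transformed = c(0.4, 0.2, 0.3, 0.3), expressed = TRUE)
  mp <- midparent_pairs(ped, tt, "orange")
  expect_identical(nrow(mp), 1L)          # clutches pooled per sire x dam
  expect_equal(mp$midparent, 0.3)
  expect_equal(mp$midoffspring, 0.3)

  # family without expressing offspring is dropped, with a count
  tt2 <- tt[tt$id %in% c("s", "d"), ]
  mp2 <- midparent_pairs(ped, tt2, "orange")
  expect_identical(nrow(mp2), 0L)
  expect_identical(attr(mp2, "n_dropped"), 1L)
})

test_that("parent_offspring_regression is plain OLS with slope-as-h2", {
  pairs <- data.frame(parent_value = c(1, 2, 3, 4),
                      offspring_value = c(1, 2, 3, 4))
  suppressWarnings({  # lm warns on the deliberately perfect fit
    r <- parent_offspring_regression(pairs, "sire")
    rd <- parent_offspring_regression(pairs, "sire", double_single_parent = TRUE)
    rm_ <- parent_offspring_regression(
      data.frame(midparent = 1:4, midoffspring = c(1, 2, 3, 4)), "midparent",
      double_single_parent = TRUE)
  })
  expect_equal(r$slope, 1); expect_equal(r$r2, 1)
  expect_equal(r$h2_reported, 1)
  expect_equal(rd$h2_reported, 2)
  expect_equal(rm_$h2_reported, 1)        # doubling never applies to midparent

  expect_error(parent_offspring_regression(pairs[1:2, ], "sire"), "3 pairs")
  degen <- data.frame(parent_value = rep(1, 5), offspring_value = rnorm(5))
  expect_error(parent_offspring_regression(degen, "sire"), "degenerate")
})

test_that("cross-trait regressions are null when colour genetics are independent", {
  set.seed(71)
  cfg <- family_config(200, 0.5, 0.5, seed = 500)
  sim0 <- simulate_pedigree(cfg)
  hits <- replicate(20, {
    sim <- simulate_quantitative(sim0, cfg, seed = sample.int(2^30, 1))
    tt <- prepare_trait_table(sim$pedigree, zero_policy = "exclude")
    sp <- single_parent_pairs(sim$pedigree, tt, "sire", "orange", "yellow")
    r <- parent_offspring_regression(sp, "sire", "orange", "yellow")
    abs(r$slope) < 2 * r$se_slope
  })
  expect_gte(mean(hits), 0.8)
})

test_that("sex-linkage ANCOVA detects unequal slopes and is calibrated", {
  set.seed(72)
  # split-sib layout: the sire and dam halves carry different offspring of
  # each clutch, so their errors are independent given the clutch effect
  make_pairs <- function(n_fam, b_sire, b_dam, sd_clutch = 0.05, sd_e = 0.15) {
    sv <- rnorm(n_fam); dv <- rnorm(n_fam)
    cl <- rnorm(n_fam, 0, sd_clutch)
    clutch <- sprintf("C%d", seq_len(n_fam))
    mk <- function() b_sire * sv + b_dam * dv + cl + rnorm(n_fam, 0, sd_e)
    list(sire = data.frame(parent_value = sv, offspring_value = mk(),
                           clutch = clutch),
         dam = data.frame(parent_value = dv, offspring_value = mk(),
                          clutch = clutch))
  }

  # power (classical fixed-effects form): unequal slopes are detected;
  # the mixed form is conservative here because parent values are
  # between-clutch (see the roxygen note)
  hits <- replicate(25, {
    p <- make_pairs(50, b_sire = 0.2, b_dam = 0.8)
    ancova_sex_linkage(p$sire, p$dam, "yellow", random_clutch = FALSE)$p < 0.05
  })
  expect_gte(mean(hits), 0.8)

  # calibration: with equal non-zero slopes the co-parent contribution makes
  # the test conservative (never anticonservative) in both forms
  pvals <- replicate(150, {
    p <- make_pairs(40, b_sire = 0.5, b_dam = 0.5)
    c(mixed = ancova_sex_linkage(p$sire, p$dam)$p,
      fixed = ancova_sex_linkage(p$sire, p$dam, random_clutch = FALSE)$p)
  })
  expect_lt(mean(pvals["mixed", ] < 0.05), 0.12)
  expect_lt(mean(pvals["fixed", ] < 0.05), 0.12)

  # with no parent effects at all, the clean null is nominally calibrated
  pvals0 <- replicate(200, {
    p <- make_pairs(40, b_sire = 0, b_dam = 0)
    ancova_sex_linkage(p$sire, p$dam, random_clutch = FALSE)$p
  })
  rate <- mean(pvals0 < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.10)

  # degrees of freedom follow the pooled fixed-effect layout (n - 4)
  p <- make_pairs(27, 0.5, 0.5)
  a <- ancova_sex_linkage(p$sire, p$dam)
  expect_identical(a$df_num, 1L)
  expect_identical(a$df_den, 2L * 27L - 4L)

  # a duplicated shared response per clutch degenerates the mixed fit and
  # falls back to the fixed-effects ANCOVA with a note
  sh <- make_pairs(30, 0.2, 0.8)
  sh$dam$offspring_value <- sh$sire$offspring_value
  a2 <- ancova_sex_linkage(sh$sire, sh$dam)
  expect_match(a2$note, "fixed-effects")

  # degenerate predictor errors out
  z <- data.frame(parent_value = rep(1, 10), offspring_value = rnorm(10),
                  clutch = "C1")
  expect_error(ancova_sex_linkage(z, z), "degenerate")
})
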