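m2 <- genetic_model("model2")
m3 <- genetic_model("model3")
m2z <- genetic_model("model2", "z_linked")
m3z <- genetic_model("model3", "z_linked")

test_that("genotype spaces enumerate each architecture completely", {
  expect_setequal(genotype_space(m2), c("OO", "OG", "OY", "YY", "YG", "GG"))
  expect_length(genotype_space(m3), 9)
  expect_setequal(genotype_space(m2z, "female"), c("O", "Y", "G"))
  expect_setequal(genotype_space(m3z, "female"), c("OY", "Oy", "oY", "oy"))
  expect_length(genotype_space(m3z, "male"), 9)  # males are ZZ diploid
  expect_false(anyDuplicated(genotype_space(m3)) > 0)
})

test_that("phenotype_of maps genotypes to morphs as each model specifies", {
  expect_identical(phenotype_of(c("OO", "OG"), m2), c("O", "O"))
  expect_identical(phenotype_of(c("YY", "YG"), m2), c("Y", "Y"))
  expect_identical(phenotype_of("OY", m2), "OY")
  expect_identical(phenotype_of("GG", m2), "G")
  expect_identical(phenotype_of(c("OoYy", "OOYy", "OoYY", "OOYY"), m3),
                   rep("OY", 4))
  expect_identical(phenotype_of(c("OOyy", "Ooyy"), m3), c("O", "O"))
  expect_identical(phenotype_of(c("ooYy", "ooYY"), m3), c("Y", "Y"))
  expect_identical(phenotype_of("ooyy", m3), "G")
  # hemizygous females express their single Z haplotype
  expect_identical(phenotype_of(c("O", "Y", "G"), m2z), c("O", "Y", "G"))
  expect_identical(phenotype_of(c("OY", "Oy", "oY", "oy"), m3z),
                   c("OY", "O", "Y", "G"))
  # model1 heterozygotes need an explicit dominance order
  m1 <- genetic_model("model1")
  expect_error(phenotype_of("O/Y", m1), "dominance")
  m1d <- genetic_model("model1", dominance = c("O", "OY", "Y", "G"))
  expect_identical(phenotype_of(c("O/Y", "Y/G", "G/G"), m1d), c("O", "Y", "G"))
})

test_that("parental genotype distributions honour the zygosity schemes", {
  eq <- zygosity_assumption("equal")
  expect_equal(parental_genotype_distribution("O", "male", m3, eq),
               c(OOyy = 0.5, Ooyy = 0.5))
  expect_equal(parental_genotype_distribution("G", "male", m2, eq), c(GG = 1))
  expect_equal(parental_genotype_distribution("OY", "male", m2, eq), c(OY = 1))
  # OY under model3: independent 50:50 at each locus
  d <- parental_genotype_distribution("OY", "male", m3, eq)
  expect_equal(d[order(names(d))],
               c(OOYY = .25, OOYy = .25, OoYY = .25, OoYy = .25)[sort(names(d))])

  # HWE at p = 0.5: P(hom | expressed) = p^2 / (p^2 + 2pq) = 1/3
  af <- list(orange = c(O = 0.5, o = 0.5), yellow = c(Y = 0.5, y = 0.5))
  hw <- zygosity_assumption("hwe", allele_freqs = af)
  expect_equal(parental_genotype_distribution("O", "male", m3, hw),
               c(OOyy = 1/3, Ooyy = 2/3), tolerance = 1e-12)

  # threshold: above the reference mean -> homozygous; ties -> heterozygous
  th <- zygosity_assumption("threshold",
                            reference_means = c(orange = 0.3, yellow = 0.3))
  ind_hi <- list(sex = "male", prop_orange = 0.4, effective_yellow = 0.1)
  ind_tie <- list(sex = "male", prop_orange = 0.3, effective_yellow = 0.1)
  expect_equal(parental_genotype_distribution("O", "male", m3, th, ind_hi),
               c(OOyy = 1))
  expect_equal(parental_genotype_distribution("O", "male", m3, th, ind_tie),
               c(Ooyy = 1))

  # scheme-specific failure modes
  expect_error(zygosity_assumption("hwe"), "allele_freqs")
  expect_error(parental_genotype_distribution("O", "male", m3, th), "proportions")
  expect_error(parental_genotype_distribution("OY", "female", m2z, eq),
               "OY female")
  # every distribution sums to 1 and is supported on the right phenotype
  for (mo in c("O", "Y", "OY", "G")) {
    d <- parental_genotype_distribution(mo, "male", m3, eq)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(phenotype_of(names(d), m3) == mo))
  }
})

test_that("allele frequencies are estimated by the HWE moment formulas", {
  cnt <- c(O = 25, Y = 25, OY = 25, G = 25)
  af3 <- estimate_allele_frequencies(cnt, m3)
  expect_equal(unname(af3$orange["o"]), sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(af3$yellow["y"]), sqrt(0.5), tolerance = 1e-12)

  allg <- estimate_allele_frequencies(c(O = 0, Y = 0, OY = 0, G = 10), m3)
  expect_equal(unname(allg$orange["o"]), 1)

  af2 <- estimate_allele_frequencies(cnt, m2)
  pre <- c(o = sqrt(0.25 + 0.25) - 0.5, y = sqrt(0.25 + 0.25) - 0.5, g = 0.5)
  expect_equal(unname(af2), unname(pre / sum(pre)), tolerance = 1e-12)
  expect_equal(sum(af2), 1)

  expect_error(
    estimate_allele_frequencies(c(O = 10, Y = 10, OY = 10, G = 0), m2),
    "zero grey")

  # fixed point: HWE phenotype freqs -> estimates -> same phenotype freqs
  p_o <- 0.35; p_y <- 0.3
  f <- c(O = (1 - (1 - p_o)^2) * (1 - p_y)^2,
         Y = (1 - p_o)^2 * (1 - (1 - p_y)^2),
         OY = (1 - (1 - p_o)^2) * (1 - (1 - p_y)^2),
         G = (1 - p_o)^2 * (1 - p_y)^2)
  af <- estimate_allele_frequencies(f * 1000, m3)
  expect_equal(unname(af$orange["O"]), p_o, tolerance = 1e-9)
  expect_equal(unname(af$yellow["Y"]), p_y, tolerance = 1e-9)
})

test_that("cross enumerates matings exactly", {
  # model2 heterozygote x heterozygote Punnett square
  out <- cross(c(OG = 1), c(YG = 1), m2)
  expect_equal(out["male", ], c(O = .25, Y = .25, OY = .25, G = .25))
  expect_equal(out["male", ], out["female", ])

  # double homozygote cross: all offspring OY
  out <- cross(c(OOYY = 1), c(ooyy = 1), m3)
  expect_equal(unname(out[, "OY"]), c(1, 1))

  # mixtures: model3 equal O sire x G dam -> (0.75, 0, 0, 0.25)
  eq <- zygosity_assumption("equal")
  sd_ <- parental_genotype_distribution("O", "male", m3, eq)
  dd_ <- parental_genotype_distribution("G", "female", m3, eq)
  out <- cross(sd_, dd_, m3)
  expect_equal(out["male", ], c(O = 0.75, Y = 0, OY = 0, G = 0.25))

  # outputs are probability vectors for random inputs
  set.seed(7)
  for (model in list(m2, m3, m2z, m3z)) {
    for (k in 1:10) {
      out <- cross(random_genotype_dist(model, "male"),
                   random_genotype_dist(model, "female"), model)
      expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
      expect_true(all(out >= 0))
    }
  }

  # Z-linked model2: daughters are hemizygous, never OY
  set.seed(8)
  for (k in 1:20) {
    out <- cross(random_genotype_dist(m2z, "male"),
                 random_genotype_dist(m2z, "female"), m2z)
    expect_equal(unname(out["female", "OY"]), 0)
  }

  # sex-mismatched distribution under Z linkage is rejected
  expect_error(cross(c(OG = 1), c(YG = 1), m2z), "genotype space")
})
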