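# Shared fixtures and independent oracles for the test suite.

# Minimal trio pedigree: unrelated sire and dam, one offspring.
trio_pedigree <- function(sire_morph = "O", dam_morph = "G",
                          child_morph = "O", child_sex = "male") {
  pedigree(data.frame(
    id = c("s", "d", "c"),
    sex = c("male", "female", child_sex),
    generation = c("F0", "F0", "F1"),
    cohort = c("founder", "founder", "2012-2013"),
    clutch = c(NA, NA, "C1"),
    sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
    prop_orange = c(0.3, 0.01, 0.25), prop_yellow = c(0.01, 0.02, 0.01),
    morph = c(sire_morph, dam_morph, child_morph),
    stringsAsFactors = FALSE))
}

# A small multi-family pedigree used by I/O and counting tests.
small_pedigree <- function() {
  make_paper_like_fixture(seed = 303)
}

# --- independent Monte-Carlo gamete oracle for cross() --------------------
# Simulates gamete draws allele-by-allele with its own (deliberately
# re-derived) phenotype rules, so it shares no code path with cross().

oracle_parse <- function(geno, model_name) {
  ch <- strsplit(geno, "", fixed = TRUE)[[1]]
  if (model_name == "model2") return(list(ch))      # one locus, 1-2 alleles
  if (length(ch) == 4) list(ch[1:2], ch[3:4]) else list(ch[1], ch[2])
}

# Per-locus allele matrices (support genotypes x 1 or 2 allele columns).
oracle_support <- function(dist_names, model_name) {
  parsed <- lapply(dist_names, oracle_parse, model_name = model_name)
  n_loci <- length(parsed[[1]])
  lapply(seq_len(n_loci), function(l)
    do.call(rbind, lapply(parsed, function(p) p[[l]])))
}

# Vectorised gamete draw: one allele per locus for each of n draws.
oracle_gametes <- function(support, gi, n) {
  lapply(support, function(m) {
    col <- if (ncol(m) == 2) 1L + stats::rbinom(n, 1, 0.5) else rep(1L, n)
    m[cbind(gi, col)]
  })
}

oracle_morph_vec <- function(orange_on, yellow_on) {
  out <- rep("G", length(orange_on))
  out[orange_on & !yellow_on] <- "O"
  out[!orange_on & yellow_on] <- "Y"
  out[orange_on & yellow_on] <- "OY"
  out
}

# Monte-Carlo oracle for cross(): per-sex morph frequencies over n offspring,
# simulated allele-by-allele independently of the analytic enumeration.
mc_cross <- function(sire_dist, dam_dist, model, n = 1e5) {
  gs <- sample(seq_along(sire_dist), n, replace = TRUE, prob = sire_dist)
  gd <- sample(seq_along(dam_dist), n, replace = TRUE, prob = dam_dist)
  sup_s <- oracle_support(names(sire_dist), model$name)
  sup_d <- oracle_support(names(dam_dist), model$name)
  pat <- oracle_gametes(sup_s, gs, n)
  mat <- oracle_gametes(sup_d, gd, n)  # hemizygous dams have 1 column
  if (model$name == "model2") {
    son_o <- pat[[1]] == "O" | mat[[1]] == "O"
    son_y <- pat[[1]] == "Y" | mat[[1]] == "Y"
    dau_o <- pat[[1]] == "O"; dau_y <- pat[[1]] == "Y"
  } else {
    son_o <- pat[[1]] == "O" | mat[[1]] == "O"
    son_y <- pat[[2]] == "Y" | mat[[2]] == "Y"
    dau_o <- pat[[1]] == "O"; dau_y <- pat[[2]] == "Y"
  }
  son <- oracle_morph_vec(son_o, son_y)
  daughter <- if (model$linkage == "autosomal") son
              else oracle_morph_vec(dau_o, dau_y)
  rbind(male = table(factor(son, c("O", "Y", "OY", "G"))) / n,
        female = table(factor(daughter, c("O", "Y", "OY", "G"))) / n)
}

# Random genotype distribution over a model's genotype space for one sex.
random_genotype_dist <- function(model, sex) {
  space <- genotype_space(model, sex)
  w <- stats::rexp(length(space))
  stats::setNames(w / sum(w), space)
}

# Verify Mendelian allele transmission for every offspring of a simulation.
check_allele_conservation <- function(ped, genotypes, model) {
  ok <- TRUE
  for (i in which(!is.na(ped$sire) & !is.na(ped$dam))) {
    off <- morphherit:::geno_alleles(genotypes[[ped$id[i]]], model)[[1]]
    sire <- morphherit:::geno_alleles(genotypes[[ped$sire[i]]], model)[[1]]
    dam <- morphherit:::geno_alleles(genotypes[[ped$dam[i]]], model)[[1]]
    if (model$name != "model3") { off <- list(off); sire <- list(sire); dam <- list(dam) }
    for (l in seq_along(off)) {
      a <- off[[l]]
      if (length(a) == 2) {
        comp <- (a[1] %in% sire[[l]] && a[2] %in% dam[[l]]) ||
                (a[2] %in% sire[[l]] && a[1] %in% dam[[l]])
      } else {
        comp <- a %in% sire[[l]]  # hemizygous daughter: paternal Z
      }
      if (!comp) ok <- FALSE
    }
  }
  ok
}
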