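# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulation configuration
#'
#' Describes the breeding design and genetic architecture to simulate. The
#' defaults emulate the package's reference study design: 23 sires and 17
#' dams (wild-caught adults), 25 clutches, 58 offspring over two cohorts
#' with a slight male bias, a two-locus dominant architecture with founder
#' allele frequencies matched to the adult morph frequencies (9 G, 9 O, 14
#' OY, 8 Y of 40), reduced female colour expression (2/3 for orange, 1/2 for
#' yellow, applied on the proportion scale), and additive-genetic plus
#' residual variation of transformed colour proportions.
#'
#' @param model A [genetic_model()].
#' @param allele_freqs Founder allele frequencies. For model3 a list
#'   `orange = c(O=,o=)`, `yellow = c(Y=,y=)`; for model2 `c(O=,Y=,G=)`; for
#'   model1 morph-allele frequencies `c(O=,Y=,OY=,G=)`.
#' @param founder_scheme `"hwe"`: founder genotypes drawn allele-wise at
#'   Hardy-Weinberg proportions; `"by_morph_equal"`: founder morphs drawn
#'   from `founder_morph_freqs`, genotypes then drawn with 50:50 per-locus
#'   zygosity (the "equal" assumption made true); `"homozygous"` (model1):
#'   founders homozygous for the allele matching their drawn morph.
#' @param founder_morph_freqs Morph probabilities used by the
#'   `by_morph_equal`/`homozygous` schemes.
#' @param n_sires,n_dams,n_clutches,n_offspring Design sizes.
#' @param h2,V_p,trait_means Named vectors over `orange`/`yellow`: narrow
#'   sense heritability, phenotypic variance and mean of the transformed
#'   trait among expressing individuals (radians). The yellow trait is the
#'   effective yellow (orange + yellow in OY morphs), which by construction
#'   sits above orange plus the yellow expression threshold, hence its
#'   higher default mean; defaults correspond to roughly 27% orange and 61%
#'   effective yellow coverage with sd ~0.14 rad.
#' @param sex_scaling Female expression multipliers on the proportion scale.
#' @param thresholds An [expression_thresholds()].
#' @param sex_ratio Probability an offspring is male.
#' @param prop_unsexed Probability an offspring remains unsexed.
#' @param seed Integer seed (reproducible output) or `NULL`.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(model = genetic_model("model3"),
                              allele_freqs = NULL,
                              founder_scheme = c("hwe", "by_morph_equal",
                                                 "homozygous"),
                              founder_morph_freqs = c(O = 9, Y = 8, OY = 14,
                                                      G = 9) / 40,
                              n_sires = 23, n_dams = 17,
                              n_clutches = 25, n_offspring = 58,
                              h2 = c(orange = 0.84, yellow = 0.67),
                              V_p = c(orange = 0.02, yellow = 0.02),
                              trait_means = c(orange = 0.55, yellow = 0.90),
                              sex_scaling = c(orange = 2/3, yellow = 0.5),
                              thresholds = expression_thresholds(),
                              sex_ratio = 0.58,
                              prop_unsexed = 0.0,
                              seed = NULL) {
  founder_scheme <- match.arg(founder_scheme)
  if (is.null(allele_freqs)) {
    allele_freqs <- switch(model$name,
      # q_o = sqrt((G+Y)/N), q_y = sqrt((G+O)/N) from the default adult counts
      model3 = list(orange = c(O = 1 - sqrt(0.425), o = sqrt(0.425)),
                    yellow = c(Y = 1 - sqrt(0.45), y = sqrt(0.45))),
      model2 = c(O = 0.25, Y = 0.25, G = 0.5),
      model1 = c(O = 0.225, Y = 0.2, OY = 0.35, G = 0.225))
  }
  stopifnot(all(h2 >= 0 & h2 <= 1), all(V_p > 0),
            sex_ratio >= 0, sex_ratio <= 1, n_clutches >= max(1, n_dams %/% 2))
  structure(list(model = model, allele_freqs = allele_freqs,
                 founder_scheme = founder_scheme,
                 founder_morph_freqs = founder_morph_freqs,
                 n_sires = n_sires, n_dams = n_dams,
                 n_clutches = n_clutches, n_offspring = n_offspring,
                 h2 = h2, V_p = V_p, trait_means = trait_means,
                 sex_scaling = sex_scaling, thresholds = thresholds,
                 sex_ratio = sex_ratio, prop_unsexed = prop_unsexed,
                 seed = seed),
            class = "simulation_config")
}

# Draw one founder genotype given its sex.
draw_founder_genotype <- function(config, sex) {
  model <- config$model
  af <- config$allele_freqs
  hemi <- model$linkage == "z_linked" && sex == "female"
  if (config$founder_scheme == "hwe") {
    draw_locus <- function(freqs) {
      k <- if (hemi) 1 else 2
      sample(names(freqs), k, replace = TRUE, prob = freqs)
    }
    loci <- if (model$name == "model3") list(draw_locus(af$orange),
                                             draw_locus(af$yellow))
            else list(draw_locus(af))
    make_geno(loci, model)
  } else {
    morph <- sample(MORPHS, 1, prob = config$founder_morph_freqs[MORPHS])
    if (config$founder_scheme == "homozygous") {
      loci <- if (hemi) list(morph) else list(c(morph, morph))
      make_geno(loci, model)
    } else {
      if (hemi && model$name == "model2" && morph == "OY")
        morph <- sample(c("O", "Y"), 1)  # OY female impossible when hemizygous
      d <- parental_genotype_distribution(morph, sex, model,
                                          zygosity_assumption("equal"))
      sample(names(d), 1, prob = d)
    }
  }
}

# One offspring genotype from parental genotypes, honouring ZW transmission.
transmit <- function(sire_geno, dam_geno, sex, model) {
  gp <- gametes(sire_geno, model)
  pat <- sample(names(gp), 1, prob = gp)
  if (model$linkage == "z_linked") {
    if (sex == "female") return(hemi_geno(pat, model))
    mat <- names(gametes(dam_geno, model))  # dam's single Z haplotype
    return(zygote(pat, mat, model))
  }
  gm <- gametes(dam_geno, model)
  mat <- sample(names(gm), 1, prob = gm)
  zygote(pat, mat, model)
}

#' Simulate a breeding pedigree with Mendelian morph transmission
#'
#' Generates founders (sires and dams) with genotypes per the configured
#' founder scheme, assigns clutches to dams (each dam at least one clutch,
#' extras to randomly chosen dams) and sires to clutches (all sires used
#' before any repeats), distributes the configured number of offspring over
#' clutches and two cohorts, transmits genotypes by Mendelian segregation
#' (ZW-aware under Z linkage), and sets each individual's morph to the
#' phenotype of its genotype.
#'
#' @param config A [simulation_config()].
#' @return List with `pedigree` (a [pedigree()]; no colour proportions yet,
#'   see [simulate_quantitative()]) and `truth` (genotypes, config echo).
#' @export
simulate_pedigree <- function(config) {
  with_seed(config$seed, {
    model <- config$model
    sires <- sprintf("S%02d", seq_len(config$n_sires))
    dams <- sprintf("D%02d", seq_len(config$n_dams))
    geno <- c(
      stats::setNames(vapply(sires, function(i)
        draw_founder_genotype(config, "male"), ""), sires),
      stats::setNames(vapply(dams, function(i)
        draw_founder_genotype(config, "female"), ""), dams))

    # clutch -> dam: every dam once, remaining clutches to random dams
    extra <- config$n_clutches - config$n_dams
    clutch_dam <- c(dams, if (extra > 0) sample(dams, extra, replace = extra > length(dams)))
    clutch_dam <- clutch_dam[seq_len(config$n_clutches)]
    # clutch -> sire: use all sires before repeating any
    reps <- ceiling(config$n_clutches / config$n_sires)
    clutch_sire <- unlist(lapply(seq_len(reps), function(i) sample(sires)))
    clutch_sire <- clutch_sire[seq_len(config$n_clutches)]

    sizes <- rep(config$n_offspring %/% config$n_clutches, config$n_clutches)
    rem <- config$n_offspring - sum(sizes)
    if (rem > 0) {
      ix <- sample(config$n_clutches, rem)
      sizes[ix] <- sizes[ix] + 1
    }
    cohort_of <- rep(c("2012-2013", "2013-2014"),
                     c(ceiling(config$n_clutches * 2 / 3),
                       config$n_clutches - ceiling(config$n_clutches * 2 / 3)))

    rows <- data.frame(
      id = c(sires, dams), sex = rep(c("male", "female"),
                                     c(length(sires), length(dams))),
      generation = "F0", cohort = "founder", clutch = NA_character_,
      sire = NA_character_, dam = NA_character_, stringsAsFactors = FALSE)
    k <- 0
    off <- list()
    for (cl in seq_len(config$n_clutches)) {
      for (j in seq_len(sizes[cl])) {
        k <- k + 1
        u <- stats::runif(1)
        sex <- if (u < config$prop_unsexed) "unknown"
               else if (stats::runif(1) < config$sex_ratio) "male" else "female"
        id <- sprintf("O%03d", k)
        gsex <- if (sex == "unknown") sample(c("male", "female"), 1) else sex
        g <- transmit(geno[[clutch_sire[cl]]], geno[[clutch_dam[cl]]], gsex,
                      model)
        geno[[id]] <- g
        off[[k]] <- data.frame(
          id = id, sex = sex, generation = "F1", cohort = cohort_of[cl],
          clutch = sprintf("C%02d", cl), sire = clutch_sire[cl],
          dam = clutch_dam[cl], stringsAsFactors = FALSE)
      }
    }
    rows <- rbind(rows, do.call(rbind, off))
    rows$morph <- phenotype_of(geno[rows$id], model)
    ped <- pedigree(rows)
    list(pedigree = ped,
         truth = list(genotypes = geno, model = model$name,
                      config = config, breeding_values = NULL))
  })
}

#' Attach quantitative colour proportions to a simulated pedigree
#'
#' Simulates additive-genetic trait variation on the arcsine-square-root
#' scale: founder breeding values are N(0, h2 * V_p); an offspring's
#' breeding value is the mid-parent value plus a Mendelian-sampling deviate
#' with variance Va/2 (parental inbreeding ignored by default, appropriate
#' for founder-heavy designs). An individual whose morph expresses a colour
#' receives transformed value `trait_mean + breeding value + residual`
#' (residual variance `(1 - h2) * V_p`), back-transformed to a proportion
#' via `sin^2`; female proportions are then multiplied by the sex-expression
#' scaling. Morph-inconsistent draws are clamped to the expression threshold
#' so that re-classification recovers the simulated morph; non-expressed
#' colours receive below-threshold background noise.
#'
#' For OY individuals the yellow trait is simulated as effective yellow
#' (orange overlays yellow), and the stored `prop_yellow` is the visible
#' remainder.
#'
#' @param sim Output of [simulate_pedigree()] (list with `pedigree`,
#'   `truth`), or a [pedigree()] plus `truth = NULL`.
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed` (offset internally so
#'   trait noise differs from pedigree generation).
#' @return `sim` with proportions filled into the pedigree and breeding
#'   values recorded in `truth$breeding_values` (matrix ids x traits).
#' @export
simulate_quantitative <- function(sim, config, seed = NULL) {
  ped <- if (inherits(sim, "pedigree")) sim else sim$pedigree
  truth <- if (inherits(sim, "pedigree")) list() else sim$truth
  use_seed <- seed %||% (if (!is.null(config$seed)) config$seed + 1L else NULL)
  with_seed(use_seed, {
    n <- nrow(ped)
    ord <- check_acyclic(ped)
    pos <- stats::setNames(seq_len(n), ped$id)
    thr <- config$thresholds

    # breeding values, processed founders-first in generation waves
    bv <- matrix(NA_real_, n, 2, dimnames = list(ped$id, c("orange", "yellow")))
    si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
    di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
    for (tr in c("orange", "yellow")) {
      Va <- config$h2[[tr]] * config$V_p[[tr]]
      done <- si == 0L | di == 0L
      bv[done, tr] <- stats::rnorm(sum(done), 0, sqrt(Va))
      while (any(!done)) {
        ready <- !done & !is.na(bv[pmax(si, 1L), tr]) &
          !is.na(bv[pmax(di, 1L), tr])
        if (!any(ready)) stop("pedigree not topologically orderable")
        bv[ready, tr] <- 0.5 * (bv[si[ready], tr] + bv[di[ready], tr]) +
          stats::rnorm(sum(ready), 0, sqrt(Va / 2))
        done <- done | ready
      }
    }

    expressing <- cbind(orange = ped$morph %in% c("O", "OY"),
                        yellow = ped$morph %in% c("Y", "OY"))
    vals <- matrix(NA_real_, n, 2, dimnames = list(ped$id, c("orange", "yellow")))
    for (tr in c("orange", "yellow")) {
      Ve <- (1 - config$h2[[tr]]) * config$V_p[[tr]]
      t_ <- config$trait_means[[tr]] + bv[, tr] + stats::rnorm(n, 0, sqrt(Ve))
      p_ <- sin(pmin(pmax(t_, 0), pi / 2))^2
      female <- ped$sex == "female"
      p_[female] <- p_[female] * config$sex_scaling[[tr]]
      vals[, tr] <- p_
    }

    juv <- ped$generation == "F1"  # colour induced at juvenile stage handled
    tho <- threshold_for("orange", "adult", thr)
    thy <- threshold_for("yellow", "adult", thr)

    prop_o <- ifelse(expressing[, "orange"], pmax(vals[, "orange"], tho),
                     stats::runif(n, 0, 0.8 * tho))
    eff_y <- ifelse(expressing[, "yellow"], pmax(vals[, "yellow"], thy),
                    stats::runif(n, 0, 0.8 * thy))
    # OY: stored yellow is effective yellow minus the overlaying orange
    prop_y <- ifelse(ped$morph == "OY",
                     pmax(eff_y - prop_o, thy), eff_y)
    # keep proportions valid: cap the pair into the simplex
    tot <- prop_o + prop_y
    over <- tot > 1
    prop_o[over] <- prop_o[over] / tot[over]
    prop_y[over] <- prop_y[over] / tot[over]

    ped$prop_orange <- round(prop_o, 6)
    ped$prop_yellow <- round(prop_y, 6)
    truth$breeding_values <- bv
    truth$config <- config
    list(pedigree = pedigree(as.data.frame(ped)), truth = truth)
  })
}

#' Deterministic study-scale fixture pedigree
#'
#' Builds a two-generation pedigree with the reference design's structure
#' and exactly its published morph margins: 23 sires (7 G, 4 O, 8 OY, 4 Y),
#' 17 dams (2 G, 5 O, 6 OY, 4 Y), 25 clutches and 58 offspring in two
#' cohorts (first cohort 23 males + 16 females, second 9 males + 7 females +
#' 3 unsexed), with offspring morph counts matching the published per-cohort
#' frequency table. Pairings, clutch membership and colour proportions are
#' pseudo-random under `seed`; morph margins are exact by construction.
#' Because the true sire-dam pairing table is unpublished, pairing-dependent
#' statistics of the original study are not reproduced.
#'
#' @param seed Integer seed.
#' @return A [pedigree()].
#' @export
make_paper_like_fixture <- function(seed = 1) {
  with_seed(seed, {
    sire_morphs <- sample(rep(c("G", "O", "OY", "Y"), c(7, 4, 8, 4)))
    dam_morphs <- sample(rep(c("G", "O", "OY", "Y"), c(2, 5, 6, 4)))
    sires <- sprintf("S%02d", 1:23)
    dams <- sprintf("D%02d", 1:17)

    clutch_dam <- c(dams, sample(dams, 8))
    clutch_sire <- c(sample(sires), sample(sires, 2))
    cohort_of <- rep(c("2012-2013", "2013-2014"), c(17, 8))

    # per-cohort offspring sex x morph counts from the reference table
    off_spec <- rbind(
      expand_spec("2012-2013", "male", c(G = 5, O = 7, OY = 2, Y = 9)),
      expand_spec("2012-2013", "female", c(G = 5, O = 4, OY = 5, Y = 2)),
      expand_spec("2013-2014", "male", c(G = 1, O = 5, OY = 2, Y = 1)),
      expand_spec("2013-2014", "female", c(G = 1, O = 2, OY = 3, Y = 1)),
      expand_spec("2013-2014", "unknown", c(O = 3)))

    # allocate offspring to clutches of their cohort
    rows <- list()
    for (co in c("2012-2013", "2013-2014")) {
      cl_ix <- which(cohort_of == co)
      members <- off_spec[off_spec$cohort == co, ]
      members <- members[sample(nrow(members)), ]
      # at least one offspring per clutch, remainder random
      assign <- c(cl_ix, sample(cl_ix, nrow(members) - length(cl_ix),
                                replace = TRUE))
      members$clutch <- assign[seq_len(nrow(members))]
      rows[[co]] <- members
    }
    off <- do.call(rbind, rows)
    off$id <- sprintf("O%03d", seq_len(nrow(off)))

    ped_df <- rbind(
      data.frame(id = sires, sex = "male", generation = "F0",
                 cohort = "founder", clutch = NA_character_,
                 sire = NA_character_, dam = NA_character_,
                 morph = sire_morphs, stringsAsFactors = FALSE),
      data.frame(id = dams, sex = "female", generation = "F0",
                 cohort = "founder", clutch = NA_character_,
                 sire = NA_character_, dam = NA_character_,
                 morph = dam_morphs, stringsAsFactors = FALSE),
      data.frame(id = off$id, sex = off$sex, generation = "F1",
                 cohort = off$cohort,
                 clutch = sprintf("C%02d", off$clutch),
                 sire = clutch_sire[off$clutch], dam = clutch_dam[off$clutch],
                 morph = off$morph, stringsAsFactors = FALSE))

    # morph-consistent colour proportions (adult thresholds)
    thr <- expression_thresholds()
    n <- nrow(ped_df)
    po <- ifelse(ped_df$morph %in% c("O", "OY"),
                 stats::runif(n, 0.10, 0.45), stats::runif(n, 0, 0.015))
    py <- ifelse(ped_df$morph %in% c("Y", "OY"),
                 stats::runif(n, 0.10, 0.40), stats::runif(n, 0, 0.035))
    ped_df$prop_orange <- round(po, 6)
    ped_df$prop_yellow <- round(py, 6)
    pedigree(ped_df)
  })
}

expand_spec <- function(cohort, sex, counts) {
  data.frame(cohort = cohort, sex = sex,
             morph = rep(names(counts), counts), stringsAsFactors = FALSE)
}
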