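#' Parental zygosity assumption schemes
#'
#' A phenotypically orange or yellow parent may be homozygous or heterozygous
#' at the colour locus; its genotype cannot be read off the phenotype. Three
#' schemes assign homozygote/heterozygote probabilities:
#' \describe{
#'   \item{equal}{50:50 homozygous vs heterozygous.}
#'   \item{hwe}{probabilities implied by population allele frequencies at
#'     Hardy-Weinberg equilibrium (supply `allele_freqs`, e.g. from
#'     [estimate_allele_frequencies()]).}
#'   \item{threshold}{deterministic: an individual expressing strictly more
#'     than the population mean proportion of the colour is called
#'     homozygous, otherwise (ties included) heterozygous. Requires
#'     per-individual proportions and `reference_means`.}
#' }
#'
#' @param scheme One of `"equal"`, `"hwe"`, `"threshold"`.
#' @param allele_freqs For `hwe`: allele frequencies as returned by
#'   [estimate_allele_frequencies()].
#' @param reference_means For `threshold`: named list per sex
#'   (`male`, `female`), each a named vector `c(orange = , yellow = )` of
#'   mean observed proportions; or a single such vector applied to both
#'   sexes.
#' @return Object of class `zygosity_assumption`.
#' @export
zygosity_assumption <- function(scheme = c("equal", "hwe", "threshold"),
                                allele_freqs = NULL,
                                reference_means = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "hwe" && is.null(allele_freqs))
    stop("hwe scheme requires allele_freqs", call. = FALSE)
  if (!is.null(reference_means) && !is.list(reference_means))
    reference_means <- list(male = reference_means, female = reference_means)
  structure(list(scheme = scheme, allele_freqs = allele_freqs,
                 reference_means = reference_means),
            class = "zygosity_assumption")
}

#' Estimate allele frequencies from adult morph counts
#'
#' Moment estimators assuming Hardy-Weinberg proportions in the reference
#' adults. Writing `f_O, f_Y, f_OY, f_G` for the phenotype fractions:
#' \describe{
#'   \item{model3}{individuals without yellow (G or O phenotype) are `yy`, so
#'     `freq(y) = sqrt(f_G + f_O)`; likewise `freq(o) = sqrt(f_G + f_Y)`.}
#'   \item{model2}{`freq(G) = sqrt(f_G)`; orange phenotypes have frequency
#'     `o^2 + 2og`, so `freq(O) = sqrt(f_O + g^2) - g` (and similarly for
#'     yellow); the three estimates are renormalised to sum to 1.}
#' }
#'
#' @param adult_counts A [morph_counts()] vector (or named numeric over
#'   `O`, `Y`, `OY`, `G`).
#' @param model A [genetic_model()] (`model2` or `model3`).
#' @return For model3: list with elements `orange = c(O = , o = )` and
#'   `yellow = c(Y = , y = )`. For model2: named vector `c(O = , Y = , G = )`.
#' @export
estimate_allele_frequencies <- function(adult_counts, model) {
  cnt <- adult_counts[MORPHS]
  tot <- sum(cnt)
  stopifnot(tot > 0)
  f <- cnt / tot
  if (model$name == "model3") {
    qy <- sqrt(f[["G"]] + f[["O"]])
    qo <- sqrt(f[["G"]] + f[["Y"]])
    list(orange = c(O = 1 - qo, o = qo), yellow = c(Y = 1 - qy, y = qy))
  } else if (model$name == "model2") {
    if (f[["G"]] <= 0)
      stop("model2 HWE allele frequencies unidentifiable with zero grey ",
           "phenotypes (freq(G) = sqrt(f_G)); use the equal or threshold ",
           "scheme instead", call. = FALSE)
    g <- sqrt(f[["G"]])
    o <- sqrt(f[["O"]] + g^2) - g
    y <- sqrt(f[["Y"]] + g^2) - g
    v <- c(O = o, Y = y, G = g)
    v / sum(v)
  } else {
    stop("allele frequency estimation is defined for model2 and model3 only",
         call. = FALSE)
  }
}

# P(homozygous | colour expressed) at a di-allelic locus with dominant-allele
# frequency p: p^2 / (p^2 + 2 p q).
hom_prob_hwe <- function(p) {
  q <- 1 - p
  p^2 / (p^2 + 2 * p * q)
}

# Homozygote weight for one colour of one parent under a scheme.
hom_weight <- function(colour, model, assumption, individual = NULL) {
  switch(assumption$scheme,
    equal = 0.5,
    hwe = {
      af <- assumption$allele_freqs
      if (model$name == "model3") {
        p <- if (colour == "orange") af$orange[["O"]] else af$yellow[["Y"]]
        hom_prob_hwe(p)
      } else {
        p <- if (colour == "orange") af[["O"]] else af[["Y"]]
        g <- af[["G"]]
        # phenotype O is OO or OG: P(OO | O) = p^2 / (p^2 + 2 p g)
        p^2 / (p^2 + 2 * p * g)
      }
    },
    threshold = {
      if (is.null(individual))
        stop("threshold scheme requires the individual's colour proportions",
             call. = FALSE)
      if (is.null(assumption$reference_means))
        stop("threshold scheme requires reference means", call. = FALSE)
      sex <- individual$sex %||% "male"
      rm_ <- assumption$reference_means[[sex]] %||%
        assumption$reference_means[["male"]]
      val <- if (colour == "orange") individual$prop_orange
             else individual$effective_yellow
      if (is.null(val) || is.na(val))
        stop("threshold scheme: individual lacks a ", colour, " proportion",
             call. = FALSE)
      mean_ref <- rm_[[colour]]
      if (is.na(mean_ref)) stop("threshold scheme: missing reference mean for ",
                                colour, call. = FALSE)
      if (val > mean_ref) 1 else 0  # ties -> heterozygous
    })
}

#' Genotype distribution of a parent given its morph
#'
#' Returns the probability distribution over genotypes compatible with the
#' parent's morph, under a zygosity assumption scheme. Morphs whose genotype
#' is fully determined (model2 OY and G; model3 G; all hemizygous Z-linked
#' females) get a point mass.
#'
#' @param morph Morph code.
#' @param sex `"male"` or `"female"`.
#' @param model A [genetic_model()] (`model2` or `model3`).
#' @param assumption A [zygosity_assumption()].
#' @param individual For the threshold scheme: list with `prop_orange`,
#'   `effective_yellow` and optionally `sex`.
#' @return Named numeric probability vector over genotype labels.
#' @export
parental_genotype_distribution <- function(morph, sex, model, assumption,
                                           individual = NULL) {
  stopifnot(morph %in% MORPHS)
  if (model$name == "model1")
    stop("genotype distributions are not defined for model1", call. = FALSE)

  if (model$linkage == "z_linked" && sex == "female") {
    g <- switch(model$name,
      model2 = if (morph == "OY")
        stop("an OY female is impossible under Z-linked model2 ",
             "(hemizygous females cannot be heterozygous)", call. = FALSE)
      else morph,
      model3 = switch(morph, O = "Oy", Y = "oY", OY = "OY", G = "oy"))
    return(stats::setNames(1, g))
  }

  if (model$name == "model2") {
    return(switch(morph,
      O = {
        w <- hom_weight("orange", model, assumption, individual)
        c(OO = w, OG = 1 - w)
      },
      Y = {
        w <- hom_weight("yellow", model, assumption, individual)
        c(YY = w, YG = 1 - w)
      },
      OY = c(OY = 1),
      G = c(GG = 1)))
  }

  # model3: independent per-locus zygosity for each expressed colour
  orange_part <- if (morph %in% c("O", "OY")) {
    w <- hom_weight("orange", model, assumption, individual)
    c(OO = w, Oo = 1 - w)
  } else c(oo = 1)
  yellow_part <- if (morph %in% c("Y", "OY")) {
    w <- hom_weight("yellow", model, assumption, individual)
    c(YY = w, Yy = 1 - w)
  } else c(yy = 1)
  out <- as.numeric(outer(orange_part, yellow_part))
  names(out) <- as.vector(outer(names(orange_part), names(yellow_part), paste0))
  out[out > 0]
}

#' Sex-specific reference means of colour expression
#'
#' Mean observed proportion of orange and of (effective) yellow among
#' expressing individuals of each sex, used as the homozygote/heterozygote
#' cut-off by the threshold zygosity scheme. By default computed over the
#' pedigree founders (the wild-caught adults).
#'
#' @param ped A [pedigree()].
#' @param which_rows Logical vector or predicate function selecting the
#'   reference individuals (default: founders, i.e. no recorded parents).
#' @param thresholds An [expression_thresholds()].
#' @return List `male`/`female`, each `c(orange = , yellow = )`.
#' @export
reference_means <- function(ped, which_rows = NULL,
                            thresholds = expression_thresholds()) {
  if (is.null(which_rows)) which_rows <- is.na(ped$sire) & is.na(ped$dam)
  else if (is.function(which_rows)) which_rows <- which_rows(as.data.frame(ped))
  ref <- ped[which_rows, , drop = FALSE]
  out <- list()
  for (sx in c("male", "female")) {
    sub <- ref[ref$sex == sx, , drop = FALSE]
    eo <- sub$prop_orange
    ey <- effective_yellow(sub$morph, sub$prop_orange, sub$prop_yellow)
    keep_o <- !is.na(eo) & eo >= thresholds$adult_orange_min
    keep_y <- !is.na(ey) & !is.na(sub$prop_yellow) &
      (sub$morph %in% c("OY") | sub$prop_yellow >= thresholds$adult_yellow_min)
    out[[sx]] <- c(orange = if (any(keep_o)) mean(eo[keep_o]) else NA_real_,
                   yellow = if (any(keep_y)) mean(ey[keep_y]) else NA_real_)
  }
  out
}
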