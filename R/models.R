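#' Candidate genetic architectures for the four-morph polymorphism
#'
#' Three Mendelian models are supported, each available with autosomal or
#' Z-linked inheritance (ZW system: females carry a single Z and are
#' hemizygous at Z-linked loci):
#' \describe{
#'   \item{model1}{one locus, four alleles, one per morph. Heterozygote
#'     phenotype requires an explicit `dominance` order (most dominant
#'     first); used for exclusion logic and simulation only.}
#'   \item{model2}{one locus, three alleles O, Y, G. O and Y are co-dominant
#'     (the OY heterozygote is the orange+yellow morph); G is recessive to
#'     both (OO/OG orange, YY/YG yellow, GG grey).}
#'   \item{model3}{two unlinked loci: an orange locus (O dominant over o) and
#'     a yellow locus (Y dominant over y); each dominant allele switches its
#'     colour on, giving OY when both are on and G (ooyy) when neither is.}
#' }
#'
#' @param name `"model1"`, `"model2"` or `"model3"`.
#' @param linkage `"autosomal"` or `"z_linked"`.
#' @param dominance For model1 only: morph codes ordered most to least
#'   dominant.
#' @return Object of class `genetic_model`.
#' @export
genetic_model <- function(name = c("model3", "model2", "model1"),
                          linkage = c("autosomal", "z_linked"),
                          dominance = NULL) {
  name <- match.arg(name)
  linkage <- match.arg(linkage)
  if (name == "model1" && !is.null(dominance))
    stopifnot(setequal(dominance, MORPHS))
  structure(list(name = name, linkage = linkage, dominance = dominance),
            class = "genetic_model")
}

# --- genotype string representation ---------------------------------------
# model1: alleles "O","Y","OY","G"; diploid "O/OY", hemizygous "O".
# model2: alleles "O","Y","G"; diploid "OG", hemizygous "O".
# model3: orange locus {"O","o"}, yellow locus {"Y","y"}; diploid "OoYy",
#         hemizygous "Oy" (one allele per locus).

ALLELE_ORDER2 <- c("O", "Y", "G")

geno_alleles <- function(g, model) {
  switch(model$name,
    model1 = strsplit(g, "/", fixed = TRUE),
    model2 = strsplit(g, "", fixed = TRUE),
    model3 = lapply(g, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      if (length(ch) == 4) list(ch[1:2], ch[3:4])
      else if (length(ch) == 2) list(ch[1], ch[2])
      else stop("malformed model3 genotype: ", s, call. = FALSE)
    })
  )
}

# Canonical label for a per-locus allele multiset.
make_geno <- function(loci, model) {
  if (model$name == "model1") {
    a <- loci[[1]]
    return(paste(a[order(match(a, c("O", "Y", "OY", "G")))], collapse = "/"))
  }
  if (model$name == "model2") {
    a <- loci[[1]]
    return(paste(a[order(match(a, ALLELE_ORDER2))], collapse = ""))
  }
  # model3: dominant allele first within each locus (locale-independent)
  paste(vapply(loci, function(a)
    paste(a[order(match(a, c("O", "o", "Y", "y")))], collapse = ""), ""),
    collapse = "")
}

#' Enumerate the genotype space of a model
#'
#' @param model A [genetic_model()].
#' @param sex `"male"` or `"female"`; only relevant under Z linkage, where
#'   females are hemizygous (one allele per locus).
#' @return Character vector of genotype labels.
#' @export
genotype_space <- function(model, sex = "male") {
  hemi <- model$linkage == "z_linked" && sex == "female"
  per_locus <- switch(model$name,
    model1 = list(c("O", "Y", "OY", "G")),
    model2 = list(ALLELE_ORDER2),
    model3 = list(c("O", "o"), c("Y", "y")))
  locus_genos <- lapply(per_locus, function(alleles) {
    if (hemi) as.list(alleles)
    else {
      idx <- expand.grid(i = seq_along(alleles), j = seq_along(alleles))
      idx <- idx[idx$i <= idx$j, ]
      lapply(seq_len(nrow(idx)), function(k) alleles[c(idx$i[k], idx$j[k])])
    }
  })
  combos <- locus_genos[[1]]
  if (length(locus_genos) > 1) {
    combos <- unlist(lapply(combos, function(g1)
      lapply(locus_genos[[2]], function(g2) list(g1, g2))), recursive = FALSE)
  } else {
    combos <- lapply(combos, list)
  }
  unique(vapply(combos, make_geno, "", model = model))
}

#' Morph phenotype of a genotype
#'
#' @param genotype Genotype label(s) as produced by [genotype_space()].
#' @param model A [genetic_model()].
#' @return Morph code(s) in `O`, `Y`, `OY`, `G`.
#' @export
phenotype_of <- function(genotype, model) {
  vapply(genotype, function(g) {
    loci <- geno_alleles(g, model)[[1]]
    if (model$name == "model1") {
      a <- loci
      if (length(a) == 1 || a[1] == a[2]) return(a[1])
      if (is.null(model$dominance))
        stop("model1 heterozygote phenotype requires a dominance order",
             call. = FALSE)
      return(model$dominance[min(match(a, model$dominance))])
    }
    if (model$name == "model2") {
      a <- loci
      has_o <- "O" %in% a
      has_y <- "Y" %in% a
      if (has_o && has_y) "OY" else if (has_o) "O" else if (has_y) "Y" else "G"
    } else {
      orange <- "O" %in% loci[[1]]
      yellow <- "Y" %in% loci[[2]]
      if (orange && yellow) "OY" else if (orange) "O"
      else if (yellow) "Y" else "G"
    }
  }, "", USE.NAMES = FALSE)
}

# Gametes of a genotype: named probability vector over per-locus allele
# combinations (gamete label = alleles joined by "/"). Hemizygous genotypes
# produce their single Z haplotype with probability 1.
gametes <- function(genotype, model) {
  loci <- geno_alleles(genotype, model)[[1]]
  if (model$name != "model3") loci <- list(loci)
  per_locus <- lapply(loci, function(a) {
    tab <- table(a) / length(a)
    stats::setNames(as.numeric(tab), names(tab))
  })
  out <- stats::setNames(1, "")
  for (pl in per_locus) {
    out <- stats::setNames(
      as.numeric(outer(out, pl)),
      as.vector(outer(names(out), names(pl), function(x, y)
        ifelse(nzchar(x), paste(x, y, sep = "/"), y))))
  }
  res <- tapply(out, names(out), sum)
  stats::setNames(as.numeric(res), names(res))
}

# Combine a paternal and maternal gamete into a diploid genotype label.
zygote <- function(g_pat, g_mat, model) {
  ap <- strsplit(g_pat, "/", fixed = TRUE)[[1]]
  am <- strsplit(g_mat, "/", fixed = TRUE)[[1]]
  loci <- lapply(seq_along(ap), function(i) c(ap[i], am[i]))
  if (model$name == "model3") make_geno(loci, model) else make_geno(loci, model)
}

# Hemizygous genotype label from a single gamete.
hemi_geno <- function(g, model) {
  a <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (model$name == "model3") paste(a, collapse = "") else a
}

#' Offspring morph distribution of a mating
#'
#' Given genotype probability distributions for a sire and a dam, returns the
#' offspring morph probability vector for each offspring sex. Under autosomal
#' inheritance the two sexes are identical. Under Z linkage the sire is ZZ
#' and the dam carries a single Z: sons receive one Z from each parent,
#' daughters receive the paternal Z only and express it hemizygously.
#'
#' @param sire_dist,dam_dist Named numeric vectors (genotype label ->
#'   probability), each summing to 1. Under Z linkage `dam_dist` must be
#'   supported on hemizygous genotypes.
#' @param model A [genetic_model()].
#' @return 2 x 4 matrix, rows `male`/`female`, columns `O`, `Y`, `OY`, `G`.
#' @export
cross <- function(sire_dist, dam_dist, model) {
  check_dist <- function(d, sex, who) {
    stopifnot(is.numeric(d), !is.null(names(d)))
    if (abs(sum(d) - 1) > 1e-9)
      stop(who, " distribution does not sum to 1", call. = FALSE)
    space <- genotype_space(model, sex)
    if (!all(names(d) %in% space))
      stop(who, " distribution has genotypes outside the model's ", sex,
           " genotype space: ",
           paste(setdiff(names(d), space), collapse = ", "), call. = FALSE)
  }
  check_dist(sire_dist, "male", "sire")
  check_dist(dam_dist, "female", "dam")

  son <- stats::setNames(numeric(4), MORPHS)
  daughter <- stats::setNames(numeric(4), MORPHS)
  for (gs in names(sire_dist)) {
    pg_s <- gametes(gs, model)
    for (gd in names(dam_dist)) {
      w <- sire_dist[[gs]] * dam_dist[[gd]]
      if (w == 0) next
      if (model$linkage == "autosomal") {
        pg_d <- gametes(gd, model)
        for (a in names(pg_s)) for (b in names(pg_d)) {
          m <- phenotype_of(zygote(a, b, model), model)
          son[m] <- son[m] + w * pg_s[[a]] * pg_d[[b]]
        }
      } else {
        # dam is hemizygous: her whole Z haplotype goes to every son
        gz <- names(gametes(gd, model))  # single haplotype
        for (a in names(pg_s)) {
          ms <- phenotype_of(zygote(a, gz, model), model)
          son[ms] <- son[ms] + w * pg_s[[a]]
          md <- phenotype_of(hemi_geno(a, model), model)
          daughter[md] <- daughter[md] + w * pg_s[[a]]
        }
      }
    }
  }
  if (model$linkage == "autosomal") daughter <- son
  rbind(male = son, female = daughter)
}
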