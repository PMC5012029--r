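#' Expected offspring morph frequencies over a pedigree
#'
#' Each phenotyped offspring whose parents' morphs are known contributes its
#' mating's offspring morph probability vector (its own sex's vector under Z
#' linkage; the son/daughter average if unsexed). Parents' genotype
#' distributions are applied independently per offspring; no conditioning on
#' sibs. Offspring with an unknown parent morph are skipped (with a warning)
#' and removed from the observed counts as well, so expected and observed
#' totals agree exactly.
#'
#' @param ped A [pedigree()].
#' @param model A [genetic_model()] (`model2` or `model3`).
#' @param assumption A [zygosity_assumption()]. For the threshold scheme,
#'   reference means default to [reference_means()] of the pedigree founders.
#' @return List with `expected` and `observed` ([morph_counts()]-style named
#'   vectors), `n` offspring used, and `skipped` ids.
#' @export
expected_offspring_frequencies <- function(ped, model, assumption) {
  stopifnot(inherits(ped, "pedigree"))
  if (assumption$scheme == "threshold" && is.null(assumption$reference_means))
    assumption$reference_means <- reference_means(ped)

  off <- ped[!is.na(ped$sire) & !is.na(ped$dam) & !is.na(ped$morph), ,
             drop = FALSE]
  morph_of <- stats::setNames(ped$morph, ped$id)
  row_of <- stats::setNames(seq_len(nrow(ped)), ped$id)

  usable <- !is.na(morph_of[off$sire]) & !is.na(morph_of[off$dam])
  skipped <- off$id[!usable]
  if (length(skipped))
    warning("skipping ", length(skipped),
            " offspring with unknown parent morph", call. = FALSE)
  off <- off[usable, , drop = FALSE]

  expected <- stats::setNames(numeric(4), MORPHS)
  observed <- stats::setNames(numeric(4), MORPHS)
  cache <- new.env(parent = emptyenv())

  parent_info <- function(pid) {
    r <- ped[row_of[[pid]], ]
    list(sex = r$sex, prop_orange = r$prop_orange,
         effective_yellow = effective_yellow(r$morph, r$prop_orange,
                                             r$prop_yellow))
  }

  for (k in seq_len(nrow(off))) {
    sire_id <- off$sire[k]; dam_id <- off$dam[k]
    # under equal/hwe the distribution depends only on the parents' morphs;
    # under threshold it is deterministic per parent, so cache per mating
    key <- paste(sire_id, dam_id, sep = "\r")
    vec <- cache[[key]]
    if (is.null(vec)) {
      sd_ <- parental_genotype_distribution(
        morph_of[[sire_id]], "male", model, assumption,
        individual = parent_info(sire_id))
      dd_ <- parental_genotype_distribution(
        morph_of[[dam_id]], "female", model, assumption,
        individual = parent_info(dam_id))
      vec <- cross(sd_, dd_, model)
      cache[[key]] <- vec
    }
    p <- switch(off$sex[k],
                male = vec["male", ],
                female = vec["female", ],
                colMeans(vec))
    expected <- expected + p
    observed[off$morph[k]] <- observed[off$morph[k]] + 1
  }
  list(expected = expected, observed = observed, n = nrow(off),
       skipped = skipped)
}

#' Likelihood-ratio goodness-of-fit G test
#'
#' `G = 2 * sum(O * log(O / E))` over morph categories, with `0 * log(0/E)`
#' taken as 0, compared to an upper-tail chi-square with `df` degrees of
#' freedom. A category with positive observed but zero expected count yields
#' infinite G, reported as an incompatibility flag rather than an error.
#'
#' @param observed,expected Named numeric vectors over `O`, `Y`, `OY`, `G`
#'   (order-insensitive).
#' @param df Degrees of freedom (default 3 = categories - 1; no reduction
#'   for estimated allele frequencies).
#' @return List with `G`, `df`, `p`, and `incompatible` (TRUE when G is
#'   infinite).
#' @export
g_test <- function(observed, expected, df = 3) {
  o <- observed[MORPHS]; e <- expected[MORPHS]
  stopifnot(!anyNA(o), !anyNA(e), all(o >= 0), all(e >= 0))
  if (any(e == 0 & o > 0)) {
    return(list(G = Inf, df = df, p = 0, incompatible = TRUE))
  }
  keep <- o > 0
  G <- 2 * sum(o[keep] * log(o[keep] / e[keep]))
  G <- max(G, 0)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE),
       incompatible = FALSE)
}

#' Fit all candidate autosomal models to a pedigree
#'
#' Computes expected offspring morph frequencies and the G test for the
#' autosomal one-locus co-dominant model (model2) and the two-locus dominant
#' model (model3), under each requested zygosity scheme, mirroring a
#' model-by-assumption comparison table. The row with the largest p among
#' evaluable rows is flagged as best fitting.
#'
#' @param ped A [pedigree()].
#' @param schemes Character vector among `"equal"`, `"hwe"`, `"threshold"`.
#' @param models Character vector among `"model2"`, `"model3"`.
#' @param adult_counts Morph counts of the reference adults used for HWE
#'   allele-frequency estimation; default: the pedigree founders.
#' @param ref_means Reference means for the threshold scheme; default
#'   computed from the pedigree founders.
#' @param df Degrees of freedom for the G test.
#' @return Data frame with one row per model x scheme: `model`, `scheme`,
#'   `G`, `df`, `p`, `evaluable`, `best`, `note`; expected/observed vectors
#'   are in `attr(, "details")`.
#' @export
fit_all_models <- function(ped, schemes = c("equal", "hwe", "threshold"),
                           models = c("model2", "model3"),
                           adult_counts = NULL, ref_means = NULL, df = 3) {
  stopifnot(inherits(ped, "pedigree"))
  founders <- is.na(ped$sire) & is.na(ped$dam)
  if (is.null(adult_counts) && "hwe" %in% schemes)
    adult_counts <- morph_counts(ped, founders)
  if (is.null(ref_means) && "threshold" %in% schemes)
    ref_means <- reference_means(ped)

  rows <- list(); details <- list()
  for (mn in models) {
    model <- genetic_model(mn, "autosomal")
    for (sc in schemes) {
      note <- ""; res <- NULL
      assumption <- tryCatch({
        switch(sc,
          equal = zygosity_assumption("equal"),
          hwe = zygosity_assumption("hwe",
            allele_freqs = estimate_allele_frequencies(adult_counts, model)),
          threshold = zygosity_assumption("threshold",
            reference_means = ref_means))
      }, error = function(e) {note <<- conditionMessage(e); NULL})
      if (!is.null(assumption)) {
        res <- tryCatch(
          expected_offspring_frequencies(ped, model, assumption),
          error = function(e) {note <<- conditionMessage(e); NULL})
      }
      if (is.null(res)) {
        rows[[length(rows) + 1]] <- data.frame(
          model = mn, scheme = sc, G = NA_real_, df = df, p = NA_real_,
          evaluable = FALSE, note = note, stringsAsFactors = FALSE)
      } else {
        gt <- g_test(res$observed, res$expected, df = df)
        rows[[length(rows) + 1]] <- data.frame(
          model = mn, scheme = sc, G = gt$G, df = gt$df, p = gt$p,
          evaluable = TRUE, note = note, stringsAsFactors = FALSE)
        details[[paste(mn, sc, sep = ".")]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  ok <- which(out$evaluable & is.finite(out$G))
  if (length(ok)) out$best[ok[which.max(out$p[ok])]] <- TRUE
  attr(out, "details") <- details
  out
}

exclusion_report <- function(model, linkage, n_checked, offending,
                             rules = NULL) {
  structure(list(model = model, linkage = linkage,
                 n_checked = n_checked,
                 n_incompatible = length(offending),
                 offending = offending, rules = rules),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion check: %s (%s)\n", x$model, x$linkage))
  cat(sprintf("  %d of %d checked offspring incompatible\n",
              x$n_incompatible, x$n_checked))
  if (!is.null(x$rules)) {
    for (i in seq_len(nrow(x$rules)))
      cat(sprintf("  rule '%s': %d/%d\n", x$rules$rule[i],
                  x$rules$n_incompatible[i], x$rules$n_pairs[i]))
  }
  invisible(x)
}

#' Categorical exclusion test for the one-locus four-allele model
#'
#' Autosomal variant: under one locus with four morph-specific alleles, an
#' offspring must share its morph with at least one parent; offspring
#' matching neither parent are counted incompatible. Z-linked variant:
#' daughters inherit their single Z from the father and so must express his
#' morph; father-daughter morph mismatches are counted.
#'
#' @param ped A [pedigree()].
#' @param linkage `"autosomal"` or `"z_linked"`.
#' @return An `exclusion_report`.
#' @export
model1_exclusion <- function(ped, linkage = c("autosomal", "z_linked")) {
  linkage <- match.arg(linkage)
  morph_of <- stats::setNames(ped$morph, ped$id)
  if (linkage == "autosomal") {
    off <- ped[!is.na(ped$sire) & !is.na(ped$dam) & !is.na(ped$morph), ]
    ok <- !is.na(morph_of[off$sire]) & !is.na(morph_of[off$dam])
    off <- off[ok, ]
    bad <- off$id[off$morph != morph_of[off$sire] &
                  off$morph != morph_of[off$dam]]
    exclusion_report("model1", linkage, nrow(off), bad)
  } else {
    off <- ped[!is.na(ped$sire) & !is.na(ped$morph) & ped$sex == "female", ]
    ok <- !is.na(morph_of[off$sire])
    off <- off[ok, ]
    bad <- off$id[off$morph != morph_of[off$sire]]
    exclusion_report("model1", linkage, nrow(off), bad)
  }
}

#' Z-linkage exclusion rules for models 2 and 3
#'
#' Checks father-daughter pairs against the phenotype combinations that
#' Z-linked inheritance forbids (ZW females express their single paternal Z):
#' \describe{
#'   \item{model2}{a daughter can only carry one of her father's alleles, so
#'     she cannot be OY (a heterozygote morph) under any father; an O father
#'     (OO/OG) can only give O or G daughters; a Y father Y or G; a G father
#'     only G; an OY father only O or Y.}
#'   \item{model3}{a grey father must produce grey daughters; a yellow
#'     father cannot produce daughters expressing orange; an orange father
#'     cannot produce daughters expressing yellow.}
#' }
#'
#' @param ped A [pedigree()].
#' @param model A [genetic_model()] with name `model2` or `model3` (linkage
#'   field ignored; the check is about the Z-linked variant).
#' @return An `exclusion_report` with a per-rule tally in `$rules`.
#' @export
zlinked_exclusion <- function(ped, model) {
  morph_of <- stats::setNames(ped$morph, ped$id)
  d <- ped[ped$sex == "female" & !is.na(ped$sire) & !is.na(ped$morph), ]
  d <- d[!is.na(morph_of[d$sire]), ]
  fm <- morph_of[d$sire]; dm <- d$morph

  if (model$name == "model2") {
    rules <- list(
      "daughter OY impossible" = dm == "OY",
      "O father: daughter must be O or G" = fm == "O" & !dm %in% c("O", "G"),
      "Y father: daughter must be Y or G" = fm == "Y" & !dm %in% c("Y", "G"),
      "G father: daughter must be G" = fm == "G" & dm != "G",
      "OY father: daughter must be O or Y" = fm == "OY" & !dm %in% c("O", "Y"))
    applies <- list(rep(TRUE, nrow(d)), fm == "O", fm == "Y", fm == "G",
                    fm == "OY")
  } else if (model$name == "model3") {
    rules <- list(
      "G father: daughter must be G" = fm == "G" & dm != "G",
      "Y father: daughter cannot express orange" =
        fm == "Y" & dm %in% c("O", "OY"),
      "O father: daughter cannot express yellow" =
        fm == "O" & dm %in% c("Y", "OY"))
    applies <- list(fm == "G", fm == "Y", fm == "O")
  } else {
    stop("zlinked_exclusion is defined for model2 and model3", call. = FALSE)
  }

  tab <- data.frame(
    rule = names(rules),
    n_pairs = vapply(applies, sum, 0L),
    n_incompatible = vapply(rules, sum, 0L),
    stringsAsFactors = FALSE)
  bad <- d$id[Reduce(`|`, rules)]
  exclusion_report(model$name, "z_linked", nrow(d), bad, rules = tab)
}
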