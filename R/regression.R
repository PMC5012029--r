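#' Mid-parent / mid-offspring pairs for a trait
#'
#' One point per sire x dam family: the mid-parent value is the mean of the
#' two parents' (transformed) trait values, the mid-offspring value the mean
#' over the pair's expressing offspring pooled across all their clutches.
#' Families in which either parent or no offspring expresses the trait are
#' dropped (their count is reported in `attr(, "n_dropped")`). Intended for
#' use with `prepare_trait_table(..., zero_policy = "exclude")`.
#'
#' @param ped A [pedigree()].
#' @param trait_table Data frame from [prepare_trait_table()].
#' @param trait `"orange"` or `"yellow"`.
#' @param value Which column of the trait table to analyse (default
#'   `"transformed"`, matching analysis on the arcsine-square-root scale).
#' @return Data frame with `midparent`, `midoffspring`, `sire`, `dam`,
#'   `family`, `n_offspring`.
#' @export
midparent_pairs <- function(ped, trait_table, trait = c("orange", "yellow"),
                            value = "transformed") {
  trait <- match.arg(trait)
  tv <- trait_values(trait_table, trait, value)
  fam <- family_table(ped)
  out <- lapply(seq_len(nrow(fam)), function(k) {
    sv <- tv[fam$sire[k]]; dv <- tv[fam$dam[k]]
    ov <- tv[fam$offspring[[k]]]
    ov <- ov[!is.na(ov)]
    if (is.na(sv) || is.na(dv) || !length(ov)) return(NULL)
    data.frame(midparent = (sv + dv) / 2, midoffspring = mean(ov),
               sire = fam$sire[k], dam = fam$dam[k],
               family = paste(fam$sire[k], fam$dam[k], sep = "x"),
               n_offspring = length(ov), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, TRUE))
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(midparent = numeric(0), midoffspring = numeric(0),
                      sire = character(0), dam = character(0),
                      family = character(0), n_offspring = integer(0))
  attr(out, "n_dropped") <- dropped
  out
}

#' Single-parent / offspring pairs, optionally cross-trait
#'
#' One point per family (or per clutch): the focal parent's trait value
#' against the mean of the expressing offspring. Setting `parent_trait !=
#' offspring_trait` gives the cross-correlation (reciprocal phenotypic
#' regression) input.
#'
#' @param ped A [pedigree()].
#' @param trait_table Data frame from [prepare_trait_table()].
#' @param mode `"sire"` or `"dam"`: which parent supplies the predictor.
#' @param parent_trait,offspring_trait `"orange"` or `"yellow"`.
#' @param per `"family"` (sire x dam pooled across clutches) or `"clutch"`.
#' @param value Trait-table column to analyse.
#' @return Data frame with `parent_value`, `offspring_value`, `sire`, `dam`,
#'   `clutch`, `family`.
#' @export
single_parent_pairs <- function(ped, trait_table, mode = c("sire", "dam"),
                                parent_trait = "orange",
                                offspring_trait = parent_trait,
                                per = c("family", "clutch"),
                                value = "transformed") {
  mode <- match.arg(mode)
  per <- match.arg(per)
  ptv <- trait_values(trait_table, parent_trait, value)
  otv <- trait_values(trait_table, offspring_trait, value)
  fam <- if (per == "family") family_table(ped) else clutches(ped)
  out <- lapply(seq_len(nrow(fam)), function(k) {
    pid <- fam[[mode]][k]
    pv <- ptv[pid]
    ov <- otv[fam$offspring[[k]]]
    ov <- ov[!is.na(ov)]
    if (is.na(pv) || !length(ov)) return(NULL)
    data.frame(parent_value = unname(pv), offspring_value = mean(ov),
               sire = fam$sire[k], dam = fam$dam[k],
               clutch = if (per == "clutch") fam$clutch[k] else NA_character_,
               family = paste(fam$sire[k], fam$dam[k], sep = "x"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(parent_value = numeric(0), offspring_value = numeric(0),
                      sire = character(0), dam = character(0),
                      clutch = character(0), family = character(0))
  out
}

# Named vector id -> value for one trait.
trait_values <- function(trait_table, trait, value) {
  tt <- trait_table[trait_table$trait == trait, ]
  stats::setNames(tt[[value]], tt$id)
}

# sire x dam families with offspring pooled across clutches.
family_table <- function(ped) {
  cl <- clutches(ped)
  if (!nrow(cl)) return(cbind(cl, data.frame(offspring = I(list()))))
  key <- paste(cl$sire, cl$dam, sep = "\r")
  groups <- split(seq_len(nrow(cl)), key)
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  data.frame(
    sire = vapply(parts, `[`, "", 1),
    dam = vapply(parts, `[`, "", 2),
    offspring = I(lapply(groups, function(ix) unlist(cl$offspring[ix]))),
    stringsAsFactors = FALSE)
}

#' Parent-offspring regression
#'
#' Ordinary least squares of (mid-)offspring value on parent value. Following
#' the convention that the plotted regression slope is reported as the
#' heritability estimate, `h2_reported` equals the raw slope for all modes;
#' the classical doubling for single-parent regressions (slope estimates
#' h2/2) is available via `double_single_parent = TRUE`.
#'
#' @param pairs Data frame from [midparent_pairs()] (columns `midparent`,
#'   `midoffspring`) or [single_parent_pairs()] (`parent_value`,
#'   `offspring_value`).
#' @param mode `"midparent"`, `"sire"` or `"dam"` (bookkeeping only, except
#'   for the doubling option).
#' @param parent_trait,offspring_trait Trait labels for bookkeeping.
#' @param double_single_parent Multiply single-parent slopes by 2 in
#'   `h2_reported`.
#' @return Object of class `regression_result`: `slope`, `se_slope`, `r2`,
#'   `p`, `n_pairs`, `h2_reported`, plus the settings.
#' @export
parent_offspring_regression <- function(pairs,
                                        mode = c("midparent", "sire", "dam"),
                                        parent_trait = "orange",
                                        offspring_trait = parent_trait,
                                        double_single_parent = FALSE) {
  mode <- match.arg(mode)
  x <- pairs$midparent %||% pairs$parent_value
  yv <- pairs$midoffspring %||% pairs$offspring_value
  if (is.null(x)) x <- pairs$parent_value
  if (is.null(yv)) yv <- pairs$offspring_value
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs, got ", n, call. = FALSE)
  if (stats::var(x) <= 0)
    stop("degenerate predictor: parent values have zero variance",
         call. = FALSE)
  fit <- stats::lm(yv ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  h2 <- if (double_single_parent && mode != "midparent") 2 * slope else slope
  structure(list(mode = mode, parent_trait = parent_trait,
                 offspring_trait = offspring_trait,
                 slope = slope, se_slope = se, r2 = sm$r.squared,
                 p = sm$coefficients[2, 4], n_pairs = n,
                 h2_reported = h2,
                 doubled = double_single_parent && mode != "midparent"),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s regression (%s parent -> %s offspring), n = %d\n",
              x$mode, x$parent_trait, x$offspring_trait, x$n_pairs))
  cat(sprintf("  slope = %.3f +/- %.3f, R2 = %.3f, p = %.4g\n",
              x$slope, x$se_slope, x$r2, x$p))
  cat(sprintf("  h2 (reported%s) = %.3f\n",
              if (x$doubled) ", doubled" else " = slope", x$h2_reported))
  invisible(x)
}

#' ANCOVA test for sex-linked inheritance
#'
#' Pools sire-offspring and dam-offspring pairs and fits
#' `offspring ~ parent_value * parent_sex` with a random clutch intercept
#' (lme4). A significant parent-value x parent-sex interaction indicates
#' different sire and dam slopes, the signature of sex linkage. The Wald F
#' for the interaction is the squared t statistic, referred to an F
#' distribution with `1` and `n - 4` degrees of freedom. With a single
#' clutch (or if the mixed fit fails) a fixed-effects ANCOVA is used and a
#' note recorded.
#'
#' Because parent values are constant within a clutch, the clutch intercept
#' competes with the parent fixed effect; together with the co-parent's
#' unmodelled contribution this makes the mixed-model interaction test
#' conservative. `random_clutch = FALSE` drops the random term and gives the
#' classical fixed-effects ANCOVA.
#'
#' @param sire_pairs,dam_pairs Data frames from [single_parent_pairs()]
#'   (use `per = "clutch"` so the clutch random factor is informative).
#' @param trait Trait label (bookkeeping).
#' @param random_clutch Include the random clutch intercept (default TRUE).
#' @return Object of class `ancova_result`: `F_interaction`, `df_num`,
#'   `df_den`, `p`, `clutch_variance`, `note`.
#' @export
ancova_sex_linkage <- function(sire_pairs, dam_pairs, trait = "orange",
                               random_clutch = TRUE) {
  dat <- rbind(
    data.frame(offspring = sire_pairs$offspring_value,
               parent = sire_pairs$parent_value, parent_sex = "sire",
               clutch = sire_pairs$clutch %||% sire_pairs$family,
               stringsAsFactors = FALSE),
    data.frame(offspring = dam_pairs$offspring_value,
               parent = dam_pairs$parent_value, parent_sex = "dam",
               clutch = dam_pairs$clutch %||% dam_pairs$family,
               stringsAsFactors = FALSE))
  dat$clutch[is.na(dat$clutch)] <- dat$parent_sex[is.na(dat$clutch)]
  n <- nrow(dat)
  if (n < 6) stop("too few pairs for the ANCOVA (", n, ")", call. = FALSE)
  if (stats::var(dat$parent) <= 0)
    stop("degenerate predictor: parent values have zero variance",
         call. = FALSE)
  note <- ""
  clutch_var <- NA_real_
  coefs <- NULL
  if (random_clutch && length(unique(dat$clutch)) > 1) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(offspring ~ parent * parent_sex + (1 | clutch),
                   data = dat, REML = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      s2 <- stats::sigma(fit)^2
      if (!is.finite(s2) || s2 < 1e-6 * stats::var(dat$offspring)) {
        # one shared offspring value per clutch: the clutch intercept
        # absorbs the response and the mixed fit degenerates
        note <- "degenerate clutch effect; fixed-effects ANCOVA used"
      } else {
        vc <- as.data.frame(lme4::VarCorr(fit))
        clutch_var <- vc$vcov[vc$grp == "clutch"]
        coefs <- stats::coef(summary(fit))
      }
    } else note <- "mixed model failed; fixed-effects ANCOVA used"
  } else note <- "single clutch; fixed-effects ANCOVA used"
  if (is.null(coefs)) {
    fit <- stats::lm(offspring ~ parent * parent_sex, data = dat)
    coefs <- stats::coef(summary(fit))
  }
  ix <- grep("parent:parent_sex", rownames(coefs))
  tval <- coefs[ix, "t value"]
  Fv <- tval^2
  df_den <- n - 4L
  structure(list(trait = trait, F_interaction = unname(Fv), df_num = 1L,
                 df_den = df_den,
                 p = stats::pf(Fv, 1, df_den, lower.tail = FALSE),
                 clutch_variance = clutch_var, n = n, note = note),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("Sex-linkage ANCOVA (%s): interaction F_%d,%d = %.2f, p = %.4g\n",
              x$trait, x$df_num, x$df_den, x$F_interaction, x$p))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
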