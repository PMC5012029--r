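#' Expression thresholds for colour classification
#'
#' Colour proportions below these cut-offs are treated as absence of the
#' colour (cream/grey throat background can leak small orange or yellow pixel
#' fractions). Mature animals use 2% for orange and 5% for yellow; juveniles
#' use 1% for both. Comparison is strict: a value exactly at the threshold
#' counts as expressed.
#'
#' @param adult_orange_min,adult_yellow_min,juvenile_min Fractions in (0, 1).
#' @return List of class `expression_thresholds`.
#' @export
expression_thresholds <- function(adult_orange_min = 0.02,
                                  adult_yellow_min = 0.05,
                                  juvenile_min = 0.01) {
  stopifnot(adult_orange_min > 0, adult_orange_min < 1,
            adult_yellow_min > 0, adult_yellow_min < 1,
            juvenile_min > 0, juvenile_min < 1,
            juvenile_min <= adult_orange_min,
            juvenile_min <= adult_yellow_min)
  structure(list(adult_orange_min = adult_orange_min,
                 adult_yellow_min = adult_yellow_min,
                 juvenile_min = juvenile_min),
            class = "expression_thresholds")
}

# Per-colour threshold for a life stage; vectorised over stage.
threshold_for <- function(trait, stage, thresholds) {
  adult <- if (trait == "orange") thresholds$adult_orange_min else thresholds$adult_yellow_min
  ifelse(stage == "juvenile", thresholds$juvenile_min, adult)
}

#' Classify a throat into one of four morphs
#'
#' An individual is orange (O) when only orange is above its expression
#' threshold, yellow (Y) when only yellow is, orange+yellow (OY) when both
#' are, and grey (G) when neither is.
#'
#' @param prop_orange,prop_yellow Fractions of throat area in `[0, 1]`
#'   (vectorised).
#' @param stage `"adult"` or `"juvenile"` (recycled).
#' @param thresholds An [expression_thresholds()].
#' @return Character vector of morph codes.
#' @export
classify_morph <- function(prop_orange, prop_yellow, stage = "adult",
                           thresholds = expression_thresholds()) {
  stopifnot(all(stage %in% c("adult", "juvenile")))
  if (any(prop_orange < 0 | prop_orange > 1, na.rm = TRUE) ||
      any(prop_yellow < 0 | prop_yellow > 1, na.rm = TRUE))
    stop("proportions must lie in [0,1]", call. = FALSE)
  o <- prop_orange >= threshold_for("orange", stage, thresholds)
  y <- prop_yellow >= threshold_for("yellow", stage, thresholds)
  out <- rep(NA_character_, length(o))
  out[o & y] <- "OY"
  out[o & !y] <- "O"
  out[!o & y] <- "Y"
  out[!o & !y] <- "G"
  out
}

#' Effective yellow coverage
#'
#' In OY morphs the central orange patch overlays yellow, so the yellow trait
#' value is taken as the sum of orange and yellow coverage; all other morphs
#' pass `prop_yellow` through. Clipped to `[0, 1]`.
#'
#' @param morph Morph code(s).
#' @param prop_orange,prop_yellow Fractions.
#' @return Numeric vector of effective yellow fractions.
#' @export
effective_yellow <- function(morph, prop_orange, prop_yellow) {
  out <- ifelse(morph == "OY", prop_orange + prop_yellow, prop_yellow)
  pmin(pmax(out, 0), 1)
}

#' Arcsine-square-root transform
#'
#' Variance-stabilising transform for proportions: `asin(sqrt(p))`, in
#' radians, mapping `[0, 1]` monotonically onto `[0, pi/2]`.
#'
#' @param p Fractions in `[0, 1]`.
#' @return Radians.
#' @export
arcsin_sqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p must lie in [0,1]", call. = FALSE)
  asin(sqrt(p))
}

#' Build an analysis-ready trait table
#'
#' Produces one record per individual and colour trait, carrying the raw
#' proportion, the effective value (after the OY yellow parameterisation),
#' its arcsine-square-root transform, and an `expressed` flag. Below-threshold
#' values are handled per `zero_policy`:
#' \describe{
#'   \item{`as_missing`}{record kept, effective/transformed set to `NA`
#'     (animal-model convention: zeros specified as missing).}
#'   \item{`as_zero`}{record kept with effective value 0.}
#'   \item{`exclude`}{record dropped (regression convention).}
#' }
#'
#' @param ped A [pedigree()]. Individuals with `generation` `"F1"` and a
#'   juvenile cohort are still classified with adult thresholds unless
#'   `stage` says otherwise; `stage` may be a single value or a function of
#'   the pedigree data frame returning per-individual stages.
#' @param thresholds An [expression_thresholds()].
#' @param zero_policy One of `"as_missing"`, `"as_zero"`, `"exclude"`.
#' @param stage `"adult"`, `"juvenile"`, or a function.
#' @return Data frame with columns `id`, `trait`, `raw`, `effective`,
#'   `transformed`, `expressed`.
#' @export
prepare_trait_table <- function(ped, thresholds = expression_thresholds(),
                                zero_policy = c("as_missing", "as_zero", "exclude"),
                                stage = "adult") {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(ped, "pedigree"))
  st <- if (is.function(stage)) stage(as.data.frame(ped)) else rep(stage, nrow(ped))

  morph <- ped$morph
  need <- is.na(morph) & !is.na(ped$prop_orange) & !is.na(ped$prop_yellow)
  morph[need] <- classify_morph(ped$prop_orange[need], ped$prop_yellow[need],
                                st[need], thresholds)

  recs <- lapply(c("orange", "yellow"), function(trait) {
    raw <- if (trait == "orange") ped$prop_orange else ped$prop_yellow
    eff <- if (trait == "orange") raw else effective_yellow(morph, ped$prop_orange, ped$prop_yellow)
    thr <- threshold_for(trait, st, thresholds)
    expressed <- !is.na(raw) & raw >= thr
    data.frame(id = ped$id, trait = trait, raw = raw, effective = eff,
               transformed = arcsin_sqrt(pmin(pmax(eff, 0), 1)),
               expressed = expressed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[!is.na(out$raw), , drop = FALSE]

  below <- !out$expressed
  if (zero_policy == "exclude") {
    out <- out[!below, , drop = FALSE]
  } else if (zero_policy == "as_missing") {
    out$effective[below] <- NA_real_
    out$transformed[below] <- NA_real_
  } else {
    out$effective[below] <- 0
    out$transformed[below] <- 0
  }
  rownames(out) <- NULL
  out
}
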