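#' Pedigree container
#'
#' A `pedigree` is a validated data frame with one row per individual and the
#' canonical columns `id`, `sex`, `generation`, `cohort`, `clutch`, `sire`,
#' `dam`, `prop_orange`, `prop_yellow`, `morph`. Founders have empty (`NA`)
#' parent links. Colour proportions are fractions of throat area in `[0, 1]`
#' (or `NA` when unmeasured); `morph` is one of `"O"`, `"Y"`, `"OY"`, `"G"`
#' or `NA`.
#'
#' @param x Data frame with at least an `id` column; missing canonical
#'   columns are added as `NA`.
#' @return An object of class `pedigree` (a data frame).
#' @seealso [read_pedigree()], [write_pedigree()], [morph_counts()]
#' @export
pedigree <- function(x) {
  stopifnot(is.data.frame(x), "id" %in% names(x))
  cols <- c("id", "sex", "generation", "cohort", "clutch", "sire", "dam",
            "prop_orange", "prop_yellow", "morph")
  for (cl in setdiff(cols, names(x))) {
    x[[cl]] <- if (cl %in% c("prop_orange", "prop_yellow")) NA_real_ else NA_character_
  }
  x <- x[, cols]
  x$id <- as.character(x$id)
  for (cl in c("sex", "generation", "cohort", "clutch", "sire", "dam", "morph")) {
    v <- as.character(x[[cl]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    x[[cl]] <- v
  }
  x$sex[is.na(x$sex)] <- "unknown"
  x$prop_orange <- as.numeric(x$prop_orange)
  x$prop_yellow <- as.numeric(x$prop_yellow)
  rownames(x) <- NULL
  class(x) <- c("pedigree", "data.frame")
  validate_pedigree(x)
  x
}

#' Validate pedigree invariants
#'
#' Checks id uniqueness, sex codes, proportion ranges, parent existence and
#' sex, morph codes, acyclicity of parent links, and (where generations are
#' coded `F0`, `F1`, ...) that offspring belong to a later generation than
#' their parents. Errors name the offending individuals.
#'
#' @param ped A `pedigree`.
#' @return Invisibly, `ped`.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (anyNA(ped$id) || any(!nzchar(ped$id)))
    ped_error("missing individual id")
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup)) ped_error("duplicate id", unique(dup))

  bad <- ped$id[!ped$sex %in% SEXES]
  if (length(bad)) ped_error("unknown sex code", bad)

  bad <- ped$id[!is.na(ped$morph) & !ped$morph %in% MORPHS]
  if (length(bad)) ped_error("unknown morph code", bad)

  for (cl in c("prop_orange", "prop_yellow")) {
    v <- ped[[cl]]
    bad <- ped$id[!is.na(v) & (v < 0 | v > 1)]
    if (length(bad)) ped_error(paste(cl, "outside [0,1]"), bad)
  }
  both <- !is.na(ped$prop_orange) & !is.na(ped$prop_yellow)
  bad <- ped$id[both & (ped$prop_orange + ped$prop_yellow > 1 + 1e-9)]
  if (length(bad)) ped_error("prop_orange + prop_yellow exceeds 1", bad)

  sex_of <- stats::setNames(ped$sex, ped$id)
  for (side in c("sire", "dam")) {
    ref <- ped[[side]]
    has <- !is.na(ref)
    miss <- ped$id[has & !(ref %in% ped$id)]
    if (length(miss)) ped_error(paste("dangling", side, "reference"), miss)
    want <- if (side == "sire") "male" else "female"
    bad <- ped$id[has & sex_of[ref] != want]
    if (length(bad))
      ped_error(paste0(side, " is not recorded as ", want), bad)
  }

  check_acyclic(ped)

  gen_num <- suppressWarnings(as.integer(sub("^F", "", ped$generation)))
  names(gen_num) <- ped$id
  for (side in c("sire", "dam")) {
    has <- !is.na(ped[[side]])
    pg <- gen_num[ped[[side]][has]]
    og <- gen_num[ped$id[has]]
    bad <- ped$id[has][!is.na(pg) & !is.na(og) & og <= pg]
    if (length(bad)) ped_error("offspring generation not later than parent's", bad)
  }
  invisible(ped)
}

# Kahn topological sort over parent->offspring edges; errors on a cycle.
# Returns ids in an order where parents precede offspring.
check_acyclic <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (side in c("sire", "dam")) {
    has <- which(!is.na(ped[[side]]))
    p <- idx[ped[[side]][has]]
    for (k in seq_along(has)) {
      children[[p[k]]] <- c(children[[p[k]]], has[k])
      indeg[has[k]] <- indeg[has[k]] + 1L
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n)
    ped_error("pedigree contains a parent-link cycle", ped$id[setdiff(seq_len(n), order)])
  invisible(ped$id[order])
}

#' Read a pedigree from CSV
#'
#' The file must have a header naming the canonical columns (`id`, `sex`,
#' `generation`, `cohort`, `clutch`, `sire`, `dam`, `prop_orange`,
#' `prop_yellow`, `morph`); `format_options` can rename them
#' (`aliases = c(file_column = "canonical_name")`) and set the missing-value
#' token (`na`, default the empty string). Missing fields become explicit
#' `NA`, never silent zeros.
#'
#' @param path CSV file path.
#' @param format_options Optional list with elements `aliases` and `na`.
#' @return A validated [pedigree()].
#' @export
read_pedigree <- function(path, format_options = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  na_token <- format_options$na %||% ""
  x <- utils::read.csv(path, colClasses = "character",
                       na.strings = na_token, check.names = FALSE,
                       strip.white = TRUE)
  aliases <- format_options$aliases
  if (!is.null(aliases)) {
    hit <- names(x) %in% names(aliases)
    names(x)[hit] <- unname(unlist(aliases[names(x)[hit]]))
  }
  if (!"id" %in% names(x))
    stop("pedigree file lacks an 'id' column (after aliasing): ", path, call. = FALSE)
  pedigree(x)
}

#' Write a pedigree to CSV
#'
#' Round-trips exactly through [read_pedigree()]: missing values are written
#' as empty cells and proportions with full double precision.
#'
#' @param ped A `pedigree`.
#' @param path Output file path.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  for (cl in c("prop_orange", "prop_yellow")) {
    v <- out[[cl]]
    out[[cl]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Count individuals per morph
#'
#' @param ped A `pedigree`.
#' @param filter Optional predicate: either a logical vector over rows or a
#'   function taking the pedigree data frame and returning one (e.g.
#'   `function(p) p$sex == "male"`). Default: all individuals.
#' @return Named numeric vector over `O`, `Y`, `OY`, `G` (class
#'   `morph_counts`), with a `total` attribute.
#' @export
morph_counts <- function(ped, filter = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  keep <- rep(TRUE, nrow(ped))
  if (is.function(filter)) keep <- filter(as.data.frame(ped))
  else if (!is.null(filter)) keep <- filter
  keep[is.na(keep)] <- FALSE
  sel <- ped[keep, , drop = FALSE]
  if (anyNA(sel$morph))
    ped_error("selected individual lacks a morph", sel$id[is.na(sel$morph)])
  cnt <- vapply(MORPHS, function(m) sum(sel$morph == m), numeric(1))
  structure(cnt, total = sum(cnt), class = "morph_counts")
}

#' @export
print.morph_counts <- function(x, ...) {
  cat("Morph counts (total ", attr(x, "total"), "):\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Group offspring ids by mating and clutch
#'
#' @param ped A `pedigree`.
#' @return Data frame with columns `sire`, `dam`, `clutch` and a list column
#'   `offspring` of id vectors; one row per (sire, dam, clutch) combination
#'   among individuals with both parents known.
#' @export
clutches <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  off <- ped[!is.na(ped$sire) & !is.na(ped$dam), , drop = FALSE]
  if (!nrow(off)) {
    return(data.frame(sire = character(0), dam = character(0),
                      clutch = character(0)))
  }
  key <- paste(off$sire, off$dam, ifelse(is.na(off$clutch), "", off$clutch),
               sep = "\r")
  groups <- split(off$id, key)
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    sire = vapply(parts, `[`, "", 1),
    dam = vapply(parts, `[`, "", 2),
    clutch = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
    stringsAsFactors = FALSE)
  out$clutch[!nzchar(out$clutch)] <- NA_character_
  out$offspring <- unname(groups)
  out
}
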