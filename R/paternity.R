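#' Microsatellite genotype table
#'
#' Wide-format container: one row per individual, two integer columns per
#' locus (`<locus>.1`, `<locus>.2`, fragment sizes; `NA` = not typed).
#'
#' @param x Data frame with an `id` column and paired allele columns.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(x) {
  stopifnot(is.data.frame(x), "id" %in% names(x))
  allele_cols <- setdiff(names(x), "id")
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  for (lc in loci) {
    for (s in 1:2) {
      cn <- paste0(lc, ".", s)
      if (!cn %in% names(x))
        stop("locus ", lc, " lacks column ", cn, call. = FALSE)
      x[[cn]] <- as.integer(x[[cn]])
      if (any(x[[cn]] <= 0, na.rm = TRUE))
        stop("non-positive allele size at locus ", lc, call. = FALSE)
    }
  }
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) stop("duplicate ids in genotype table", call. = FALSE)
  structure(x, loci = loci, class = c("genotype_table", "data.frame"))
}

#' Read a genotype table
#'
#' `format = "wide"` reads a CSV with `id` plus `<locus>.1`/`<locus>.2`
#' columns. `format = "genepop"` reads the GenePop dialect: a title line,
#' one locus name per line (or comma-separated), `Pop` separators, then
#' `id , a1a2 a1a2 ...` rows with 2- or 3-digit allele codes (`000` =
#' missing).
#'
#' @param path File path.
#' @param format `"wide"` or `"genepop"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("wide", "genepop")) {
  format <- match.arg(format)
  if (format == "wide") {
    return(genotype_table(utils::read.csv(path, check.names = FALSE)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pop_ix <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_ix)) stop("no 'Pop' line in GenePop file", call. = FALSE)
  header <- lines[2:(pop_ix[1] - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  samples <- lines[setdiff((pop_ix[1] + 1):length(lines), pop_ix)]
  rows <- lapply(samples, function(ln) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GenePop row: ", ln, call. = FALSE)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(loci))
      stop("GenePop row for ", id, " has ", length(codes),
           " genotypes for ", length(loci), " loci", call. = FALSE)
    w <- nchar(codes[1]) / 2
    a1 <- as.integer(substr(codes, 1, w))
    a2 <- as.integer(substr(codes, w + 1, 2 * w))
    a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
    out <- as.list(c(rbind(a1, a2)))
    names(out) <- paste0(rep(loci, each = 2), ".", 1:2)
    c(list(id = id), out)
  })
  genotype_table(do.call(rbind.data.frame, rows))
}

loci_of <- function(table) attr(table, "loci")

get_geno <- function(table, id, locus) {
  r <- which(table$id == id)
  if (!length(r)) stop("unknown id in genotype table: ", id, call. = FALSE)
  c(table[[paste0(locus, ".1")]][r], table[[paste0(locus, ".2")]][r])
}

# Is there an assignment of the offspring's alleles to (maternal, paternal)
# origins compatible with both parents' genotypes?
locus_compatible <- function(off, dam, sire) {
  (off[1] %in% dam && off[2] %in% sire) || (off[2] %in% dam && off[1] %in% sire)
}

#' Count mismatching loci for a candidate sire
#'
#' The dam is assumed to be the true mother. A locus mismatches when no
#' assignment of the offspring's two alleles to maternal and paternal origin
#' is compatible with both the dam's and the candidate's genotypes. Loci with
#' any missing call among the trio are skipped; if fewer than `min_typed`
#' loci remain, the result is flagged unreliable.
#'
#' @param offspring,dam,candidate_sire Individual ids.
#' @param table A [genotype_table()].
#' @param min_typed Minimum number of fully typed loci for a reliable count.
#' @return List `mismatches`, `n_typed`, `reliable`.
#' @export
mismatch_count <- function(offspring, dam, candidate_sire, table,
                           min_typed = 5) {
  mm <- 0L; typed <- 0L
  for (lc in loci_of(table)) {
    o <- get_geno(table, offspring, lc)
    d <- get_geno(table, dam, lc)
    s <- get_geno(table, candidate_sire, lc)
    if (anyNA(c(o, d, s))) next
    typed <- typed + 1L
    if (!locus_compatible(o, d, s)) mm <- mm + 1L
  }
  list(mismatches = mm, n_typed = typed, reliable = typed >= min_typed)
}

#' Assign paternity by the mismatch rule
#'
#' A candidate is acceptable when it mismatches the offspring (given the
#' dam) at no more than `max_mismatch` loci (default 1, allowing for a
#' mutation). The unique acceptable candidate with the fewest mismatches is
#' assigned; ties at the minimum, or no acceptable candidate, leave the
#' offspring unassigned with a reason.
#'
#' @param offspring,dam Ids.
#' @param candidates Character vector of candidate sire ids.
#' @param table A [genotype_table()].
#' @param max_mismatch Maximum mismatches tolerated.
#' @param min_typed Passed to [mismatch_count()].
#' @return Object of class `paternity_call`: `offspring`, `dam`,
#'   `candidates` (data frame with mismatch counts), `assigned` (id or
#'   `NA`), `reason`.
#' @export
assign_paternity <- function(offspring, dam, candidates, table,
                             max_mismatch = 1, min_typed = 5) {
  res <- lapply(candidates, function(cs)
    mismatch_count(offspring, dam, cs, table, min_typed))
  tab <- data.frame(candidate = candidates,
                    mismatches = vapply(res, `[[`, 0L, "mismatches"),
                    n_typed = vapply(res, `[[`, 0L, "n_typed"),
                    reliable = vapply(res, `[[`, TRUE, "reliable"),
                    stringsAsFactors = FALSE)
  ok <- tab$mismatches <= max_mismatch & tab$reliable
  assigned <- NA_character_; reason <- ""
  if (!any(ok)) {
    reason <- if (any(!tab$reliable)) "no acceptable candidate (some unreliable)"
              else "no candidate within mismatch limit"
  } else {
    best <- tab$mismatches == min(tab$mismatches[ok]) & ok
    if (sum(best) > 1) reason <- "tie between candidates"
    else assigned <- tab$candidate[best]
  }
  structure(list(offspring = offspring, dam = dam, candidates = tab,
                 assigned = assigned, reason = reason,
                 max_mismatch = max_mismatch),
            class = "paternity_call")
}

#' @export
print.paternity_call <- function(x, ...) {
  cat(sprintf("Paternity call for %s (dam %s): %s\n", x$offspring, x$dam,
              if (is.na(x$assigned)) paste0("unassigned - ", x$reason)
              else x$assigned))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Per-locus marker summary statistics
#'
#' Observed heterozygosity (fraction of typed individuals heterozygous),
#' unbiased expected heterozygosity `2N/(2N-1) * (1 - sum p_i^2)` (N = typed
#' individuals), and polymorphic information content
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`. Monomorphic loci report
#' zeros with a warning.
#'
#' @param table A [genotype_table()].
#' @return Data frame with columns `locus`, `n_typed`, `n_alleles`, `Ho`,
#'   `He`, `PIC`.
#' @export
locus_summary <- function(table) {
  out <- lapply(loci_of(table), function(lc) {
    a1 <- table[[paste0(lc, ".1")]]
    a2 <- table[[paste0(lc, ".2")]]
    keep <- !is.na(a1) & !is.na(a2)
    n <- sum(keep)
    if (n < 2) stop("fewer than 2 typed individuals at locus ", lc,
                    call. = FALSE)
    alleles <- c(a1[keep], a2[keep])
    p <- as.numeric(table(alleles)) / length(alleles)
    if (length(p) < 2) {
      warning("locus ", lc, " is monomorphic", call. = FALSE)
      return(data.frame(locus = lc, n_typed = n, n_alleles = 1L,
                        Ho = 0, He = 0, PIC = 0))
    }
    ho <- mean(a1[keep] != a2[keep])
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
    pic <- 1 - sum(p^2) - (sum(p^2)^2 - sum(p^4))
    data.frame(locus = lc, n_typed = n, n_alleles = length(p),
               Ho = ho, He = he, PIC = pic, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a microsatellite genotype table over a pedigree
#'
#' Founders draw two alleles per locus from the given frequencies; offspring
#' inherit one allele from each parent, with an optional per-allele mutation
#' rate (mutation replaces the transmitted allele by a uniformly chosen
#' other allele of the locus).
#'
#' @param ped A [pedigree()].
#' @param n_loci Number of loci.
#' @param n_alleles Alleles per locus.
#' @param mutation_rate Per-transmitted-allele mutation probability.
#' @param seed Optional seed.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(ped, n_loci = 6, n_alleles = 8,
                               mutation_rate = 0, seed = NULL) {
  with_seed(seed, {
    ord <- check_acyclic(ped)
    pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
    loci <- sprintf("L%02d", seq_len(n_loci))
    sizes <- lapply(seq_len(n_loci), function(l) 100 + 2 * seq_len(n_alleles))
    g <- array(NA_integer_, c(nrow(ped), n_loci, 2))
    sire <- stats::setNames(ped$sire, ped$id)
    dam <- stats::setNames(ped$dam, ped$id)
    for (id in ord) {
      i <- pos[[id]]
      for (l in seq_len(n_loci)) {
        draw_parent <- function(pid) {
          a <- g[pos[[pid]], l, sample(2, 1)]
          if (mutation_rate > 0 && stats::runif(1) < mutation_rate)
            a <- sample(setdiff(sizes[[l]], a), 1)
          a
        }
        g[i, l, ] <- if (is.na(sire[[id]]) || is.na(dam[[id]]))
          sample(sizes[[l]], 2, replace = TRUE)
        else c(draw_parent(sire[[id]]), draw_parent(dam[[id]]))
      }
    }
    out <- data.frame(id = ped$id, stringsAsFactors = FALSE)
    for (l in seq_len(n_loci)) {
      out[[paste0(loci[l], ".1")]] <- g[, l, 1]
      out[[paste0(loci[l], ".2")]] <- g[, l, 2]
    }
    genotype_table(out)
  })
}
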