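#' REML animal model for a single trait
#'
#' Fits the univariate mixed model `y = X b + a + e` with `a ~ N(0, A Va)`
#' (A = numerator relationship matrix) and `e ~ N(0, I Ve)` by restricted
#' maximum likelihood, on the arcsine-square-root transformed trait values.
#' The restricted likelihood is profiled down to the heritability ratio
#' `h2 = Va / (Va + Ve)` and maximised by a grid scan plus golden-section
#' refinement, which is robust for the design sizes (~10^2) this package
#' targets. The standard error of h2 comes from the observed information of
#' `(Va, Ve)` (finite differences) via the delta method, and the 95% CI is
#' `h2 +/- 1.96 * se`.
#'
#' Individuals with missing trait values (or unknown sex) contribute to the
#' analysis only through the relationship matrix, exactly as when zeros are
#' declared missing in a pedigree mixed model.
#'
#' @param ped A [pedigree()].
#' @param trait_table Data frame from [prepare_trait_table()] (use
#'   `zero_policy = "as_missing"`).
#' @param trait `"orange"` or `"yellow"`.
#' @param fixed Character vector of fixed factors among `"sex"`, `"cohort"`,
#'   `"generation"`; factors with a single observed level are dropped.
#' @param include_unsexed Keep records of unknown-sex individuals (default
#'   FALSE).
#' @return Object of class `animal_model_result`: `V_a`, `V_e`, `V_p`, `h2`,
#'   `se_h2`, `ci95`, `beta`, `logLik`, `converged`, `n_records`.
#' @export
reml_animal_model <- function(ped, trait_table, trait = c("orange", "yellow"),
                              fixed = c("sex", "cohort", "generation"),
                              include_unsexed = FALSE) {
  trait <- match.arg(trait)
  stopifnot(inherits(ped, "pedigree"))
  tt <- trait_table[trait_table$trait == trait & !is.na(trait_table$transformed), ]
  dat <- merge(tt[, c("id", "transformed")], as.data.frame(ped), by = "id")
  if (!include_unsexed) dat <- dat[dat$sex != "unknown", ]
  n <- nrow(dat)
  if (n < 3) stop("too few phenotyped individuals (", n, ")", call. = FALSE)

  A <- build_relationship_matrix(ped)
  Ar <- A[dat$id, dat$id]
  off <- Ar[upper.tri(Ar)]
  if (all(off == 0))
    stop("additive variance unidentifiable: no related pairs among ",
         "phenotyped individuals", call. = FALSE)

  y <- dat$transformed
  terms <- "1"
  for (f in fixed) {
    v <- dat[[f]]
    if (length(unique(v[!is.na(v)])) >= 2) {
      dat[[f]] <- factor(v)
      terms <- c(terms, f)
    }
  }
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))), dat)
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  if (n - p < 2) stop("not enough residual degrees of freedom", call. = FALSE)

  # Profiled restricted log-likelihood at heritability ratio h2.
  prof <- function(h2) {
    H <- h2 * Ar + (1 - h2) * diag(n)
    L <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(L)) return(list(ll = -Inf))
    logdetH <- 2 * sum(log(diag(L)))
    Xi <- backsolve(L, X, transpose = TRUE)
    yi <- backsolve(L, y, transpose = TRUE)
    XtX <- crossprod(Xi)
    beta <- solve(XtX, crossprod(Xi, yi))
    r <- yi - Xi %*% beta
    rss <- sum(r^2)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) + logdetH +
                    determinant(XtX, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), Vp = s2, beta = drop(beta))
  }

  grid <- seq(0.001, 1, length.out = 25)
  lls <- vapply(grid, function(h) prof(h)$ll, 0)
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(h) prof(h)$ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  h2 <- opt$maximum
  converged <- TRUE
  # boundary solutions: take the better of the interior optimum and edges
  if (prof(0.0005)$ll > opt$objective) { h2 <- 0; converged <- TRUE }
  fit <- prof(max(h2, 1e-8))
  Vp <- fit$Vp
  Va <- h2 * Vp
  Ve <- (1 - h2) * Vp

  # unprofiled restricted log-likelihood for the information matrix
  full_ll <- function(va, ve) {
    if (va < 0 || ve <= 0) return(-Inf)
    V <- va * Ar + ve * diag(n)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(-Inf)
    Xi <- backsolve(L, X, transpose = TRUE)
    yi <- backsolve(L, y, transpose = TRUE)
    XtX <- crossprod(Xi)
    beta <- solve(XtX, crossprod(Xi, yi))
    r <- yi - Xi %*% beta
    -0.5 * (2 * sum(log(diag(L))) +
              as.numeric(determinant(XtX, logarithm = TRUE)$modulus) +
              sum(r^2))
  }

  se_h2 <- NA_real_
  hstep <- pmax(c(Va, Ve), Vp * 0.05) * 1e-2
  Hmat <- matrix(NA_real_, 2, 2)
  f0 <- full_ll(Va, Ve)
  if (is.finite(f0)) {
    pars <- c(Va, Ve)
    for (a in 1:2) for (b in a:2) {
      ea <- c(0, 0); ea[a] <- hstep[a]
      eb <- c(0, 0); eb[b] <- hstep[b]
      pp <- function(s1, s2) full_ll(max(pars[1] + s1 * ea[1] + s2 * eb[1], 0),
                                     pars[2] + s1 * ea[2] + s2 * eb[2])
      Hmat[a, b] <- Hmat[b, a] <-
        (pp(1, 1) - pp(1, -1) - pp(-1, 1) + pp(-1, -1)) /
        (4 * hstep[a] * hstep[b])
    }
    info <- -Hmat
    cv <- if (all(is.finite(info))) tryCatch(solve(info), error = function(e) NULL)
          else NULL
    if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) > 0)) {
      g <- c(Ve, -Va) / Vp^2  # d h2 / d (Va, Ve)
      v <- drop(t(g) %*% cv %*% g)
      if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
    }
  }
  if (is.na(se_h2)) converged <- FALSE

  structure(list(
    trait = trait, V_a = Va, V_e = Ve, V_p = Vp, h2 = h2, se_h2 = se_h2,
    ci95 = c(lower = h2 - 1.96 * se_h2, upper = h2 + 1.96 * se_h2),
    beta = fit$beta, logLik = fit$ll, converged = converged,
    n_records = n, fixed = setdiff(terms, "1")),
    class = "animal_model_result")
}

#' @export
print.animal_model_result <- function(x, ...) {
  cat(sprintf("Animal model (REML), trait: %s, n = %d records\n",
              x$trait, x$n_records))
  cat(sprintf("  V_a = %.4g  V_e = %.4g  V_p = %.4g\n", x$V_a, x$V_e, x$V_p))
  cat(sprintf("  h2 = %.3f +/- %.3f  (95%% CI %.3f - %.3f)\n",
              x$h2, x$se_h2, x$ci95[1], x$ci95[2]))
  if (!x$converged) cat("  [warning: information matrix not positive definite;",
                        "SE unreliable]\n")
  invisible(x)
}
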