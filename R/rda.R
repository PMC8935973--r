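# Redundancy analysis (constrained ordination) and three-set variation
# partitioning, implemented directly so the standardization, adjustment and
# permutation contracts are explicit. Cross-checked against vegan in the
# test suite.

std_matrix <- function(x, what) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant ", what, " column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  scale(m)
}

#' Redundancy analysis with a seeded permutation test
#'
#' Responses and predictors are standardized to zero mean and unit
#' variance (so e.g. colony numbers and log foraging distances are
#' unit-comparable). Fitted values come from multivariate least squares;
#' canonical eigenvalues from the spectral decomposition of the fitted
#' values' covariance. `R2 = trace(Yhat'Yhat) / trace(Y'Y)`; the adjusted
#' R-squared uses Ezekiel's formula `1 - (1 - R2)(n-1)/(n-p-1)`. Global
#' significance is a permutation test on the pseudo-F with rows of `Y`
#' permuted: `p = (1 + #{F* >= F}) / (n_perm + 1)`.
#'
#' @param responses Data frame/matrix of response columns (e.g. ln
#'   aveMeanFD and colNe).
#' @param predictors Data frame/matrix of explanatory variables.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return Object of class `rda_fit`: eigenvalues, per-axis
#'   `proportion_of_model` and `proportion_of_total`, `R2`, `adj_R2`,
#'   `pseudo_F`, `perm_p`, response loadings per axis (`axis_loadings`),
#'   and `biplot` (correlations of predictors with the fitted responses,
#'   used to read effect directions).
#' @export
rda_fit <- function(responses, predictors, n_perm = 999, seed = 1) {
  Y <- std_matrix(responses, "response")
  X <- std_matrix(predictors, "predictor")
  n <- nrow(Y); p <- ncol(X)
  if (nrow(X) != n) stop("responses and predictors differ in rows")
  if (n <= p + 1) stop("need more observations than predictors + 1")
  qr_ <- qr(cbind(1, X))
  Yhat <- qr.fitted(qr_, Y)
  tot <- sum(Y^2)
  expl <- sum(Yhat^2)
  R2 <- expl / tot
  es <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  nax <- min(ncol(Y), p)
  eig <- pmax(es$values[seq_len(nax)], 0)
  loadings <- es$vectors[, seq_len(nax), drop = FALSE]
  dimnames(loadings) <- list(colnames(Y), paste0("RDA", seq_len(nax)))
  pseudo_f <- (R2 / p) / ((1 - R2) / (n - p - 1))
  perm_p <- NA_real_
  if (n_perm > 0) {
    Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
    # Y is column-centered, and row permutation preserves that, so the
    # intercept component of Q'Y is zero and fitted SS = sum((Q'Y)^2).
    f_of <- function(Yp) {
      r2 <- sum(crossprod(Q, Yp)^2) / tot
      (r2 / p) / ((1 - r2) / (n - p - 1))
    }
    stat <- with_seed(derive_seed(seed, 131L), vapply(seq_len(n_perm),
      function(i) f_of(Y[sample.int(n), , drop = FALSE]), numeric(1)))
    perm_p <- (1 + sum(stat >= pseudo_f)) / (n_perm + 1)
  }
  biplot <- stats::cor(X, Yhat)
  colnames(biplot) <- colnames(Y)
  structure(list(
    eigenvalues = eig,
    proportion_of_model = if (sum(eig) > 0) eig / sum(eig) else eig,
    proportion_of_total = eig / (tot / (n - 1)),
    R2 = R2,
    adj_R2 = 1 - (1 - R2) * (n - 1) / (n - p - 1),
    pseudo_F = pseudo_f, perm_p = perm_p, n_perm = n_perm,
    axis_loadings = loadings, biplot = biplot,
    n = n, n_predictors = p,
    standardized = TRUE
  ), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "sites,", x$n_predictors,
      "predictors (standardized)\n")
  cat(sprintf("  R2 = %.3f (%.1f%%), adjusted R2 = %.3f\n",
              x$R2, 100 * x$R2, x$adj_R2))
  for (i in seq_along(x$eigenvalues))
    cat(sprintf("  RDA%d: %.1f%% of model, %.1f%% of total variation\n",
                i, 100 * x$proportion_of_model[i],
                100 * x$proportion_of_total[i]))
  if (!is.na(x$perm_p))
    cat(sprintf("  Permutation test (%d perms): pseudo-F = %.2f, p = %.4g\n",
                x$n_perm, x$pseudo_F, x$perm_p))
  invisible(x)
}

#' Three-set variation partitioning on adjusted R-squared
#'
#' Fits redundancy analyses on each of the seven unions of three predictor
#' sets and solves the unique and shared adjusted-R-squared fractions by
#' inclusion-exclusion. Fractions are reported as computed (they can be
#' negative, which preserves the exact sum identity: unique + pairwise +
#' triple fractions equal the full-model adjusted R-squared).
#'
#' @param responses Response table (see [rda_fit()]).
#' @param set1,set2,set3 Data frames/matrices of the three predictor
#'   categories (e.g. demography, infrastructure, natural habitat).
#' @param labels Character length 3, names for the sets.
#' @return Object of class `varpart3`: `fractions` (named vector: unique
#'   `[a]`, `[b]`, `[c]`; pairwise `[d]`, `[e]`, `[f]`; triple `[g]`;
#'   `residual`), `adj_R2` per union, `labels`.
#' @export
varpart3 <- function(responses, set1, set2, set3,
                     labels = c("set1", "set2", "set3")) {
  adj <- function(X) rda_fit(responses, X, n_perm = 0)$adj_R2
  u <- function(...) {
    parts <- lapply(list(...), as.matrix)
    do.call(cbind, parts)
  }
  rA <- adj(u(set1)); rB <- adj(u(set2)); rC <- adj(u(set3))
  rAB <- adj(u(set1, set2)); rAC <- adj(u(set1, set3))
  rBC <- adj(u(set2, set3)); rABC <- adj(u(set1, set2, set3))
  a <- rABC - rBC
  b <- rABC - rAC
  c_ <- rABC - rAB
  d <- rABC - rC - a - b          # shared by set1 & set2 only
  e <- rABC - rA - b - c_         # shared by set2 & set3 only
  f <- rABC - rB - a - c_         # shared by set1 & set3 only
  g <- rABC - a - b - c_ - d - e - f
  fr <- c(a, b, c_, d, e, f, g, 1 - rABC)
  names(fr) <- c(paste0("unique_", labels),
                 paste0("shared_", labels[1], "_", labels[2]),
                 paste0("shared_", labels[2], "_", labels[3]),
                 paste0("shared_", labels[1], "_", labels[3]),
                 "shared_all", "residual")
  structure(list(
    fractions = fr,
    adj_R2 = c(set1 = rA, set2 = rB, set3 = rC, set12 = rAB,
               set13 = rAC, set23 = rBC, full = rABC),
    labels = labels
  ), class = "varpart3")
}

#' @export
print.varpart3 <- function(x, ...) {
  cat("Variation partitioning (adjusted R-squared fractions):\n")
  print(round(x$fractions, 4))
  cat(sprintf("Full model adjusted R2 = %.4f\n", x$adj_R2[["full"]]))
  invisible(x)
}

#' Total variation explained by each set including overlaps
#'
#' Convenience accessor: the testable/reported per-category fractions
#' (unique + the shared parts touching that set).
#'
#' @param x A `varpart3` object.
#' @return Named numeric vector, one total fraction per set.
#' @export
varpart3_totals <- function(x) {
  stopifnot(inherits(x, "varpart3"))
  f <- x$fractions
  stats::setNames(c(
    f[1] + f[4] + f[6] + f[7],
    f[2] + f[4] + f[5] + f[7],
    f[3] + f[5] + f[6] + f[7]
  ), x$labels)
}
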