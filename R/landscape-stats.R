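# Landscape covariate extraction and the univariate/regression side of the
# statistical battery.

#' Extract a per-cell covariate from polygon overlaps or point features
#'
#' Three extraction modes, matching how GIS layers are summarized onto a
#' survey grid:
#' \describe{
#'   \item{count}{number of point features falling in each cell
#'     (`overlaps` has columns `cell_id`, one row per feature).}
#'   \item{percent}{100 times the summed overlap fractions of the layer's
#'     polygons with the cell (`overlaps`: `cell_id`, `polygon_id`,
#'     `fraction`).}
#'   \item{weighted_average}{mean of the polygons' attribute values
#'     weighted by their overlap fraction with the cell; needs
#'     `attributes` (`polygon_id`, `value`).}
#' }
#'
#' @param overlaps Data frame as described per mode. Overlap fractions must
#'   lie in `[0, 1]` and sum to at most 1 (+1e-6) per cell for one layer.
#' @param mode One of `"count"`, `"percent"`, `"weighted_average"`.
#' @param attributes Polygon attribute table for `weighted_average`.
#' @param cell_ids Cells to report (default: those present in `overlaps`);
#'   cells without features get 0 (count/percent) or `NA`
#'   (weighted_average).
#' @return Data frame `cell_id`, `value`.
#' @export
extract_covariates <- function(overlaps,
                               mode = c("count", "percent",
                                        "weighted_average"),
                               attributes = NULL, cell_ids = NULL) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unknown extraction mode: ",
                                            paste(mode, collapse = "/")))
  if (is.null(cell_ids)) cell_ids <- sort(unique(overlaps$cell_id))
  if (mode == "count") {
    tab <- table(factor(overlaps$cell_id, levels = cell_ids))
    return(data.frame(cell_id = cell_ids, value = as.numeric(tab)))
  }
  if (!all(overlaps$fraction >= 0 & overlaps$fraction <= 1))
    stop("overlap fractions must be in [0, 1]")
  tot <- tapply(overlaps$fraction, overlaps$cell_id, sum)
  if (any(tot > 1 + 1e-6))
    stop("overlap fractions sum to more than 1 in cell(s): ",
         paste(names(tot)[tot > 1 + 1e-6], collapse = ", "))
  if (mode == "percent") {
    v <- tapply(overlaps$fraction, factor(overlaps$cell_id,
                                          levels = cell_ids), sum)
    v[is.na(v)] <- 0
    return(data.frame(cell_id = cell_ids, value = 100 * as.numeric(v)))
  }
  # weighted average
  if (is.null(attributes) ||
      !all(c("polygon_id", "value") %in% names(attributes)))
    stop("weighted_average mode needs an attribute table ",
         "(polygon_id, value)")
  val <- attributes$value[match(overlaps$polygon_id,
                                attributes$polygon_id)]
  if (anyNA(val)) stop("polygon(s) without an attribute value")
  f <- factor(overlaps$cell_id, levels = cell_ids)
  num <- tapply(overlaps$fraction * val, f, sum)
  den <- tapply(overlaps$fraction, f, sum)
  data.frame(cell_id = cell_ids, value = as.numeric(num) / as.numeric(den))
}

#' Pairwise Spearman correlations with Benjamini-Hochberg adjustment
#'
#' Spearman's rho on mid-ranked data for every pair of columns, with
#' two-sided p-values, adjusted across all tested pairs by the BH step-up
#' false discovery rate procedure.
#'
#' @param data Data frame or matrix of numeric variables (columns).
#' @return List of three matrices: `rho`, `p` (raw), `p_adj` (BH-adjusted,
#'   diagonal `NA`).
#' @export
spearman_fdr <- function(data) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  v <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  k <- ncol(x)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(v, v))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- suppressWarnings(
      stats::cor.test(x[, i], x[, j], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- stats::p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(rho = rho, p = p, p_adj = padj)
}

#' Variance inflation factor screen
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on all others.
#' Variables with VIF above `threshold` are flagged; flagging is advisory
#' (an explicit `keep` list records variables retained despite
#' collinearity, as is often biologically warranted). Perfectly collinear
#' predictors get an `Inf` sentinel.
#'
#' @param predictors Data frame or matrix of numeric predictors.
#' @param threshold Flagging threshold (default 5).
#' @param keep Character vector of variables to never recommend removing.
#' @return Data frame: `variable`, `vif`, `flagged`, `recommend_remove`.
#' @export
vif_screen <- function(predictors, threshold = 5, keep = character()) {
  x <- as.matrix(predictors)
  storage.mode(x) <- "double"
  v <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  vif <- vapply(seq_len(ncol(x)), function(j) {
    y <- x[, j]
    others <- x[, -j, drop = FALSE]
    qr_ <- qr(cbind(1, others))
    res <- qr.resid(qr_, y)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = v, vif = vif, flagged = vif > threshold,
             recommend_remove = vif > threshold & !(v %in% keep))
}

#' Best-subset linear regression ranked by adjusted R-squared and AIC
#'
#' Exhaustively enumerates predictor subsets up to `max_size` (falling back
#' to a forward beam search when the enumeration would exceed 2^20
#' subsets), fits ordinary least squares to each, and reports the top
#' models by adjusted R-squared together with their AIC; the selected model
#' is the one with the lowest AIC among the top set. AIC is computed as
#' `n*log(RSS/n) + 2*(p+2)` (Gaussian likelihood with the error variance
#' counted as a parameter); only AIC differences matter for selection.
#' Per-predictor variance-explained is the drop in adjusted R-squared when
#' that predictor is removed from the selected subset. Rank-deficient
#' subsets are skipped.
#'
#' @param response Numeric response vector.
#' @param predictors Data frame or matrix of candidate predictors.
#' @param max_size Largest subset size considered (default 10).
#' @param top Number of models to report (default 10).
#' @param beam_width Beam width for the fallback search (default 200).
#' @return Object of class `best_subsets`: `models` (data frame with
#'   `size`, `adj_r2`, `AIC`, `predictors`), `best` (list with
#'   `predictors`, `coefficients`, `adj_r2`, `AIC`, `var_explained`), `n`.
#' @export
best_subset_regression <- function(response, predictors, max_size = 10,
                                   top = 10, beam_width = 200) {
  y <- as.numeric(response)
  x <- as.matrix(predictors)
  storage.mode(x) <- "double"
  v <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- v
  n <- length(y)
  max_size <- min(max_size, ncol(x))
  if (n <= max_size + 2)
    stop("need n > max_size + 2 observations")
  tss <- sum((y - mean(y))^2)

  fit_subset <- function(cols) {
    xm <- cbind(`(Intercept)` = 1, x[, cols, drop = FALSE])
    qr_ <- qr(xm)
    if (qr_$rank < ncol(xm)) return(NULL)     # collinear subset: skip
    rss <- sum(qr.resid(qr_, y)^2)
    p <- length(cols)
    r2 <- 1 - rss / tss
    list(adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         AIC = n * log(rss / n) + 2 * (p + 2),
         coef = qr.coef(qr_, y))
  }

  n_subsets <- sum(choose(ncol(x), seq_len(max_size)))
  subsets <- if (n_subsets <= 2^20) {
    unlist(lapply(seq_len(max_size), function(k)
      utils::combn(ncol(x), k, simplify = FALSE)), recursive = FALSE)
  } else {
    # forward beam search: grow the best `beam_width` subsets per size
    beam <- lapply(seq_len(ncol(x)), function(j) j)
    all_subs <- beam
    for (k in 2:max_size) {
      score <- vapply(beam, function(s) {
        f <- fit_subset(s); if (is.null(f)) -Inf else f$adj_r2
      }, numeric(1))
      beam <- beam[order(score, decreasing = TRUE)]
      beam <- beam[seq_len(min(beam_width, length(beam)))]
      ext <- unlist(lapply(beam, function(s)
        lapply(setdiff(seq_len(ncol(x)), s), function(j) sort(c(s, j)))),
        recursive = FALSE)
      ext <- ext[!duplicated(vapply(ext, paste, character(1),
                                    collapse = ","))]
      beam <- ext
      all_subs <- c(all_subs, ext)
    }
    all_subs
  }

  fits <- lapply(subsets, fit_subset)
  ok <- !vapply(fits, is.null, logical(1))
  subsets <- subsets[ok]; fits <- fits[ok]
  adj <- vapply(fits, `[[`, numeric(1), "adj_r2")
  ord <- order(adj, decreasing = TRUE)[seq_len(min(top, length(fits)))]
  models <- data.frame(
    size = vapply(subsets[ord], length, 0L),
    adj_r2 = adj[ord],
    AIC = vapply(fits[ord], `[[`, numeric(1), "AIC"),
    predictors = vapply(subsets[ord], function(s)
      paste(v[s], collapse = " + "), character(1))
  )
  win <- ord[which.min(models$AIC)]
  best_cols <- subsets[[win]]
  best_fit <- fits[[win]]
  var_expl <- vapply(best_cols, function(j) {
    sub <- setdiff(best_cols, j)
    f <- if (length(sub)) fit_subset(sub) else list(adj_r2 = 0)
    best_fit$adj_r2 - (if (is.null(f)) NA_real_ else f$adj_r2)
  }, numeric(1))
  names(var_expl) <- v[best_cols]
  structure(list(
    models = models,
    best = list(predictors = v[best_cols],
                coefficients = best_fit$coef,
                adj_r2 = best_fit$adj_r2, AIC = best_fit$AIC,
                var_explained = var_expl),
    n = n), class = "best_subsets")
}

#' @export
print.best_subsets <- function(x, ...) {
  cat("Best-subset regression (n =", x$n, "): top",
      nrow(x$models), "models by adjusted R-squared\n")
  print(transform(x$models, adj_r2 = round(100 * adj_r2, 1),
                  AIC = round(AIC, 1)), row.names = FALSE)
  cat("\nSelected (lowest AIC):",
      paste(x$best$predictors, collapse = " + "), "\n")
  invisible(x)
}
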