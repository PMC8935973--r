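test_that("covariate extraction implements count, percent and weighted-average
           modes", {
  # weighted average: polygons covering 30% and 70% with values 10 and 20
  ov <- data.frame(cell_id = 1, polygon_id = c("p1", "p2"),
                   fraction = c(0.3, 0.7))
  at <- data.frame(polygon_id = c("p1", "p2"), value = c(10, 20))
  expect_equal(extract_covariates(ov, "weighted_average", at)$value, 17)
  # full cover by one polygon -> that polygon's value
  ov1 <- data.frame(cell_id = 1, polygon_id = "p1", fraction = 1)
  expect_equal(extract_covariates(ov1, "weighted_average", at)$value, 10)
  # percent: 100 * summed fractions; empty cells get 0
  expect_equal(extract_covariates(ov, "percent", cell_ids = 1:2)$value,
               c(100, 0))
  # count mode and the empty-cell zero
  pts <- data.frame(cell_id = c(1, 1, 3))
  expect_equal(extract_covariates(pts, "count", cell_ids = 1:3)$value,
               c(2, 0, 1))
  expect_error(extract_covariates(ov, "median"), "unknown")
  ovbad <- data.frame(cell_id = 1, polygon_id = c("p1", "p2"),
                      fraction = c(0.8, 0.7))
  expect_error(extract_covariates(ovbad, "percent"), "more than 1")
})

test_that("Spearman correlations and BH adjustment behave as defined", {
  x <- 1:10
  d <- data.frame(x = x, y = 2 * x + 3, z = rev(x))
  s <- spearman_fdr(d)
  expect_equal(s$rho["x", "y"], 1)
  expect_equal(s$rho["x", "z"], -1)
  expect_equal(s$rho, t(s$rho))
  # BH on p = (.01,.02,.03,.04,.05) -> all adjusted to .05
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), "BH"),
               bh_stepup(c(0.01, 0.02, 0.03, 0.04, 0.05)))
  expect_equal(bh_stepup(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
})

test_that("BH matches the brute-force step-up definition on small grids", {
  set.seed(8)
  for (i in 1:200) {
    m <- sample(1:6, 1)
    p <- sample(seq(0.01, 1, by = 0.01), m, replace = TRUE)
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("Spearman's rho equals Pearson on mid-ranks, ties included", {
  set.seed(9)
  for (i in 1:100) {
    x <- sample(1:8, 30, replace = TRUE)   # plenty of ties
    y <- sample(1:8, 30, replace = TRUE)
    expect_equal(suppressWarnings(stats::cor(x, y, method = "spearman")),
                 stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("VIF screening flags collinearity and respects the keep-list", {
  n <- 60
  set.seed(61)
  # exactly orthogonal, mean-centered predictors: orthogonalize against the
  # intercept too, so empirical correlations are exactly zero
  q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 3), n, 3))))[, -1]
  orth <- as.data.frame(q); names(orth) <- c("a", "b", "c")
  v <- vif_screen(orth)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)
  # a pair with empirical r = 0.9 among otherwise orthogonal columns:
  # VIF = 1/(1-0.81) ~ 5.263 for both
  q4 <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 4), n, 4))))[, -1]
  x1 <- q4[, 1]; x2 <- 0.9 * q4[, 1] + sqrt(1 - 0.81) * q4[, 2]
  d <- data.frame(x1 = x1, x2 = x2, x3 = q4[, 3], x4 = q4[, 4])
  v2 <- vif_screen(d)
  expect_equal(v2$vif[1:2], rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_true(all(v2$flagged[1:2]))
  expect_false(any(v2$flagged[3:4]))
  keepers <- vif_screen(d, keep = "x1")
  expect_false(keepers$recommend_remove[keepers$variable == "x1"])
  # duplicated column -> infinite sentinel
  dup <- data.frame(x1 = x1, x1b = x1, x3 = q4[, 3])
  expect_true(all(is.infinite(vif_screen(dup)$vif[1:2])))
})

test_that("best-subset regression finds exact supports and penalizes noise", {
  set.seed(12)
  n <- 40
  X <- as.data.frame(matrix(stats::rnorm(n * 6), n, 6))
  names(X) <- paste0("x", 1:6)
  y <- 2 * X$x2 - 3 * X$x5          # exactly linear in x2, x5
  fit <- best_subset_regression(y, X, max_size = 3)
  expect_setequal(fit$best$predictors, c("x2", "x5"))
  expect_equal(fit$best$adj_r2, 1, tolerance = 1e-9)
  expect_equal(fit$models$AIC[which.max(fit$models$adj_r2)],
               min(fit$models$AIC[fit$models$adj_r2 > 1 - 1e-9]))
  # single candidate subset returned unchanged
  one <- best_subset_regression(y + stats::rnorm(n), X[, "x2", drop = FALSE],
                                max_size = 1)
  expect_equal(one$best$predictors, "x2")
  expect_equal(nrow(one$models), 1)
  # a pure-noise extra predictor lowers adjusted R2 most of the time;
  # the theoretical rate is P(F[1, n-3] < 1) ~ 0.68 at n = 49, so "most"
  # means comfortably above a coin flip
  set.seed(13)
  worse <- vapply(1:200, function(i) {
    n <- 49
    x1 <- stats::rnorm(n); noise <- stats::rnorm(n)
    yy <- x1 + stats::rnorm(n)
    f1 <- summary(stats::lm(yy ~ x1))$adj.r.squared
    f2 <- summary(stats::lm(yy ~ x1 + noise))$adj.r.squared
    f2 < f1
  }, logical(1))
  expect_gte(mean(worse), 0.6)
  expect_equal(mean(worse), stats::pf(1, 1, 46), tolerance = 0.1)
  expect_error(best_subset_regression(y[1:5], X[1:5, ], max_size = 4), "n >")
})

test_that("the RDA matches vegan and the one-response OLS limit", {
  skip_if_not_installed("vegan")
  set.seed(21)
  n <- 49
  X <- as.data.frame(matrix(stats::rnorm(n * 5), n, 5))
  names(X) <- paste0("x", 1:5)
  Y <- data.frame(r1 = X$x1 - X$x2 + stats::rnorm(n),
                  r2 = 0.5 * X$x3 + stats::rnorm(n))
  f <- rda_fit(Y, X, n_perm = 0)
  v <- vegan::rda(scale(Y) ~ ., data = as.data.frame(scale(X)))
  expect_equal(f$R2, unname(vegan::RsquareAdj(v)$r.squared),
               tolerance = 1e-12)
  expect_equal(f$adj_R2, unname(vegan::RsquareAdj(v)$adj.r.squared),
               tolerance = 1e-12)
  expect_equal(unname(f$eigenvalues), unname(v$CCA$eig), tolerance = 1e-10)
  expect_equal(sum(f$proportion_of_model), 1, tolerance = 1e-12)
  # single response: R2 equals the univariate OLS R2
  f1 <- rda_fit(Y["r1"], X, n_perm = 0)
  ols <- summary(stats::lm(scale(Y$r1) ~ ., data = as.data.frame(scale(X))))
  expect_equal(f1$R2, ols$r.squared, tolerance = 1e-10)
  # responses orthogonal to predictors: R2 ~ 0 and p large
  Yn <- data.frame(r1 = stats::resid(stats::lm(stats::rnorm(n) ~ ., data = X)),
                   r2 = stats::resid(stats::lm(stats::rnorm(n) ~ ., data = X)))
  fn <- rda_fit(Yn, X, n_perm = 199, seed = 2)
  expect_lt(fn$R2, 0.01)
  expect_gt(fn$perm_p, 0.5)
  expect_error(rda_fit(data.frame(a = rep(1, n)), X), "constant")
})

test_that("variation partitioning matches vegan and its exact identities", {
  skip_if_not_installed("vegan")
  set.seed(31)
  n <- 49
  q <- qr.Q(qr(matrix(stats::rnorm(n * 3), n, 3)))
  s1 <- data.frame(a = q[, 1]); s2 <- data.frame(b = q[, 2])
  s3 <- data.frame(c = q[, 3])
  Y <- data.frame(y1 = q[, 1] + q[, 2] + q[, 3] + 0.3 * stats::rnorm(n))
  vp <- varpart3(Y, s1, s2, s3)
  # identity: fractions sum to the full-model adjusted R2 (and + residual = 1)
  expect_equal(sum(vp$fractions[1:7]), vp$adj_R2[["full"]], tolerance = 1e-9)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)
  # orthogonal single-predictor sets, additive response: unique fractions
  # match each set's own adjusted R2, shared parts ~ 0
  # (small systematic gaps remain because the adjusted R2 of nested models
  # counts different numbers of parameters)
  expect_lt(abs(vp$fractions[[1]] - vp$adj_R2[["set1"]]), 0.05)
  expect_lt(max(abs(vp$fractions[4:7])), 0.05)
  # duplicated set: essentially no unique contribution from either copy
  # (tiny negative values possible via the adjusted-R2 parameter counts)
  vp2 <- varpart3(Y, s1, s1, s3)
  expect_lt(abs(vp2$fractions[[1]]), 0.05)
  expect_lt(abs(vp2$fractions[[2]]), 0.05)
  expect_gt(vp2$fractions[["shared_set1_set2"]], 0.1)
  # cross-check all seven fractions against vegan::varpart
  vv <- vegan::varpart(scale(Y), scale(as.matrix(s1)), scale(as.matrix(s2)),
                       scale(as.matrix(s3)))
  expect_equal(unname(vp$fractions), vv$part$indfract$Adj.R.square,
               tolerance = 1e-9)
})
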