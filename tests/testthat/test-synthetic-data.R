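test_that("landscape simulation is deterministic, bounded and configurable", {
  cfg <- landscape_config(n_rows = 27, n_cols = 10, seed = 5)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_equal(nrow(a$covariates), 270)
  expect_equal(ncol(a$covariates), 29)  # cell_id + 28 variables
  pct <- grep("Perc$", names(a$covariates), value = TRUE)
  expect_length(pct, 14)
  for (v in pct)
    expect_true(all(a$covariates[[v]] >= 0 & a$covariates[[v]] <= 100))
  # zero latent variance -> constant covariates
  flat <- simulate_landscape(landscape_config(n_rows = 4, n_cols = 4,
                                              latent_scale = 0, seed = 5))
  expect_true(all(apply(flat$covariates[-1], 2,
                        function(x) diff(range(x))) == 0))
})

test_that("non-PSD covariate correlation matrices are rejected", {
  m <- diag(28); m[1, 2] <- m[2, 1] <- 1.5
  expect_error(landscape_config(covariate_cor = m),
               "positive semi-definite")
})

test_that("colony counts follow the covariate-linked Poisson model", {
  cfg <- landscape_config(n_rows = 10, n_cols = 10, seed = 2)
  land <- simulate_landscape(cfg)
  # mean 0 everywhere -> no colonies
  none <- simulate_colonies(land$grid, land$covariates,
                            density_model = list(intercept = 0, coefs = NULL),
                            seed = 3)
  expect_equal(nrow(none), 0)
  # constant mean 3 over 100 cells: total within 3 SD of 300
  const <- simulate_colonies(land$grid, land$covariates,
                             density_model = list(intercept = 3, coefs = NULL),
                             seed = 3)
  expect_lt(abs(nrow(const) - 300), 3 * sqrt(300))
  # determinism
  again <- simulate_colonies(land$grid, land$covariates,
                             density_model = list(intercept = 3, coefs = NULL),
                             seed = 3)
  expect_identical(const, again)
  # colonies sit inside their cells
  i <- match(const$cell_id, land$grid$cell_id)
  expect_true(all(const$lon >= land$grid$west[i] &
                    const$lon < land$grid$east[i]))
  # negative expected counts rejected
  expect_error(
    simulate_colonies(land$grid, land$covariates,
                      density_model = list(intercept = 0.1,
                                           coefs = c(roadPerc = -5))),
    "negative")
})

test_that("haplodiploid inheritance holds exactly without genotyping error", {
  freqs <- toy_freqs(k = 6, loci = paste0("L", 1:4))
  colonies <- data.frame(colony_id = 1:5, cell_id = 1, lon = 0, lat = 0,
                         kernel_scale_m = 0, n_workers = 4)
  gen <- simulate_genotypes(colonies, freqs, error_model(0, 0), seed = 9)
  # every worker carries the paternal allele at every locus
  m <- merge(gen$genotypes,
             merge(gen$workers, gen$parents, by = "colony_id"),
             by = c("worker_id", "locus"))
  expect_true(all(m$allele1 == m$father | m$allele2 == m$father))
  # two sisters share >= 1 allele at every locus
  sis <- gen$workers$worker_id[gen$workers$colony_id == 1][1:2]
  g1 <- gen$genotypes[gen$genotypes$worker_id == sis[1], ]
  g2 <- gen$genotypes[gen$genotypes$worker_id == sis[2], ]
  g2 <- g2[match(g1$locus, g2$locus), ]
  expect_true(all(g1$allele1 == g2$allele1 | g1$allele1 == g2$allele2 |
                    g1$allele2 == g2$allele1 | g1$allele2 == g2$allele2))
})

test_that("a monomorphic locus yields only homozygotes for its allele", {
  freqs <- toy_freqs(k = 1)
  colonies <- data.frame(colony_id = 1:3, cell_id = 1, lon = 0, lat = 0,
                         kernel_scale_m = 0, n_workers = 5)
  gen <- simulate_genotypes(colonies, freqs, error_model(0, 0), seed = 1)
  expect_true(all(gen$genotypes$allele1 == 102 & gen$genotypes$allele2 == 102))
})

test_that("empty frequency tables are rejected", {
  colonies <- data.frame(colony_id = 1, cell_id = 1, lon = 0, lat = 0,
                         kernel_scale_m = 0, n_workers = 2)
  expect_error(simulate_genotypes(colonies, structure(list(),
                                                      class = "allele_freqs")),
               "empty")
})

test_that("capture displacement follows the half-normal foraging kernel", {
  g <- make_grid(10, 10, 2000, c(-79.6, 43.58))
  colonies <- data.frame(colony_id = 1, cell_id = 55,
                         lon = mean(range(g$west)), lat = mean(range(g$south)),
                         kernel_scale_m = 500, n_workers = 4000)
  workers <- data.frame(worker_id = sprintf("W%05d", 1:4000), colony_id = 1)
  cap <- simulate_sampling(colonies, workers, g,
                           sampling_protocol(max_per_cell = 10000), seed = 4)
  d <- geodesic_distance(cbind(cap$lon, cap$lat),
                         cbind(colonies$lon, colonies$lat))
  # half-normal mean = sigma * sqrt(2/pi); SE of the mean ~ sigma*0.6/sqrt(n)
  expect_equal(mean(d), 500 * sqrt(2 / pi), tolerance = 0.02)
  # zero kernel scale -> capture at the colony
  colonies$kernel_scale_m <- 0
  cap0 <- simulate_sampling(colonies, workers[1:5, ], g,
                            sampling_protocol(), seed = 4)
  d0 <- geodesic_distance(cbind(cap0$lon, cap0$lat),
                          cbind(colonies$lon, colonies$lat))
  expect_true(all(d0 < 1e-6))
})

test_that("the per-cell capture cap and sampled-cell subset are honored", {
  cfg <- landscape_config(n_rows = 5, n_cols = 5, seed = 8)
  land <- simulate_landscape(cfg)
  colonies <- simulate_colonies(land$grid, land$covariates,
                                density_model = list(intercept = 4,
                                                     coefs = NULL), seed = 8)
  colonies$n_workers <- 10
  gen <- simulate_genotypes(colonies, toy_freqs(), seed = 8)
  cap <- simulate_sampling(colonies, gen$workers, land$grid,
                           sampling_protocol(max_per_cell = 1), seed = 8)
  expect_true(all(table(cap$cell_id) <= 1))
  cap2 <- simulate_sampling(colonies, gen$workers, land$grid,
                            sampling_protocol(cells_sampled = c(1L, 2L)),
                            seed = 8)
  expect_true(all(cap2$cell_id %in% c(1L, 2L)))
})
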