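# Synthetic study generator: landscape covariates, colonies, genotypes and
# foraging captures, with truth tables retained for parameter-recovery tests.

covariate_catalogue <- function() {
  # name, type and typical level/spread on the output scale. Percent-type
  # variables are generated through a logistic link so they stay in [0,100];
  # typical levels are plausible for a large North American city.
  pc <- function(name, p0, s = 1) data.frame(name = name, type = "percent",
                                             p0 = p0, mu = NA, sd = NA, s = s)
  wa <- function(name, mu, sd) data.frame(name = name, type = "wavg",
                                          p0 = NA, mu = mu, sd = sd, s = 1)
  rbind(
    pc("buildPerc", 0.15), pc("roofPerc", 0.002), pc("green1Perc", 0.08),
    data.frame(name = "treeCount", type = "count", p0 = NA, mu = 600,
               sd = NA, s = 0.4),
    pc("treeCanopyPerc", 0.25), pc("grassShrubPerc", 0.20),
    pc("waterPerc", 0.03), pc("bareEarthPerc", 0.02), pc("roadPerc", 0.12),
    pc("otherPavedPerc", 0.15), wa("elevat", 120, 30), wa("slope", 2.5, 1),
    pc("beachPerc", 0.004), pc("forestPerc", 0.05), pc("meadPerc", 0.02),
    pc("succPerc", 0.01), pc("wetPerc", 0.005),
    wa("popTotalCom", 15000, 5000), wa("popMale", 7300, 2500),
    wa("popFemale", 7700, 2500), wa("pop_less20", 3300, 1200),
    wa("pop_20_39", 4500, 1600), wa("pop_40_59", 4200, 1500),
    wa("pop_60plus", 3000, 1100), wa("popDensity", 4000, 1800),
    wa("houseDensity", 1700, 800), wa("indTI", 45000, 15000),
    wa("famTI", 95000, 30000)
  )
}

# Default latent correlation structure: an "urbanization" factor loading
# positively on built surfaces and population, negatively on green space.
# Factor construction keeps the implied correlation matrix PSD by design.
default_factor_loadings <- function(vars) {
  l <- stats::setNames(rep(0, length(vars)), vars)
  urban <- c(buildPerc = 0.7, roadPerc = 0.6, otherPavedPerc = 0.6,
             popDensity = 0.7, houseDensity = 0.5, popTotalCom = 0.6,
             popMale = 0.6, popFemale = 0.6, pop_less20 = 0.5,
             pop_20_39 = 0.5, pop_40_59 = 0.5, pop_60plus = 0.5,
             treeCanopyPerc = -0.5, green1Perc = -0.4, forestPerc = -0.45,
             grassShrubPerc = -0.3, meadPerc = -0.3, treeCount = 0.3)
  l[names(urban)] <- urban
  l
}

#' Configure a synthetic landscape
#'
#' @param n_rows,n_cols Grid dimensions (default 27 x 10 = 270 cells of a
#'   city-wide survey grid).
#' @param cell_size_m Cell side (meters, default 2000).
#' @param origin_lonlat South-west corner, WGS84 degrees.
#' @param gradient_weight Share of each covariate's latent variance carried
#'   by a smooth west-east/south-north gradient (0-1, default 0.4); the rest
#'   is cell-level noise, correlated across covariates.
#' @param covariate_cor Optional correlation matrix (28 x 28, covariate
#'   order of `covariate_catalogue()`) for the noise component. Must be
#'   positive semi-definite; if `NULL`, a one-factor "urbanization"
#'   structure is used.
#' @param latent_scale Multiplier on the latent fields' standard deviation
#'   (default 1); 0 collapses every covariate to its typical level
#'   (constant across cells).
#' @param seed Integer seed; all landscape randomness derives from it.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 27, n_cols = 10, cell_size_m = 2000,
                             origin_lonlat = c(-79.6, 43.58),
                             gradient_weight = 0.4, covariate_cor = NULL,
                             latent_scale = 1, seed = 1) {
  stopifnot(n_rows * n_cols >= 1, cell_size_m > 0,
            gradient_weight >= 0, gradient_weight <= 1, latent_scale >= 0)
  cat_ <- covariate_catalogue()
  if (!is.null(covariate_cor)) {
    if (!is.matrix(covariate_cor) ||
        any(dim(covariate_cor) != nrow(cat_)))
      stop("covariate_cor must be a ", nrow(cat_), " x ", nrow(cat_), " matrix")
    ev <- eigen(covariate_cor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("covariate correlation matrix is not positive semi-definite")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size_m = cell_size_m,
                 origin_lonlat = origin_lonlat,
                 gradient_weight = gradient_weight,
                 covariate_cor = covariate_cor, latent_scale = latent_scale,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Simulate a gridded landscape with physical and demographic covariates
#'
#' Generates, per grid cell, the 28 standard survey covariates (building,
#' road and paved-surface cover, green space, tree counts, elevation,
#' population structure, income, ...). Each covariate is a transform of a
#' latent Gaussian field composed of a shared smooth spatial gradient plus
#' correlated cell-level noise; percent-type covariates are mapped through a
#' logistic link to [0, 100], counts through an exponential link, and
#' weighted-average covariates are affine (clamped at zero where negative
#' values are physically meaningless).
#'
#' @param config A [landscape_config()].
#' @return List with `grid` (a [make_grid()] grid) and `covariates` (data
#'   frame: `cell_id` + 28 variables). Deterministic given `config$seed`.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  grid <- make_grid(config$n_rows, config$n_cols, config$cell_size_m,
                    config$origin_lonlat)
  cat_ <- covariate_catalogue()
  n_cell <- nrow(grid); n_var <- nrow(cat_)
  with_seed(derive_seed(config$seed, 11L), {
    # shared gradient field, standardized
    gfield <- 0.6 * grid$col / max(grid$col) + 0.4 * grid$row / max(grid$row)
    gfield <- if (stats::sd(gfield) > 0) as.numeric(scale(gfield))
    else rep(0, n_cell)
    noise <- matrix(stats::rnorm(n_cell * n_var), n_cell, n_var)
    if (is.null(config$covariate_cor)) {
      load <- default_factor_loadings(cat_$name)
      fac <- stats::rnorm(n_cell)
      noise <- outer(fac, load) +
        sweep(noise, 2, sqrt(1 - load^2), `*`)
    } else {
      es <- eigen(config$covariate_cor, symmetric = TRUE)
      rt <- es$vectors %*% diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
      noise <- noise %*% rt
    }
    w <- config$gradient_weight
    # latent fields, ~N(0,1) before the optional overall scaling
    z <- (config$latent_scale %||% 1) *
      (sqrt(w) * gfield + sqrt(1 - w) * noise)
    cov <- matrix(NA_real_, n_cell, n_var,
                  dimnames = list(NULL, cat_$name))
    for (j in seq_len(n_var)) {
      zj <- z[, j]
      cov[, j] <- switch(cat_$type[j],
        percent = 100 * stats::plogis(stats::qlogis(cat_$p0[j]) + 1.0 * zj),
        count   = round(cat_$mu[j] * exp(cat_$s[j] * zj)),
        wavg    = pmax(cat_$mu[j] + cat_$sd[j] * zj, 0)
      )
    }
    covariates <- data.frame(cell_id = grid$cell_id, cov,
                             check.names = FALSE)
    attr(covariates, "seed") <- config$seed
    list(grid = grid, covariates = covariates)
  })
}

#' Simulate colony placement from a covariate-linked density model
#'
#' Per-cell colony counts are Poisson with mean given by a linear link on
#' (standardized) covariates; colonies are placed uniformly within their
#' cell. Each colony also receives a foraging-kernel scale from a second
#' linear link, and a worker count.
#'
#' @param grid,covariates Output of [simulate_landscape()].
#' @param density_model List with `intercept`, named `coefs` and an
#'   optional `transform` (`"rank"`, the default, or `"scale"`): expected
#'   colonies per cell = `intercept + sum(coefs * t(covariate))`. With the
#'   rank transform each covariate is mapped to `2*(pctl - 0.5)` in
#'   (-1, 1), so the expectation stays inside
#'   `intercept +/- sum(|coefs|)` by construction; a model that still
#'   yields a negative expectation in any cell is rejected.
#' @param kernel_model Same shape; gives the per-cell half-normal foraging
#'   kernel scale in meters.
#' @param workers_mean Mean foraging workers per colony (Poisson; default 5).
#' @param seed Integer seed.
#' @return Data frame of colonies: `colony_id`, `cell_id`, `lon`, `lat`,
#'   `kernel_scale_m`, `n_workers`.
#' @export
simulate_colonies <- function(grid, covariates,
                              density_model = list(intercept = 3,
                                                   coefs = c(otherPavedPerc = -1)),
                              kernel_model = list(intercept = 600,
                                                  coefs = c(roadPerc = 250)),
                              workers_mean = 5, seed = 1) {
  lin <- function(model) {
    transform <- model$transform %||% "rank"
    x <- rep(model$intercept, nrow(covariates))
    for (nm in names(model$coefs)) {
      if (!nm %in% names(covariates)) stop("unknown covariate: ", nm)
      v <- covariates[[nm]]
      t_ <- switch(transform,
                   rank = 2 * (rank(v) / (length(v) + 1) - 0.5),
                   scale = as.numeric(scale(v)),
                   stop("unknown covariate transform: ", transform))
      x <- x + model$coefs[[nm]] * t_
    }
    x
  }
  lambda <- lin(density_model)
  if (any(lambda < 0))
    stop("density model yields negative expected colony counts; ",
         "shrink its coefficients or raise the intercept")
  kscale <- pmax(lin(kernel_model), 0)
  with_seed(derive_seed(seed, 23L), {
    counts <- stats::rpois(length(lambda), lambda)
    cells <- rep(grid$cell_id, counts)
    n_col <- sum(counts)
    if (n_col == 0L)
      return(data.frame(colony_id = integer(), cell_id = integer(),
                        lon = numeric(), lat = numeric(),
                        kernel_scale_m = numeric(), n_workers = integer()))
    i <- match(cells, grid$cell_id)
    lon <- stats::runif(n_col, grid$west[i], grid$east[i])
    lat <- stats::runif(n_col, grid$south[i], grid$north[i])
    data.frame(
      colony_id = seq_len(n_col), cell_id = cells, lon = lon, lat = lat,
      kernel_scale_m = kscale[i],
      n_workers = stats::rpois(n_col, workers_mean)
    )
  })
}

#' Genotyping error model
#'
#' @param dropout_rate Per-allele probability of a missing call (default 0).
#' @param mistype_rate Per-allele probability that the observed allele is
#'   replaced by a random allele drawn from the locus frequencies
#'   (default 0.01, covering miscalls and mutations).
#' @return An `error_model` list.
#' @export
error_model <- function(dropout_rate = 0, mistype_rate = 0.01) {
  structure(list(dropout_rate = assert_prob(dropout_rate, "dropout_rate"),
                 mistype_rate = assert_prob(mistype_rate, "mistype_rate")),
            class = "error_model")
}

#' Simulate worker genotypes under haplodiploidy
#'
#' Each colony has one diploid queen (two alleles i.i.d. from the locus
#' frequencies) mated to a single haploid male (one allele). Every worker
#' inherits one maternal allele (probability 1/2 each) plus the paternal
#' allele, so full sisters always share their father's allele. Each observed
#' allele is then independently mistyped (replaced by a frequency-weighted
#' random allele) with probability `error$mistype_rate`; a dropout renders
#' the whole locus call missing for that worker.
#'
#' @param colonies Data frame from [simulate_colonies()].
#' @param allele_freqs An `allele_freqs` list (e.g.
#'   [allele_freqs_from_loci()]).
#' @param error An [error_model()].
#' @param seed Integer seed.
#' @return List with `genotypes` (worker x locus long table: `worker_id`,
#'   `locus`, `allele1`, `allele2`), `workers` (truth table `worker_id`,
#'   `colony_id`) and `parents` (queen/father genotypes per colony).
#' @export
simulate_genotypes <- function(colonies, allele_freqs, error = error_model(),
                               seed = 1) {
  check_allele_freqs(allele_freqs)
  stopifnot(inherits(error, "error_model"))
  n_workers <- sum(colonies$n_workers)
  worker_col <- rep(colonies$colony_id, colonies$n_workers)
  worker_id <- sprintf("W%05d", seq_len(max(n_workers, 0)))
  loci <- names(allele_freqs)
  with_seed(derive_seed(seed, 37L), {
    geno <- vector("list", length(loci))
    parents <- vector("list", length(loci))
    draw <- function(sizes, p, n) {
      if (length(sizes) == 1L) rep(sizes, n)   # sample() would misread this
      else sample(sizes, n, replace = TRUE, prob = p)
    }
    for (li in seq_along(loci)) {
      p <- allele_freqs[[li]]
      sizes <- as.numeric(names(p))
      nc <- nrow(colonies)
      qa <- draw(sizes, p, nc)
      qb <- draw(sizes, p, nc)
      fa <- draw(sizes, p, nc)
      parents[[li]] <- data.frame(colony_id = colonies$colony_id,
                                  locus = loci[li],
                                  queen_a = qa, queen_b = qb, father = fa)
      if (n_workers == 0L) { geno[[li]] <- NULL; next }
      ci <- match(worker_col, colonies$colony_id)
      maternal <- ifelse(stats::runif(n_workers) < 0.5, qa[ci], qb[ci])
      paternal <- fa[ci]
      mist <- function(a) {
        hit <- stats::runif(n_workers) < error$mistype_rate
        a[hit] <- draw(sizes, p, sum(hit))
        a
      }
      maternal <- mist(maternal); paternal <- mist(paternal)
      drop1 <- stats::runif(n_workers) < error$dropout_rate
      drop2 <- stats::runif(n_workers) < error$dropout_rate
      miss <- drop1 | drop2    # losing either allele voids the locus call
      a1 <- pmin(maternal, paternal); a2 <- pmax(maternal, paternal)
      a1[miss] <- NA; a2[miss] <- NA
      geno[[li]] <- data.frame(worker_id = worker_id, locus = loci[li],
                               allele1 = a1, allele2 = a2)
    }
    list(
      genotypes = do.call(rbind, geno),
      workers = data.frame(worker_id = worker_id, colony_id = worker_col),
      parents = do.call(rbind, parents)
    )
  })
}

#' Sampling protocol for netted captures
#'
#' @param max_per_cell Cap on captures per grid cell (default 60, the
#'   per-cell collection target of the field protocol).
#' @param cells_sampled Integer vector of cell ids visited by collectors;
#'   captures falling in unvisited cells are discarded. `NULL` = all cells.
#' @return A `sampling_protocol` list.
#' @export
sampling_protocol <- function(max_per_cell = 60, cells_sampled = NULL) {
  stopifnot(max_per_cell >= 1)
  structure(list(max_per_cell = as.integer(max_per_cell),
                 cells_sampled = cells_sampled),
            class = "sampling_protocol")
}

#' Simulate netted captures of foraging workers
#'
#' Each worker's capture point is its colony location displaced isotropically
#' by a half-normal distance (scale = the colony's `kernel_scale_m`), so the
#' mean capture distance is `scale * sqrt(2/pi)`. Sisters may be netted in
#' different cells than their natal one. Captures are restricted to sampled
#' cells and truncated at `max_per_cell` per capture cell (a uniformly
#' random subset is kept).
#'
#' @param colonies Data frame from [simulate_colonies()].
#' @param workers Worker truth table from [simulate_genotypes()].
#' @param grid A [make_grid()] grid.
#' @param protocol A [sampling_protocol()].
#' @param seed Integer seed.
#' @return Capture table: `worker_id`, `lon`, `lat`, `date`, `cell_id`,
#'   with the worker-to-colony truth mapping retained in the `truth`
#'   attribute.
#' @export
simulate_sampling <- function(colonies, workers, grid,
                              protocol = sampling_protocol(), seed = 1) {
  stopifnot(inherits(protocol, "sampling_protocol"))
  n <- nrow(workers)
  ci <- match(workers$colony_id, colonies$colony_id)
  with_seed(derive_seed(seed, 53L), {
    dist <- abs(stats::rnorm(n, 0, colonies$kernel_scale_m[ci]))
    theta <- stats::runif(n, 0, 2 * pi)
    k <- pi / 180 * EARTH_RADIUS_M
    lat0 <- colonies$lat[ci]
    lon <- colonies$lon[ci] + dist * sin(theta) / (k * cos(lat0 * pi / 180))
    lat <- lat0 + dist * cos(theta) / k
    cell <- cell_of(grid, lon, lat)
    date <- as.Date("2016-07-01") +
      sample.int(120, n, replace = TRUE) - 1
    cap <- data.frame(worker_id = workers$worker_id, lon = lon, lat = lat,
                      date = as.character(date), cell_id = cell)
    keep <- !is.na(cap$cell_id)
    if (!is.null(protocol$cells_sampled))
      keep <- keep & cap$cell_id %in% protocol$cells_sampled
    cap <- cap[keep, , drop = FALSE]
    # per-cell truncation: keep a random subset of at most max_per_cell
    split_idx <- split(seq_len(nrow(cap)), cap$cell_id)
    kept <- unlist(lapply(split_idx, function(ix) {
      if (length(ix) <= protocol$max_per_cell) ix
      else sample(ix, protocol$max_per_cell)
    }), use.names = FALSE)
    cap <- cap[sort(kept), , drop = FALSE]
    rownames(cap) <- NULL
    attr(cap, "truth") <- workers[match(cap$worker_id, workers$worker_id), ]
    attr(cap, "seed") <- seed
    cap
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining [simulate_landscape()],
#' [simulate_colonies()], [simulate_genotypes()] and [simulate_sampling()],
#' subsetting genotypes to captured workers (uncaptured bees are never
#' genotyped in a real survey).
#'
#' @param config A [landscape_config()]; its seed drives all stages.
#' @param density_model,kernel_model,workers_mean See [simulate_colonies()].
#' @param allele_freqs,error See [simulate_genotypes()].
#' @param protocol See [simulate_sampling()].
#' @return List: `grid`, `covariates`, `colonies`, `captures`, `genotypes`,
#'   `truth` (worker to colony mapping for captured workers), `seed`.
#' @export
simulate_study <- function(config = landscape_config(),
                           density_model = list(intercept = 3,
                                                coefs = c(otherPavedPerc = -1)),
                           kernel_model = list(intercept = 600,
                                               coefs = c(roadPerc = 250)),
                           workers_mean = 5,
                           allele_freqs = allele_freqs_from_loci(),
                           error = error_model(),
                           protocol = sampling_protocol()) {
  land <- simulate_landscape(config)
  colonies <- simulate_colonies(land$grid, land$covariates,
                                density_model, kernel_model,
                                workers_mean, seed = config$seed)
  gen <- simulate_genotypes(colonies, allele_freqs, error,
                            seed = config$seed)
  captures <- simulate_sampling(colonies, gen$workers, land$grid,
                                protocol, seed = config$seed)
  genotypes <- gen$genotypes[gen$genotypes$worker_id %in% captures$worker_id, ,
                             drop = FALSE]
  rownames(genotypes) <- NULL
  list(grid = land$grid, covariates = land$covariates, colonies = colonies,
       captures = captures, genotypes = genotypes,
       truth = attr(captures, "truth"), seed = config$seed)
}
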