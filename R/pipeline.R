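# End-to-end orchestration: simulate (or load) -> sibship -> QC -> colony
# metrics -> landscape statistics, as one seeded, configured, logged run.

default_categories <- function() {
  list(
    demography = c("popDensity", "indTI", "popTotalCom", "pop_40_59",
                   "pop_60plus"),
    infrastructure = c("buildPerc", "houseDensity", "roadPerc",
                       "otherPavedPerc"),
    natural = c("meadPerc", "green1Perc", "grassShrubPerc", "forestPerc",
                "bareEarthPerc", "treeCount", "elevat", "treeCanopyPerc")
  )
}

#' Configure a pipeline run
#'
#' @param out_dir Run directory for outputs (created if absent).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Final stage to reach: one of `"simulate"`, `"sibship"`,
#'   `"qc"`, `"metrics"`, `"stats"`; earlier stages run automatically.
#' @param genotype_file,capture_file,covariate_file Optional CSV inputs; if
#'   all `NULL`, data are simulated with `sim`.
#' @param sim A [landscape_config()] plus generator options, as produced by
#'   [landscape_config()]; used only when simulating.
#' @param density_model,kernel_model,workers_mean,protocol Generator
#'   options forwarded to [simulate_study()].
#' @param m,n Mating frequency and queens per colony for
#'   [effective_colonies()].
#' @param min_support,coord_tol_m Sibship retention threshold and
#'   identical-coordinate tolerance (meters).
#' @param restarts Sibship reconstruction restarts.
#' @param n_perm RDA permutations.
#' @param hwe_shuffles Monte-Carlo shuffles for the HWE screen.
#' @param max_subset Largest best-subset model size.
#' @param categories Named list assigning covariates to the three varpart
#'   categories (`demography`, `infrastructure`, `natural`); every
#'   covariate used must appear in exactly one category.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("colonyscape_run_"), seed = 1,
                       stages = "stats", genotype_file = NULL,
                       capture_file = NULL, covariate_file = NULL,
                       sim = landscape_config(seed = seed),
                       density_model = list(intercept = 3,
                                            coefs = c(otherPavedPerc = -1)),
                       kernel_model = list(intercept = 600,
                                           coefs = c(roadPerc = 250)),
                       workers_mean = 5, protocol = sampling_protocol(),
                       m = 1, n = 1, min_support = 0.80, coord_tol_m = 0.5,
                       restarts = 3, n_perm = 999, hwe_shuffles = 10000,
                       max_subset = 6, categories = default_categories()) {
  stages <- match.arg(stages, c("simulate", "sibship", "qc", "metrics",
                                "stats"))
  cfg <- as.list(environment())
  allv <- unlist(categories, use.names = FALSE)
  if (anyDuplicated(allv))
    stop("covariates assigned to more than one category: ",
         paste(unique(allv[duplicated(allv)]), collapse = ", "))
  for (f in c(genotype_file, capture_file, covariate_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file does not exist: ", f)
  structure(cfg, class = "run_config")
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# colonyscape config_hash=%s seed=%d",
                     stamp$hash, stamp$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Run the full inference pipeline
#'
#' Executes the configured stages in dependency order, logging record
#' counts at every filter (workers in, clusters retained at the support
#' threshold, triangulable clusters, colonies per cell) and writing CSV/JSON
#' outputs stamped with the configuration hash and seed. Re-running with an
#' identical configuration reproduces identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results of each executed
#'   stage plus `out_dir` and `config_hash`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[colonyscape] ", ...)
  order_ <- c("simulate", "sibship", "qc", "metrics", "stats")
  todo <- order_[seq_len(match(config$stages, order_))]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(hash = config_hash(config[setdiff(names(config), "out_dir")]),
                seed = as.integer(config$seed))
  res <- list(out_dir = config$out_dir, config_hash = stamp$hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate or load -------------------------------------------------
  stage("simulate", {
    if (is.null(config$genotype_file)) {
      say("simulating study (seed ", config$seed, ")")
      study <- simulate_study(config$sim, config$density_model,
                              config$kernel_model, config$workers_mean,
                              protocol = config$protocol)
      res$grid <- study$grid
      res$covariates <- study$covariates
      res$genotypes <- study$genotypes
      res$captures <- study$captures
      res$truth <- study$truth
      if ("simulate" %in% todo) {
        write_stamped_csv(study$genotypes,
                          file.path(config$out_dir, "genotypes.csv"), stamp)
        write_stamped_csv(study$captures,
                          file.path(config$out_dir, "captures.csv"), stamp)
        write_stamped_csv(study$covariates,
                          file.path(config$out_dir, "covariates.csv"), stamp)
        write_stamped_csv(study$truth,
                          file.path(config$out_dir, "truth_workers.csv"),
                          stamp)
        write_stamped_csv(study$colonies[, setdiff(names(study$colonies),
                                                   "member_distances")],
                          file.path(config$out_dir, "truth_colonies.csv"),
                          stamp)
        grid_to_geojson(study$grid,
                        file.path(config$out_dir, "grid.geojson"))
      }
    } else {
      say("loading inputs")
      res$genotypes <- read_stamped_csv(config$genotype_file)
      res$captures <- read_stamped_csv(config$capture_file)
      res$covariates <- read_stamped_csv(config$covariate_file)
      res$grid <- make_grid(config$sim$n_rows, config$sim$n_cols,
                            config$sim$cell_size_m,
                            config$sim$origin_lonlat)
    }
    say(length(unique(res$genotypes$worker_id)), " genotyped workers in")
  })
  if (config$stages == "simulate") return(invisible(res))

  # -- sibship ----------------------------------------------------------
  stage("sibship", {
    part <- reconstruct_sibships(res$genotypes, restarts = config$restarts,
                                 seed = config$seed)
    res$partition_raw <- part
    res$partition <- filter_clusters(part, config$min_support)
    sz <- lengths(res$partition$clusters)
    say(sum(sz >= 2), " clusters (>=2 sisters, support >= ",
        config$min_support, ") holding ", sum(sz[sz >= 2]),
        " workers; ", sum(sz == 1), " singletons")
    write_stamped_csv(as.data.frame(res$partition),
                      file.path(config$out_dir, "sibship_partition.csv"),
                      stamp)
    jsonlite::write_json(
      list(config_hash = stamp$hash, seed = stamp$seed,
           restart_logliks = part$restart_logliks,
           total_loglik = part$total_loglik),
      file.path(config$out_dir, "sibship_summary.json"),
      auto_unbox = TRUE, digits = NA)
  })
  if (config$stages == "sibship") return(invisible(res))

  # -- popgen QC --------------------------------------------------------
  stage("qc", {
    pruned <- prune_one_per_colony(res$genotypes, res$partition,
                                   seed = config$seed)
    res$qc <- popgen_qc_table(pruned, n_shuffles = config$hwe_shuffles,
                              seed = config$seed)
    say("QC on ", length(unique(pruned$worker_id)),
        " colony-pruned workers; ", sum(res$qc$hwe_flag),
        " locus/loci flagged for HWE departure")
    write_stamped_csv(res$qc, file.path(config$out_dir, "popgen_qc.csv"),
                      stamp)
  })
  if (config$stages == "qc") return(invisible(res))

  # -- colony metrics ---------------------------------------------------
  stage("metrics", {
    tri <- triangulable_clusters(res$partition, res$captures,
                                 config$coord_tol_m)
    say(length(tri$clusters), " triangulable clusters (",
        sum(lengths(tri$clusters)), " workers)")
    res$colonies <- colony_records(tri, res$captures, res$grid)
    res$cells <- summarize_cells(res$colonies, res$grid,
                                 m = config$m, n = config$n)
    say(nrow(res$cells), " grid cells with >=1 colony; mean colNe ",
        round(mean(res$cells$colNe), 2), ", mean aveMeanFD ",
        round(mean(res$cells$aveMeanFD_m)), " m")
    write_stamped_csv(res$colonies[, c("colony_id", "lon", "lat", "cell_id",
                                       "n_members", "mean_fd_m")],
                      file.path(config$out_dir, "colonies.csv"), stamp)
    write_stamped_csv(res$cells,
                      file.path(config$out_dir, "cell_summary.csv"), stamp)
  })
  if (config$stages == "metrics") return(invisible(res))

  # -- landscape statistics --------------------------------------------
  stage("stats", {
    cells <- res$cells
    cov <- res$covariates[match(cells$cell_id, res$covariates$cell_id), ,
                          drop = FALSE]
    vars <- intersect(unlist(config$categories, use.names = FALSE),
                      names(cov))
    dat <- cbind(cells[, c("colNe", "ln_aveMeanFD")],
                 cov[, vars, drop = FALSE])
    res$spearman <- spearman_fdr(dat)
    res$vif <- vif_screen(cov[, vars, drop = FALSE])
    res$best_colne <- best_subset_regression(
      cells$colNe, cov[, vars, drop = FALSE],
      max_size = config$max_subset)
    res$best_fd <- best_subset_regression(
      cells$ln_aveMeanFD, cov[, vars, drop = FALSE],
      max_size = config$max_subset)
    res$rda <- rda_fit(cells[, c("ln_aveMeanFD", "colNe")],
                       cov[, vars, drop = FALSE],
                       n_perm = config$n_perm, seed = config$seed)
    cats <- lapply(config$categories, function(v)
      cov[, intersect(v, names(cov)), drop = FALSE])
    res$varpart <- varpart3(cells[, c("ln_aveMeanFD", "colNe")],
                            cats$demography, cats$infrastructure,
                            cats$natural,
                            labels = c("demography", "infrastructure",
                                       "natural"))
    say(sprintf("RDA: R2 = %.1f%%, permutation p = %.4g",
                100 * res$rda$R2, res$rda$perm_p))
    write_stamped_csv(as.data.frame(res$spearman$rho),
                      file.path(config$out_dir, "spearman_rho.csv"), stamp)
    write_stamped_csv(as.data.frame(res$spearman$p_adj),
                      file.path(config$out_dir, "spearman_p_adj.csv"),
                      stamp)
    write_stamped_csv(res$vif, file.path(config$out_dir, "vif.csv"), stamp)
    write_stamped_csv(res$best_colne$models,
                      file.path(config$out_dir, "best_models_colNe.csv"),
                      stamp)
    write_stamped_csv(res$best_fd$models,
                      file.path(config$out_dir, "best_models_lnFD.csv"),
                      stamp)
    jsonlite::write_json(
      list(config_hash = stamp$hash, seed = stamp$seed,
           rda = list(R2 = res$rda$R2, adj_R2 = res$rda$adj_R2,
                      proportion_of_model = res$rda$proportion_of_model,
                      proportion_of_total = res$rda$proportion_of_total,
                      perm_p = res$rda$perm_p),
           varpart = as.list(res$varpart$fractions),
           varpart_totals = as.list(varpart3_totals(res$varpart))),
      file.path(config$out_dir, "landscape_stats.json"),
      auto_unbox = TRUE, digits = NA)
  })
  invisible(res)
}
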