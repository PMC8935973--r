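# Per-locus descriptive genetics and Hardy-Weinberg screening on a
# colony-pruned dataset (one sister retained per family, so family structure
# does not masquerade as HWE departure).

#' Prune a genotype table to one worker per colony
#'
#' Randomly retains one sister from each multi-member sibship cluster
#' (uniformly, seeded); singletons are all retained. Workers not covered by
#' the partition are kept.
#'
#' @param genotypes Long genotype table.
#' @param partition A `sibship_partition` whose clusters cover a subset of
#'   the genotyped workers.
#' @param seed Integer seed.
#' @return The genotype table restricted to the retained workers.
#' @export
prune_one_per_colony <- function(genotypes, partition, seed = 1) {
  check_genotypes(genotypes)
  clusters <- if (inherits(partition, "sibship_partition"))
    partition$clusters else partition
  ids <- unique(genotypes$worker_id)
  covered <- unlist(clusters, use.names = FALSE)
  if (!all(covered %in% ids))
    stop("partition contains workers absent from the genotype table")
  keep <- with_seed(derive_seed(seed, 89L), {
    unlist(lapply(clusters, function(ws)
      if (length(ws) == 1L) ws else ws[sample.int(length(ws), 1L)]),
      use.names = FALSE)
  })
  keep <- c(keep, setdiff(ids, covered))
  out <- genotypes[genotypes$worker_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-locus summaries: allele counts, size ranges, heterozygosities
#'
#' Observed heterozygosity is the fraction of heterozygous non-missing
#' genotypes. Expected heterozygosity is Nei's unbiased estimator
#' `(2n/(2n-1)) * (1 - sum(p_i^2))` with allele frequencies from observed
#' counts. Loci with all calls missing are excluded (with a warning).
#'
#' @param genotypes Long genotype table.
#' @return Data frame: `locus`, `n`, `n_alleles`, `size_min`, `size_max`,
#'   `Ho`, `He`.
#' @export
locus_summaries <- function(genotypes) {
  check_genotypes(genotypes)
  loci <- unique(genotypes$locus)
  rows <- lapply(loci, function(l) {
    g <- genotypes[genotypes$locus == l, , drop = FALSE]
    g <- g[!is.na(g$allele1) & !is.na(g$allele2), , drop = FALSE]
    if (!nrow(g)) return(NULL)
    n <- nrow(g)
    if (n < 2)
      stop("locus ", l, " has fewer than 2 non-missing genotypes")
    a <- c(g$allele1, g$allele2)
    p <- as.numeric(table(a)) / length(a)
    data.frame(locus = l, n = n, n_alleles = length(p),
               size_min = min(a), size_max = max(a),
               Ho = mean(g$allele1 != g$allele2),
               He = (2 * n / (2 * n - 1)) * (1 - sum(p^2)))
  })
  dropped <- loci[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("locus/loci with all calls missing excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg screening by Monte-Carlo allele permutation
#'
#' Per locus, the observed heterozygote count is compared with its null
#' distribution obtained by randomly re-pairing the observed alleles
#' (`n_shuffles` seeded permutations). The two-sided p-value doubles the
#' smaller mid-p tail (mid-p keeps the discrete permutation p close to
#' uniform under the null), floored at `1/(n_shuffles+1)`; loci are flagged
#' when `p < alpha / L` (Bonferroni over the `L` loci tested).
#'
#' @param genotypes Long genotype table.
#' @param alpha Family-wise error rate for the Bonferroni flag (default
#'   0.05).
#' @param n_shuffles Permutations per locus (>= 100; default 10000).
#' @param seed Integer seed.
#' @return Data frame: `locus`, `n`, `het_obs`, `het_null_mean`, `hwe_p`,
#'   `hwe_flag`, with the per-locus Bonferroni threshold in the
#'   `"threshold"` attribute.
#' @export
hwe_test <- function(genotypes, alpha = 0.05, n_shuffles = 10000, seed = 1) {
  check_genotypes(genotypes)
  if (n_shuffles < 100) stop("need at least 100 shuffles")
  loci <- unique(genotypes$locus)
  res <- with_seed(derive_seed(seed, 97L), {
    lapply(loci, function(l) {
      g <- genotypes[genotypes$locus == l, , drop = FALSE]
      g <- g[!is.na(g$allele1) & !is.na(g$allele2), , drop = FALSE]
      n <- nrow(g)
      if (n < 5)
        stop("locus ", l, " has fewer than 5 non-missing genotypes")
      alleles <- c(g$allele1, g$allele2)
      het_obs <- sum(g$allele1 != g$allele2)
      het_null <- vapply(seq_len(n_shuffles), function(s) {
        a <- sample(alleles)
        sum(a[seq_len(n)] != a[n + seq_len(n)])
      }, numeric(1))
      ties <- 0.5 * sum(het_null == het_obs)
      lo <- (sum(het_null < het_obs) + ties) / n_shuffles
      hi <- (sum(het_null > het_obs) + ties) / n_shuffles
      p <- max(min(1, 2 * min(lo, hi)), 1 / (n_shuffles + 1))
      data.frame(locus = l, n = n, het_obs = het_obs,
                 het_null_mean = mean(het_null), hwe_p = p)
    })
  })
  out <- do.call(rbind, res)
  threshold <- alpha / nrow(out)
  out$hwe_flag <- out$hwe_p < threshold
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

#' One-stop per-locus QC table
#'
#' Combines [locus_summaries()] and [hwe_test()] into the standard
#' locus-by-locus report (allele count, size range, Ho, He, HWE p and
#' Bonferroni flag).
#'
#' @inheritParams hwe_test
#' @return Data frame, one row per locus.
#' @export
popgen_qc_table <- function(genotypes, alpha = 0.05, n_shuffles = 10000,
                            seed = 1) {
  s <- locus_summaries(genotypes)
  h <- hwe_test(genotypes, alpha = alpha, n_shuffles = n_shuffles,
                seed = seed)
  out <- merge(s, h[, c("locus", "hwe_p", "hwe_flag")], by = "locus",
               sort = FALSE)
  attr(out, "threshold") <- attr(h, "threshold")
  out
}
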