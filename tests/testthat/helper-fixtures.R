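# Shared fixtures and small oracles, all built in code.

# A tiny equifrequent frequency table.
toy_freqs <- function(k = 4, loci = "L1", base_size = 100) {
  out <- lapply(loci, function(l)
    stats::setNames(rep(1 / k, k), as.character(base_size + 2 * seq_len(k))))
  names(out) <- loci
  class(out) <- c("allele_freqs", "list")
  out
}

# Long genotype table from a worker x (locus:2) allele matrix.
geno_table <- function(mat, loci) {
  ids <- sprintf("W%03d", seq_len(nrow(mat)))
  do.call(rbind, lapply(seq_along(loci), function(li) {
    data.frame(worker_id = ids, locus = loci[li],
               allele1 = pmin(mat[, 2 * li - 1], mat[, 2 * li]),
               allele2 = pmax(mat[, 2 * li - 1], mat[, 2 * li]))
  }))
}

# Brute-force full-sib likelihood: exhaustive sum over ordered queen
# genotypes (a, b) and father allele c, with the same observation model as
# the package (each observed allele true w.p. 1-e, else a random allele).
# Deliberately naive and independent of the package's collapsed-space code.
brute_fullsib_loglik <- function(members, freqs, e) {
  # members: list of c(o1, o2) observed allele pairs (single locus)
  sizes <- as.numeric(names(freqs))
  p <- as.numeric(freqs)
  q <- function(o, t) (1 - e) * (o == t) + e * p[match(o, sizes)]
  p_obs_given_true <- function(o1, o2, t1, t2) {
    if (o1 != o2) q(o1, t1) * q(o2, t2) + q(o2, t1) * q(o1, t2)
    else q(o1, t1) * q(o1, t2)
  }
  total <- 0
  for (ai in seq_along(sizes)) for (bi in seq_along(sizes))
    for (ci in seq_along(sizes)) {
      a <- sizes[ai]; b <- sizes[bi]; c_ <- sizes[ci]
      lik <- p[ai] * p[bi] * p[ci]
      for (m in members) {
        lik <- lik * (0.5 * p_obs_given_true(m[1], m[2], a, c_) +
                        0.5 * p_obs_given_true(m[1], m[2], b, c_))
      }
      total <- total + lik
    }
  log(total)
}

# Simulate `n_fam` full-sib families of `fam_size` workers with the panel's
# published diversity; returns genotypes plus the true family labels.
sim_families <- function(n_fam, fam_size, error = error_model(), seed = 1) {
  freqs <- allele_freqs_from_loci()
  colonies <- data.frame(colony_id = seq_len(n_fam), cell_id = 1,
                         lon = 0, lat = 0, kernel_scale_m = 0,
                         n_workers = fam_size)
  gen <- simulate_genotypes(colonies, freqs, error, seed = seed)
  list(genotypes = gen$genotypes, truth = gen$workers, freqs = freqs)
}

# Mann-Whitney AUC: probability a random positive scores above a random
# negative (ties counted half).
auc_mw <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Brute-force BH step-up: the definitional procedure, independent of
# p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Partition -> integer labels in worker order, for ARI computations.
partition_labels <- function(partition, worker_ids) {
  df <- as.data.frame(partition)
  df$cluster_id[match(worker_ids, df$worker_id)]
}
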