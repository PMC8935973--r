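# Full-sib family reconstruction under haplodiploidy, monogyny and monoandry.
#
# Model: each colony has one diploid queen (alleles a, b drawn from the
# population frequencies) and one haploid father (allele c). A worker's true
# genotype at a locus is {x, c} with x = a or b (probability 1/2 each). Each
# observed allele is, independently, the true allele with probability 1 - e
# or a random allele drawn from the locus frequencies with probability e
# (mistype). The likelihood of a putative full-sib cluster integrates over
# (a, b, c) with Hardy-Weinberg priors.
#
# The sum over (a, b, c) is computed exactly on a collapsed allele space:
# alleles not observed in any cluster member are pooled into a single "rest"
# class (the summand is constant across them, so pooling with the summed
# frequency is exact). This keeps evaluation fast even for loci with 30
# alleles.

# --- internal locus-level machinery ----------------------------------------

# observation model: probability that allele `obs` is reported when the true
# allele is `true`: (1-e) on a match plus e * p(obs) always.
# p_obs is the frequency of the observed allele (floored if unseen).

# Exact log-likelihood of one cluster at one locus.
# obs1, obs2: numeric vectors of the members' observed alleles (NA = missing
# locus call, which contributes a factor of 1).
locus_cluster_loglik <- function(obs1, obs2, freqs, e, floor_freq) {
  typed <- !is.na(obs1)
  if (!any(typed)) return(0)
  o1 <- obs1[typed]; o2 <- obs2[typed]
  alle <- sort(unique(c(o1, o2)))
  fr <- freqs[as.character(alle)]
  fr[is.na(fr)] <- floor_freq
  p_rest <- max(1 - sum(freqs), 0) + sum(freqs[!names(freqs) %in% as.character(alle)])
  has_rest <- p_rest > 0
  k <- length(alle) + has_rest
  p <- c(as.numeric(fr), if (has_rest) p_rest)
  # match observed alleles to the collapsed space (rest never matches an obs)
  m1 <- match(o1, alle); m2 <- match(o2, alle)
  pob1 <- p[m1]; pob2 <- p[m2]
  n <- length(o1)
  # q[w, t]: P(observe member w's first/second allele | true allele t)
  tmat <- matrix(seq_len(k), n, k, byrow = TRUE)
  q1 <- (1 - e) * (tmat == m1) + e * pob1
  q2 <- (1 - e) * (tmat == m2) + e * pob2
  # unordered true genotypes (i <= j)
  gi <- rep(seq_len(k), times = k:1)
  gj <- unlist(lapply(seq_len(k), function(i) i:k))
  het <- o1 != o2
  V <- matrix(NA_real_, n, length(gi))
  if (any(het))
    V[het, ] <- q1[het, gi, drop = FALSE] * q2[het, gj, drop = FALSE] +
      q2[het, gi, drop = FALSE] * q1[het, gj, drop = FALSE]
  if (any(!het))
    V[!het, ] <- q1[!het, gi, drop = FALSE] * q1[!het, gj, drop = FALSE]
  # genotype lookup: index of unordered pair (i, j)
  gidx <- matrix(0L, k, k)
  gidx[cbind(gi, gj)] <- seq_along(gi)
  gidx[cbind(gj, gi)] <- seq_along(gi)
  # parental combos: queen pair (a <= b) x father c
  qa <- rep(gi, each = k); qb <- rep(gj, each = k)
  fc <- rep(seq_len(k), times = length(gi))
  prior <- p[qa] * p[qb] * ifelse(qa == qb, 1, 2) * p[fc]
  fac_ac <- V[, gidx[cbind(qa, fc)], drop = FALSE]
  fac_bc <- V[, gidx[cbind(qb, fc)], drop = FALSE]
  W <- 0.5 * (fac_ac + fac_bc)
  prod_w <- W[1, ]
  if (n > 1) for (w in 2:n) prod_w <- prod_w * W[w, ]
  log(sum(prior * prod_w))
}

# Hardy-Weinberg log-probability of a single member's observed genotypes
# (same error model); vectorized over members via the cluster machinery with
# one member, which reduces to the HWE null exactly.
locus_unrelated_loglik <- function(obs1, obs2, freqs, e, floor_freq) {
  typed <- which(!is.na(obs1))
  sum(vapply(typed, function(i)
    locus_cluster_loglik(obs1[i], obs2[i], freqs, e, floor_freq),
    numeric(1)))
}

# long genotype table -> per-locus observation matrices for a set of workers
geno_obs <- function(genotypes, loci, worker_ids) {
  lapply(loci, function(l) {
    g <- genotypes[genotypes$locus == l, , drop = FALSE]
    i <- match(worker_ids, g$worker_id)
    cbind(a1 = g$allele1[i], a2 = g$allele2[i])
  })
}

default_floor <- function(allele_freqs) {
  n <- attr(allele_freqs, "n", exact = TRUE)
  n <- if (is.null(n)) 100 else max(n)
  1 / (2 * n + 1)
}

#' Log-likelihood that a set of workers are full sisters
#'
#' Exact marginal likelihood of the members' multilocus genotypes under a
#' shared (queen, father) parent pair, integrating the unknown parental
#' alleles against Hardy-Weinberg priors, with the package's mistype error
#' model. Loci are independent and summed; missing locus calls contribute 0.
#' Observed alleles absent from the frequency table are assigned a floor
#' frequency (default `1/(2n+1)` with `n` the workers the frequencies were
#' estimated from).
#'
#' @param member_genotypes Long genotype table for the members (`worker_id`,
#'   `locus`, `allele1`, `allele2`).
#' @param allele_freqs An `allele_freqs` list.
#' @param error An [error_model()].
#' @param floor_freq Frequency assigned to alleles missing from the table.
#' @return A single log-likelihood (can be `-Inf` when members cannot share
#'   a father, e.g. two error-free sisters sharing no allele at a locus).
#' @export
fullsib_loglik <- function(member_genotypes, allele_freqs,
                           error = error_model(),
                           floor_freq = default_floor(allele_freqs)) {
  check_genotypes(member_genotypes)
  check_allele_freqs(allele_freqs)
  ids <- unique(member_genotypes$worker_id)
  loci <- intersect(names(allele_freqs), unique(member_genotypes$locus))
  obs <- geno_obs(member_genotypes, loci, ids)
  sum(vapply(seq_along(loci), function(li)
    locus_cluster_loglik(obs[[li]][, 1], obs[[li]][, 2],
                         allele_freqs[[loci[li]]],
                         error$mistype_rate, floor_freq),
    numeric(1)))
}

#' Log-likelihood that a set of workers are mutually unrelated
#'
#' The null for the full-sib likelihood ratio: the sum over members and loci
#' of the log Hardy-Weinberg genotype probability, under the same error
#' model. Additive over members; equal to [fullsib_loglik()] for a single
#' worker. An empty table gives 0.
#'
#' @inheritParams fullsib_loglik
#' @return A single log-likelihood.
#' @export
unrelated_loglik <- function(member_genotypes, allele_freqs,
                             error = error_model(),
                             floor_freq = default_floor(allele_freqs)) {
  if (is.null(member_genotypes) || !nrow(member_genotypes)) return(0)
  check_allele_freqs(allele_freqs)
  ids <- unique(member_genotypes$worker_id)
  sum(vapply(ids, function(w)
    fullsib_loglik(member_genotypes[member_genotypes$worker_id == w, ,
                                    drop = FALSE],
                   allele_freqs, error, floor_freq), numeric(1)))
}

# --- partition container ----------------------------------------------------

sibship_partition <- function(clusters, support = rep(NA_real_, length(clusters)),
                              total_loglik = NA_real_, restart_logliks = NULL) {
  structure(list(clusters = clusters, support = support,
                 total_loglik = total_loglik,
                 restart_logliks = restart_logliks),
            class = "sibship_partition")
}

#' @export
print.sibship_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat("Sibship partition:", sum(sz), "workers in", sum(sz >= 2),
      "clusters (>= 2 sisters) and", sum(sz == 1), "singletons\n")
  if (is.finite(x$total_loglik))
    cat("Total log-likelihood:", format(x$total_loglik, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.sibship_partition <- function(object, ...) {
  sz <- lengths(object$clusters)
  out <- list(n_workers = sum(sz), n_clusters = sum(sz >= 2),
              n_singletons = sum(sz == 1),
              cluster_sizes = table(sz[sz >= 2]),
              support = object$support[sz >= 2],
              total_loglik = object$total_loglik)
  class(out) <- "summary.sibship_partition"
  out
}

#' @export
print.summary.sibship_partition <- function(x, ...) {
  cat(x$n_workers, "workers;", x$n_clusters, "multi-member clusters;",
      x$n_singletons, "singletons\n")
  if (length(x$cluster_sizes)) {
    cat("Cluster sizes:\n"); print(x$cluster_sizes)
  }
  invisible(x)
}

#' Convert a sibship partition to a worker-level data frame
#'
#' @param x A `sibship_partition`.
#' @param ... Unused.
#' @return Data frame: `worker_id`, `cluster_id`, `cluster_size`,
#'   `cluster_support`.
#' @export
as.data.frame.sibship_partition <- function(x, ...) {
  data.frame(
    worker_id = unlist(x$clusters, use.names = FALSE),
    cluster_id = rep(seq_along(x$clusters), lengths(x$clusters)),
    cluster_size = rep(lengths(x$clusters), lengths(x$clusters)),
    cluster_support = rep(x$support, lengths(x$clusters))
  )
}

# --- reconstruction ---------------------------------------------------------

# cheap pairwise compatibility prefilter: candidate full-sib pairs must share
# at least one allele at all but `allow_mismatch` of their jointly typed
# loci (mistypes can break sharing at the odd locus). Missing calls count as
# shared (uninformative).
compatible_pairs <- function(obs, n_workers, allow_mismatch = 2L) {
  mism <- matrix(0L, n_workers, n_workers)
  for (li in seq_along(obs)) {
    a1 <- obs[[li]][, 1]; a2 <- obs[[li]][, 2]
    sh <- outer(a1, a1, `==`) | outer(a1, a2, `==`) |
      outer(a2, a1, `==`) | outer(a2, a2, `==`)
    sh[is.na(sh)] <- TRUE
    mism <- mism + !sh
  }
  idx <- which(mism <= allow_mismatch & upper.tri(mism), arr.ind = TRUE)
  idx
}

#' Reconstruct full-sib families by maximum likelihood
#'
#' Multi-restart randomized agglomerative search: each restart starts from
#' singletons and repeatedly applies the merge of two clusters with the
#' largest positive gain in total log-likelihood (full-sib likelihood of the
#' merged set minus the sum of its parts), stopping when no candidate merge
#' gains more than `tau`. Candidate merges are limited to clusters connected
#' by a pairwise allele-sharing compatibility edge, a pure speed device (the
#' likelihood itself is exact). The support of a cluster is the fraction of
#' restarts whose final partition contains exactly that member set; the
#' reported partition is the highest-likelihood restart.
#'
#' @param genotypes Long genotype table (`worker_id`, `locus`, `allele1`,
#'   `allele2`) for all workers to partition (>= 2 workers).
#' @param allele_freqs An `allele_freqs` list; defaults to frequencies
#'   estimated from `genotypes` itself.
#' @param error An [error_model()].
#' @param restarts Number of randomized restarts (>= 1; default 3).
#' @param seed Integer seed.
#' @param tau Merge-acceptance threshold on the log-likelihood gain
#'   (default 0: any gain).
#' @param allow_mismatch Loci at which a candidate pair may fail to share an
#'   allele before the pair is ruled out (default 2).
#' @return A `sibship_partition`: `clusters` (list of worker-id vectors,
#'   singletons included), per-cluster `support`, `total_loglik`, and the
#'   per-restart log-likelihoods.
#' @export
reconstruct_sibships <- function(genotypes, allele_freqs = NULL,
                                 error = error_model(), restarts = 3,
                                 seed = 1, tau = 0, allow_mismatch = 2L) {
  check_genotypes(genotypes)
  if (restarts < 1) stop("restarts must be >= 1")
  if (is.null(allele_freqs)) allele_freqs <- estimate_allele_freqs(genotypes)
  check_allele_freqs(allele_freqs)
  floor_freq <- default_floor(allele_freqs)
  e <- error$mistype_rate
  ids <- unique(genotypes$worker_id)
  n <- length(ids)
  if (n < 2) stop("need at least 2 workers to reconstruct sibships")
  loci <- intersect(names(allele_freqs), unique(genotypes$locus))
  obs <- geno_obs(genotypes, loci, ids)
  freqs <- allele_freqs[loci]

  clu_ll <- function(members) {     # members: integer worker indices
    sum(vapply(seq_along(loci), function(li)
      locus_cluster_loglik(obs[[li]][members, 1], obs[[li]][members, 2],
                           freqs[[li]], e, floor_freq), numeric(1)))
  }
  single_ll <- vapply(seq_len(n), function(i) clu_ll(i), numeric(1))
  edges0 <- compatible_pairs(obs, n, allow_mismatch)

  cache <- new.env(parent = emptyenv())
  cached_ll <- function(members) {
    key <- paste(sort(members), collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) { v <- clu_ll(members); cache[[key]] <- v }
    v
  }

  run_restart <- function() {
    members <- as.list(seq_len(n))
    ll <- single_ll
    owner <- seq_len(n)               # worker -> current cluster id
    active <- rep(TRUE, n)
    # cluster-level candidate edges from worker-level compatibility
    E <- unique(cbind(pmin(edges0[, 1], edges0[, 2]),
                      pmax(edges0[, 1], edges0[, 2])))
    if (nrow(E)) E <- E[sample.int(nrow(E)), , drop = FALSE]
    gain <- rep(NA_real_, nrow(E))
    for (r in seq_len(nrow(E)))
      gain[r] <- cached_ll(c(members[[E[r, 1]]], members[[E[r, 2]]])) -
        ll[E[r, 1]] - ll[E[r, 2]]
    repeat {
      if (!length(gain) || all(gain <= tau)) break
      best <- which(gain >= max(gain) - 1e-9)
      pick <- if (length(best) > 1) sample(best, 1) else best
      i <- E[pick, 1]; j <- E[pick, 2]
      new_members <- c(members[[i]], members[[j]])
      new_id <- length(members) + 1L
      members[[new_id]] <- new_members
      ll[new_id] <- ll[i] + ll[j] + gain[pick]
      active[c(i, j)] <- FALSE; active[new_id] <- TRUE
      owner[new_members] <- new_id
      # neighbors of the merged cluster = clusters adjacent to either part
      touch <- E[, 1] %in% c(i, j) | E[, 2] %in% c(i, j)
      nbr <- setdiff(unique(c(E[touch, 1], E[touch, 2])), c(i, j))
      nbr <- nbr[active[nbr]]
      E <- E[!touch, , drop = FALSE]; gain <- gain[!touch]
      if (length(nbr)) {
        add <- cbind(pmin(nbr, new_id), pmax(nbr, new_id))
        g <- vapply(seq_len(nrow(add)), function(r)
          cached_ll(c(members[[add[r, 1]]], members[[add[r, 2]]])) -
            ll[add[r, 1]] - ll[add[r, 2]], numeric(1))
        E <- rbind(E, add); gain <- c(gain, g)
      }
    }
    keep <- which(active)
    list(clusters = lapply(keep, function(i) sort(members[[i]])),
         loglik = sum(ll[keep]))
  }

  res <- with_seed(derive_seed(seed, 71L),
                   lapply(seq_len(restarts), function(r) run_restart()))
  keys <- lapply(res, function(r)
    vapply(r$clusters, paste, character(1), collapse = ","))
  lls <- vapply(res, `[[`, numeric(1), "loglik")
  best <- which.max(lls)
  support <- vapply(keys[[best]], function(k)
    mean(vapply(keys, function(kk) k %in% kk, logical(1))), numeric(1))
  clusters <- lapply(res[[best]]$clusters, function(ix) ids[ix])
  sibship_partition(clusters, unname(support), lls[best], lls)
}

#' Filter sibship clusters by support and size
#'
#' Retains clusters whose restart-consensus support meets `min_support`
#' (inclusive) and whose size meets `min_size`; workers in removed clusters
#' are reported as singletons.
#'
#' @param partition A `sibship_partition`.
#' @param min_support Minimum support probability (default 0.80).
#' @param min_size Minimum cluster size (default 2).
#' @return A `sibship_partition` with retained clusters followed by
#'   singleton entries for released workers.
#' @export
filter_clusters <- function(partition, min_support = 0.80, min_size = 2) {
  stopifnot(inherits(partition, "sibship_partition"))
  sz <- lengths(partition$clusters)
  sup <- partition$support
  keep <- sz >= min_size & (is.na(sup) | sup >= min_support - 1e-9)
  dropped <- unlist(partition$clusters[!keep], use.names = FALSE)
  clusters <- c(partition$clusters[keep], as.list(dropped))
  support <- c(sup[keep], rep(NA_real_, length(dropped)))
  sibship_partition(clusters, support, partition$total_loglik,
                    partition$restart_logliks)
}
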