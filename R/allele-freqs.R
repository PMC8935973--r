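#' Reference microsatellite panel for *Bombus impatiens*
#'
#' The 12 hypervariable loci routinely used to genotype Common Eastern
#' Bumblebee workers, with the published per-locus allele counts, fragment
#' size ranges (bp) and heterozygosities. Used to calibrate the synthetic
#' genotype generator so simulated diversity matches what a real survey
#' observes (12-30 alleles per locus, expected heterozygosity 0.43-0.92).
#'
#' @return Data frame with columns `locus`, `n_alleles`, `size_min`,
#'   `size_max`, `Ho`, `He`.
#' @export
bombus_loci <- function() {
  data.frame(
    locus = c("BT01", "BT23", "BT08", "BT26", "B124", "B126",
              "B96", "BL13", "BL15", "B10", "BT10", "BTERN01"),
    n_alleles = c(18L, 14L, 12L, 19L, 30L, 20L,
                  19L, 15L, 20L, 20L, 27L, 22L),
    size_min = c(143, 158, 156, 93, 226, 136, 228, 144, 117, 171, 135, 98),
    size_max = c(201, 206, 182, 155, 306, 182, 266, 194, 173, 229, 189, 162),
    Ho = c(0.800, 0.427, 0.664, 0.886, 0.890, 0.863,
           0.780, 0.601, 0.862, 0.806, 0.911, 0.802),
    He = c(0.796, 0.428, 0.643, 0.887, 0.915, 0.871,
           0.775, 0.618, 0.853, 0.806, 0.923, 0.799)
  )
}

#' Build per-locus allele frequency tables matching target diversities
#'
#' For each locus, places `n_alleles` allele sizes on a 2-bp ladder inside
#' the locus size range and assigns geometric-decay frequencies
#' `p_i proportional to r^i`, with `r` solved so the gene diversity
#' `1 - sum(p_i^2)` matches the locus's target expected heterozygosity.
#' Deterministic: the same summary always yields the same tables.
#'
#' @param loci Data frame shaped like [bombus_loci()] (columns `locus`,
#'   `n_alleles`, `size_min`, `size_max`, `He`).
#' @return Named list (per locus) of named numeric frequency vectors;
#'   names are allele sizes in bp. Class `allele_freqs`.
#' @export
allele_freqs_from_loci <- function(loci = bombus_loci()) {
  out <- lapply(seq_len(nrow(loci)), function(i) {
    k <- loci$n_alleles[i]
    ladder <- seq(loci$size_min[i], loci$size_max[i], by = 2)
    sizes <- if (length(ladder) >= k)
      ladder[round(seq(1, length(ladder), length.out = k))]
    else seq(loci$size_min[i], by = 2, length.out = k)
    target <- 1 - loci$He[i]            # target sum of squared frequencies
    if (target <= 1 / k + 1e-12) {
      p <- rep(1 / k, k)
    } else {
      f <- function(r) {
        w <- r^(seq_len(k) - 1); p <- w / sum(w); sum(p^2) - target
      }
      r <- stats::uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-12)$root
      w <- r^(seq_len(k) - 1); p <- w / sum(w)
    }
    stats::setNames(p, as.character(sizes))
  })
  names(out) <- loci$locus
  class(out) <- c("allele_freqs", "list")
  out
}

#' Estimate allele frequencies from a genotype table
#'
#' Simple allele-count frequencies per locus, computed over all genotyped
#' workers (missing calls ignored). These are the frequencies fed to the
#' sibship likelihood; estimating them from the full worker sample (sisters
#' included) accepts a slight upward kinship bias, as is common practice.
#'
#' @param genotypes Genotype table: data frame with columns `worker_id`,
#'   `locus`, `allele1`, `allele2` (fragment sizes in bp, `NA` = missing).
#' @return An `allele_freqs` list with an `n` attribute (workers typed per
#'   locus) used to set the floor frequency for unseen alleles.
#' @export
estimate_allele_freqs <- function(genotypes) {
  check_genotypes(genotypes)
  loci <- unique(genotypes$locus)
  out <- lapply(loci, function(l) {
    g <- genotypes[genotypes$locus == l, , drop = FALSE]
    a <- c(g$allele1, g$allele2)
    a <- a[!is.na(a)]
    if (!length(a)) return(NULL)
    tab <- table(a)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(out) <- loci
  keep <- !vapply(out, is.null, logical(1))
  out <- out[keep]
  attr(out, "n") <- vapply(loci[keep], function(l)
    sum(genotypes$locus == l &
          !(is.na(genotypes$allele1) & is.na(genotypes$allele2))), 0L)
  class(out) <- c("allele_freqs", "list")
  out
}

check_allele_freqs <- function(freqs) {
  if (!length(freqs)) stop("empty allele frequency table")
  bad <- vapply(freqs, function(p) abs(sum(p) - 1) > 1e-9, logical(1))
  if (any(bad))
    stop("allele frequencies must sum to 1 at each locus (off at: ",
         paste(names(freqs)[bad], collapse = ", "), ")")
  invisible(TRUE)
}

check_genotypes <- function(genotypes) {
  need <- c("worker_id", "locus", "allele1", "allele2")
  if (!is.data.frame(genotypes) || !all(need %in% names(genotypes)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  if (!nrow(genotypes)) stop("empty genotype table")
  invisible(TRUE)
}
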