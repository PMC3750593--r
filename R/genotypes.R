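#' Minor allele frequency and recoding to the minor allele
#'
#' Computes the frequency of allele 1 for every marker of a dosage matrix
#' (individuals x markers, values 0/1/2/NA) and recodes markers where allele
#' 1 is the major allele (`dosage -> 2 - dosage`) so that, on output, allele
#' 1 is always the minor allele and dosages count minor-allele copies.
#' Missing genotypes are excluded from the allele tally. Recoding is
#' idempotent: a second application changes nothing.
#'
#' @param geno integer matrix, individuals x markers, dosages in
#'   `{0, 1, 2, NA}` with marker ids as column names.
#' @return list with `geno` (recoded matrix), `maf` (named numeric, NA for
#'   all-missing markers), `recoded` (logical, which markers were flipped),
#'   `all_missing` (logical).
#' @export
compute_maf <- function(geno) {
  stopifnot(is.matrix(geno))
  n_called <- colSums(!is.na(geno))
  freq1 <- colSums(geno, na.rm = TRUE) / (2 * n_called)
  freq1[n_called == 0L] <- NA_real_
  recode <- !is.na(freq1) & freq1 > 0.5
  if (any(recode)) geno[, recode] <- 2L - geno[, recode, drop = FALSE]
  maf <- ifelse(recode, 1 - freq1, freq1)
  names(maf) <- colnames(geno)
  list(geno = geno, maf = maf, recoded = recode,
       all_missing = n_called == 0L)
}

#' Pearson correlation of two genotype vectors
#'
#' Correlation of dosage vectors (coded 0/1/2) over the pairwise-complete
#' subset. This is the LD proxy used throughout: genotype correlations are
#' available for unphased data where the haplotype-based r is not. Returns
#' `NA` when fewer than 2 complete pairs remain or either vector is constant
#' on the shared subset; callers treat `NA` as no linkage.
#'
#' @param g1,g2 numeric dosage vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
genotype_correlation <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# all-pairs genotype correlation matrix, pairwise-complete, NA for
# constant/degenerate columns
genotype_cor_matrix <- function(geno) {
  suppressWarnings(stats::cor(geno, use = "pairwise.complete.obs"))
}

#' Marker quality control
#'
#' Filters markers on four criteria: call rate, parent-progeny conflict
#' rate, minor allele frequency, and Hardy-Weinberg equilibrium. A marker is
#' retained iff it passes all four. Defaults: call rate >= 0.95, conflict
#' rate <= 0.02, MAF >= 0.03, HWE chi-square (1 df) p >= 1e-4.
#'
#' A parent-progeny conflict at a marker is a Mendelian impossibility for a
#' single genotyped parent-offspring pair: one homozygous for allele 0 while
#' the other is homozygous for allele 1. The conflict rate is conflicts
#' divided by the number of pairs with both genotypes called at the marker.
#' If the pedigree yields no genotyped parent-offspring pairs the conflict
#' filter is skipped with a warning.
#'
#' @param geno dosage matrix (individuals x markers), rownames = ids.
#' @param ped optional [pedigree()]; `NULL` skips the conflict filter.
#' @param call_rate,conflict_rate,maf_min,hwe_p filter thresholds.
#' @return list with `keep` (logical per marker), `report` (data.frame of
#'   per-criterion removal counts) and per-marker statistics.
#' @export
qc_filter_markers <- function(geno, ped = NULL, call_rate = 0.95,
                              conflict_rate = 0.02, maf_min = 0.03,
                              hwe_p = 1e-4) {
  stopifnot(is.matrix(geno))
  m <- ncol(geno)
  cr <- colMeans(!is.na(geno))
  maf <- compute_maf(geno)$maf
  hwe <- apply(geno, 2, hwe_chisq_p)

  fail_cr <- cr < call_rate
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- !is.na(hwe) & hwe < hwe_p

  fail_conf <- rep(FALSE, m)
  conf_rate <- rep(NA_real_, m)
  if (!is.null(ped)) {
    pairs <- genotyped_parent_pairs(ped, rownames(geno))
    if (nrow(pairs) == 0L) {
      warning("no genotyped parent-offspring pairs; conflict filter skipped")
    } else {
      cc <- conflict_rates(geno, pairs)
      conf_rate <- cc
      fail_conf <- !is.na(cc) & cc > conflict_rate
    }
  }

  keep <- !(fail_cr | fail_maf | fail_hwe | fail_conf)
  report <- data.frame(
    criterion = c("call_rate", "conflict_rate", "maf", "hwe", "any", "retained"),
    n = c(sum(fail_cr), sum(fail_conf), sum(fail_maf), sum(fail_hwe),
          sum(!keep), sum(keep))
  )
  list(keep = keep, report = report,
       stats = data.frame(marker_id = colnames(geno), call_rate = cr,
                          maf = maf, hwe_p = hwe, conflict_rate = conf_rate,
                          row.names = NULL))
}

# chi-square goodness-of-fit test for HWE, 1 df, on genotype counts
hwe_chisq_p <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0L) return(NA_real_)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p1 <- (obs[2] + 2 * obs[3]) / (2 * n)
  exp <- n * c((1 - p1)^2, 2 * p1 * (1 - p1), p1^2)
  if (any(exp == 0 & obs > 0)) return(0)
  nz <- exp > 0
  x2 <- sum((obs[nz] - exp[nz])^2 / exp[nz])
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# (parent, offspring) id pairs where both are genotyped
genotyped_parent_pairs <- function(ped, genotyped_ids) {
  po <- rbind(
    data.frame(parent = ped$sire, offspring = ped$id, stringsAsFactors = FALSE),
    data.frame(parent = ped$dam, offspring = ped$id, stringsAsFactors = FALSE)
  )
  po <- po[!is.na(po$parent) &
           po$parent %in% genotyped_ids &
           po$offspring %in% genotyped_ids, , drop = FALSE]
  po
}

# per-marker conflict rate over genotyped parent-offspring pairs
conflict_rates <- function(geno, pairs) {
  gp <- geno[pairs$parent, , drop = FALSE]
  go <- geno[pairs$offspring, , drop = FALSE]
  called <- !is.na(gp) & !is.na(go)
  conflict <- called & ((gp == 0 & go == 2) | (gp == 2 & go == 0))
  n_pairs <- colSums(called)
  rate <- colSums(conflict) / n_pairs
  rate[n_pairs == 0L] <- NA_real_
  rate
}
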