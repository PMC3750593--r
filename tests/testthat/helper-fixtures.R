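# Shared fixture builders: tiny pedigrees, toy maps, fully informative
# families, and random genotype matrices. All randomness goes through an
# explicit seed at the call site.

# three-generation pedigree: founders GS, GD, F2, F3; sire S = GS x GD;
# dam D = S x F3; offspring X = SX x D (SX a founder sire)
toy_pedigree <- function() {
  pedigree(id   = c("GS", "GD", "F2", "F3", "SX", "S", "D", "X"),
           sire = c(NA,  NA,   NA,   NA,   NA,   "GS", "S", "SX"),
           dam  = c(NA,  NA,   NA,   NA,   NA,   "GD", "F3", "D"))
}

# equally spaced single- or multi-chromosome map
toy_map <- function(n_chrom = 1, per_chrom = 10, length_mb = 90) {
  data.frame(
    marker_id = paste0("m", seq_len(n_chrom * per_chrom)),
    chrom = rep(as.character(seq_len(n_chrom)), each = per_chrom),
    pos_mb = rep(seq(0, length_mb, length.out = per_chrom), n_chrom),
    known = TRUE, stringsAsFactors = FALSE)
}

# random dosage matrix with optional missingness, minor-allele coded
random_geno <- function(n, m, miss = 0, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  g <- sapply(maf, function(p) rbinom(n, 2, p))
  if (miss > 0) g[runif(n * m) < miss] <- NA
  g <- matrix(as.integer(g), n, m,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("m", seq_len(m))))
  g
}

# fully informative family on a toy map: sire heterozygous at every marker
# (pat all 0, mat all 1), offspring inherits the sire's paternal strand and
# the dam's first haplotype, both without crossovers. The dam haplotype is
# 0 at the panel markers (so the offspring is homozygous there) and random
# elsewhere.
informative_family <- function(n_chrom = 2, per_chrom = 30, panel_every = 5,
                               seed = 99) {
  set.seed(seed)
  map <- toy_map(n_chrom, per_chrom)
  m <- nrow(map)
  panel <- map$marker_id[seq(1, m, by = panel_every)]
  dam_h1 <- rbinom(m, 1, 0.5)
  dam_h1[map$marker_id %in% panel] <- 0L
  dam_h2 <- rbinom(m, 1, 0.5)
  mk <- function(v) matrix(as.integer(v), 1, m,
                           dimnames = list(NULL, map$marker_id))
  pat <- rbind(mk(rep(0L, m)), mk(dam_h1))
  mat <- rbind(mk(rep(1L, m)), mk(dam_h2))
  rownames(pat) <- rownames(mat) <- c("SIRE", "DAM")
  lib <- haplotype_library(pat, mat)
  truth <- as.integer(0L + dam_h1)          # offspring dosage, no crossover
  names(truth) <- map$marker_id
  ped <- pedigree(c("SIRE", "DAM", "KID"), c(NA, NA, "SIRE"),
                  c(NA, NA, "DAM"))
  list(map = map, lib = lib, ped = ped, panel = panel, truth = truth)
}

# brute-force conflict profile: for every other marker, count conflicting
# markers strictly between it and the focal marker (by position)
oracle_conflict_counts <- function(h, i, focal, pos) {
  n <- length(h)
  counts <- integer(5)
  for (j in setdiff(seq_len(n), focal)) {
    between <- which(pos > min(pos[focal], pos[j]) &
                     pos < max(pos[focal], pos[j]))
    between <- setdiff(between, c(focal, j))
    k <- sum(!is.na(i[between]) & !is.na(h[between]) &
             h[between] != i[between])
    if (k <= 4) counts[k + 1] <- counts[k + 1] + 1L
  }
  names(counts) <- paste0("c", 0:4)
  counts
}

# brute-force greedy panel step: exhaustive argmax of score x min distance,
# infinite-distance candidates first (by score, then index)
oracle_next_pick <- function(cand, selected, geno, map, maf, cfg) {
  score <- marker_score(cand, maf, map, cfg)
  if (!length(selected)) mind <- rep(Inf, length(cand))
  else mind <- sapply(cand, function(m)
    min(sapply(selected, function(s) marker_distance(m, s, map, geno, cfg))))
  if (any(is.infinite(mind))) {
    inf <- which(is.infinite(mind))
    return(cand[inf[which.max(score[inf])]])
  }
  obj <- score * mind
  cand[which.max(obj)]
}
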