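test_that("origin determination matches exhaustive genotype enumeration", {
  # all 3 offspring dosages x 4 phased sire genotypes
  combos <- expand.grid(d = 0:2, sp = 0:1, sm = 0:1)
  res <- determine_origins(combos$d, combos$sp, combos$sm)
  for (k in seq_len(nrow(combos))) {
    d <- combos$d[k]; sp <- combos$sp[k]; sm <- combos$sm[k]
    if (d == 1 || sp == sm) {
      expected <- -1L
      conflict <- d != 1 && sp == sm && sp != d / 2
    } else {
      expected <- if (sp == d / 2) 0L else 1L
      conflict <- FALSE
    }
    expect_identical(res$which[k], expected,
                     info = sprintf("d=%d sire=(%d,%d)", d, sp, sm))
    expect_identical(res$conflict[k], conflict,
                     info = sprintf("d=%d sire=(%d,%d)", d, sp, sm))
  }
  # missing data is undetermined, never a conflict
  na_res <- determine_origins(c(NA, 0L), c(0L, NA), c(1L, 1L))
  expect_identical(unname(na_res$which), c(-1L, -1L))
  expect_false(any(na_res$conflict))
})

test_that("origin extension: equal flanks, midpoint crossover, spillover", {
  map <- data.frame(marker_id = paste0("m", 1:9), chrom = "1",
                    pos_mb = c(5, 10, 12, 14.9, 15, 17, 20, 25, 40),
                    known = TRUE)
  w <- c(m2 = 0L, m7 = 0L)
  ext <- extend_origins(w, map, map$marker_id)
  expect_true(all(ext == 0L))            # equal flanks + ends
  w2 <- c(m2 = 0L, m7 = 1L)              # crossover centred at 15
  ext2 <- extend_origins(w2, map, map$marker_id)
  expect_identical(unname(ext2[c("m3", "m4")]), c(0L, 0L))   # < midpoint
  expect_identical(unname(ext2[c("m5", "m6")]), c(1L, 1L))   # >= midpoint
  expect_identical(unname(ext2[c("m1", "m8", "m9")]), c(0L, 1L, 1L)) # ends
  # a single determined marker covers its whole chromosome
  ext3 <- extend_origins(c(m5 = 1L), map, map$marker_id)
  expect_true(all(ext3 == 1L))
  # chromosome with no determined marker stays undetermined
  map2 <- rbind(map, data.frame(marker_id = "x1", chrom = "2", pos_mb = 1,
                                known = TRUE))
  ext4 <- extend_origins(w2, map2, map2$marker_id)
  expect_true(is.na(ext4["x1"]))
  # extension never alters a directly determined origin
  expect_identical(ext2[names(w2)], w2)
})

test_that("paternal imputation: copy, splice, conflict-count fallback", {
  map <- toy_map(1, 10)
  sp <- rep(0L, 10); sm <- rep(1L, 10)
  names(sp) <- names(sm) <- map$marker_id
  all0 <- setNames(rep(0L, 10), map$marker_id)
  out <- impute_paternal(all0, sp, sm, map, setNames(rep(NA_integer_, 10),
                                                     map$marker_id))
  expect_identical(unname(out$pat), unname(sp))
  # one crossover after marker 4: hand-constructed splice
  org <- setNames(c(rep(0L, 4), rep(1L, 6)), map$marker_id)
  out2 <- impute_paternal(org, sp, sm, map, all0)
  expect_identical(unname(out2$pat), c(rep(0L, 4), rep(1L, 6)))
  # undetermined chromosome: strand with fewer conflicts wins
  und <- setNames(rep(NA_integer_, 10), map$marker_id)
  obs <- setNames(rep(2L, 10), map$marker_id)   # offspring all hom-1
  out3 <- impute_paternal(und, sp, sm, map, obs)
  expect_identical(unname(out3$pat), unname(sm))  # sm conflicts 0 < sp 10
  expect_true(all(out3$provenance == "fallback"))
  # tie goes to the paternal strand
  out4 <- impute_paternal(und, sp, sm, map, und)
  expect_identical(unname(out4$pat), unname(sp))
})

test_that("partial maternal derivation and conflicts", {
  d <- c(2L, 1L, 0L, 1L, NA)
  p <- c(1L, 0L, 1L, 1L, 1L)
  res <- derive_partial_maternal(d, p)
  expect_identical(res$mat, c(1L, 1L, NA, 0L, NA))
  expect_identical(res$conflict, c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("conflict profiles match the brute-force interval oracle", {
  # all-match haplotype: c(0) = number of other markers
  n <- 12L
  pos <- sort(runif(n, 0, 50))
  i <- rep(1L, n)
  cc <- conflict_counts(rep(1L, n), i, 5, pos)
  expect_identical(unname(cc), c(n - 1L, 0L, 0L, 0L, 0L))
  # planted conflicts on a 23-marker chromosome
  set.seed(91)
  pos23 <- sort(runif(23, 0, 80))
  i23 <- rbinom(23, 1, 0.5)
  h23 <- i23; h23[c(3, 9, 15, 21)] <- 1L - h23[c(3, 9, 15, 21)]
  i23[c(5, 18)] <- NA                      # missing never conflicts
  for (focal in c(1, 7, 12, 23)) {
    expect_identical(conflict_counts(h23, i23, focal, pos23),
                     oracle_conflict_counts(h23, i23, focal, pos23),
                     info = paste("focal", focal))
  }
  # a conflict adjacent to the focal shifts everything beyond it by one
  h1 <- rep(0L, 10); i1 <- rep(0L, 10); i1_pos <- 1:10
  h1[6] <- 1L
  cc2 <- conflict_counts(h1, i1, 5, i1_pos)
  expect_identical(unname(cc2), c(5L, 4L, 0L, 0L, 0L))
  # random instances against the oracle
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:20, 1)
    pos <- sort(runif(n, 0, 100))
    h <- rbinom(n, 1, 0.5)
    i <- ifelse(runif(n) < 0.2, NA, rbinom(n, 1, 0.5))
    focal <- sample(n, 1)
    expect_identical(conflict_counts(h, i, focal, pos),
                     oracle_conflict_counts(h, i, focal, pos),
                     info = paste("seed", seed))
  }
})

test_that("haplotype score formula and relationship weighting", {
  counts <- c(6, 5, 5, 3, 3)   # worked conflict profile
  expected <- (6 + 5 * 0.75 + 5 * 0.75^2 + 3 * 0.75^3 + 3 * 0.75^4)
  expect_equal(score_haplotype(counts, 0.5), expected * 1.5)
  expect_equal(score_haplotype(counts, 0.5) / score_haplotype(counts, 0),
               1.5)
  expect_equal(score_haplotype(c(1, 0, 0, 0, 0), 0), 1)
})

test_that("the dam's haplotype beats an unrelated identical profile", {
  map <- toy_map(1, 20)
  m <- nrow(map)
  set.seed(95)
  dam_h <- rbinom(m, 1, 0.5)
  mk <- function(v) matrix(as.integer(v), 1, m,
                           dimnames = list(NULL, map$marker_id))
  # two library individuals carrying identical paternal haplotypes
  pat <- rbind(mk(dam_h), mk(dam_h))
  mat <- rbind(mk(rbinom(m, 1, 0.5)), mk(rbinom(m, 1, 0.5)))
  rownames(pat) <- rownames(mat) <- c("DAM", "STRANGER")
  lib <- haplotype_library(pat, mat)
  partial <- setNames(as.integer(dam_h[seq(1, m, 4)]),
                      map$marker_id[seq(1, m, 4)])
  res <- impute_maternal(partial, lib, map,
                         rel = c(DAM = 0.5, STRANGER = 0))
  expect_identical(unname(res$mat), as.integer(dam_h))
  # conflict-free winner spans the whole chromosome in one pass
  expect_true(all(res$provenance %in% c("observed", "library")))
})

test_that("maternal scoring agrees with conflict_counts + score_haplotype", {
  # the vectorised scorer inside impute_maternal must equal the per-
  # haplotype primitives: reconstruct the pick at the first focal marker
  set.seed(97)
  map <- toy_map(1, 15)
  m <- nrow(map)
  n_lib <- 4
  pat <- matrix(rbinom(n_lib * m, 1, 0.5), n_lib, m,
                dimnames = list(paste0("L", 1:n_lib), map$marker_id))
  mat <- matrix(rbinom(n_lib * m, 1, 0.5), n_lib, m,
                dimnames = list(paste0("L", 1:n_lib), map$marker_id))
  storage.mode(pat) <- storage.mode(mat) <- "integer"
  lib <- haplotype_library(pat, mat)
  panel_idx <- seq(1, m, 2)
  partial <- setNames(rbinom(length(panel_idx), 1, 0.5),
                      map$marker_id[panel_idx])
  storage.mode(partial) <- "integer"
  rel <- setNames(runif(n_lib, 0, 0.5), rownames(pat))
  res <- impute_maternal(partial, lib, map, rel = rel)
  # manual argmax at the first panel marker over all 8 haplotypes
  ids <- sort(rownames(pat))
  scores <- unlist(lapply(ids, function(id) {
    vapply(c("pat", "mat"), function(s) {
      h <- lib[[s]][id, panel_idx]
      score_haplotype(conflict_counts(h, partial, 1,
                                      map$pos_mb[panel_idx]), rel[id])
    }, numeric(1))
  }))
  hapmat <- rbind(pat[ids, ], mat[ids, ])[rep(seq_along(ids),
                                              each = 2) +
                                          c(0, length(ids)), ]
  winner <- which.max(scores)
  # the first imputed (non-observed) marker allele comes from that winner
  first_lib <- which(res$provenance == "library")[1]
  expect_equal(unname(res$mat[first_lib]), unname(hapmat[winner, first_lib]))
})

test_that("fully informative family is recovered exactly end-to-end", {
  fam <- informative_family()
  obs <- fam$truth[fam$panel]
  res <- impute_individual(obs, "SIRE", fam$lib, fam$map, fam$ped,
                           dam_id = "DAM")
  expect_identical(unname(res$dosage), unname(fam$truth))
  expect_length(res$mendelian_conflicts, 0)
  expect_length(res$derivation_conflicts, 0)
})

test_that("offspring genotyped at all markers are reproduced verbatim", {
  cfg <- sim_config(n_chrom = 1, markers_per_chrom = 80, n_founders = 40,
                    burnin_generations = 5, n_sires = 3, seed = 77)
  sim <- simulate_population(cfg)
  lib <- haplotype_library(sim$lib$pat[sim$roles$sires, , drop = FALSE],
                           sim$lib$mat[sim$roles$sires, , drop = FALSE])
  kid <- sim$roles$offspring[1]
  full <- sim$geno[kid, ]
  res <- impute_individual(full, sim$ped$sire[sim$ped$id == kid], lib,
                           sim$map, sim$ped,
                           dam_id = sim$ped$dam[sim$ped$id == kid])
  expect_identical(unname(res$dosage), unname(full))
})

test_that("imputation is deterministic and Mendel-consistent at panel markers", {
  cfg <- sim_config(n_chrom = 2, markers_per_chrom = 100, n_founders = 60,
                    burnin_generations = 8, n_sires = 5, seed = 31)
  sim <- simulate_population(cfg)
  lib <- haplotype_library(sim$lib$pat[sim$roles$sires, , drop = FALSE],
                           sim$lib$mat[sim$roles$sires, , drop = FALSE])
  mf <- compute_maf(sim$geno[sim$roles$sires, ])
  pan <- select_panel(colnames(sim$geno), sim$geno[sim$roles$sires, ],
                      sim$map, 30, mf$maf, panel_config())
  truth <- sim$geno[sim$roles$offspring, ]
  mk <- mask_panel(truth, pan$marker_id)
  imp1 <- impute_offspring_set(mk$geno[, pan$marker_id], sim$ped, lib,
                               sim$map)
  imp2 <- impute_offspring_set(mk$geno[, pan$marker_id], sim$ped, lib,
                               sim$map)
  expect_identical(imp1$dosage, imp2$dosage)
  # paternal + maternal reproduces the observed genotype at every
  # non-conflicted panel marker
  for (kid in sim$roles$offspring[1:5]) {
    r <- imp1$results[[kid]]
    ok <- setdiff(pan$marker_id,
                  c(r$mendelian_conflicts, r$derivation_conflicts))
    expect_identical(r$dosage[ok], truth[kid, ok])
  }
})

test_that("errors name the missing sire and an empty library is rejected", {
  fam <- informative_family()
  expect_error(impute_individual(fam$truth[fam$panel], "GHOST", fam$lib,
                                 fam$map, fam$ped, dam_id = "DAM"),
               "GHOST")
  empty <- haplotype_library(
    matrix(integer(0), 0, nrow(fam$map),
           dimnames = list(character(0), fam$map$marker_id)),
    matrix(integer(0), 0, nrow(fam$map),
           dimnames = list(character(0), fam$map$marker_id)))
  expect_error(impute_maternal(fam$truth[fam$panel], empty, fam$map),
               "empty")
})
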