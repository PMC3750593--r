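# builds a dosage matrix whose marker correlations are controlled by
# copying (and partially resampling) a base column
correlated_col <- function(base, flip_frac, seed) {
  set.seed(seed)
  idx <- sample(length(base), round(flip_frac * length(base)))
  out <- base
  out[idx] <- rbinom(length(idx), 2, 0.5)
  out
}

test_that("markers linked above the threshold share a class", {
  set.seed(10)
  a <- rbinom(400, 2, 0.5)
  b <- correlated_col(a, 0.3, 11)     # high correlation with a
  c_ <- rbinom(400, 2, 0.5)           # independent
  g <- cbind(a = a, b = b, c = c_)
  storage.mode(g) <- "integer"
  mf <- compute_maf(g)
  stopifnot(abs(genotype_correlation(mf$geno[, "a"], mf$geno[, "b"])) > 0.4,
            abs(genotype_correlation(mf$geno[, "a"], mf$geno[, "c"])) < 0.4)
  cls <- build_marker_classes(mf$geno, mf$maf)
  expect_equal(cls[["a"]], cls[["b"]])
  expect_false(cls[["a"]] == cls[["c"]])
})

test_that("low-MAF interior markers cannot relay a chain", {
  # a -- b -- c with b rare: a and c must end up in different classes and
  # b attaches to its strongest neighbour
  set.seed(12)
  n <- 600
  b <- rbinom(n, 2, 0.07)                      # MAF ~ 0.06 < 0.15
  # a and c tag b on disjoint halves of its carriers, so each correlates
  # with b above the threshold but not with the other
  carriers <- which(b > 0)
  half <- seq_along(carriers) %% 2 == 0
  a <- ifelse(seq_len(n) %in% carriers[half], 2L, rbinom(n, 2, 0.15))
  c_ <- ifelse(seq_len(n) %in% carriers[!half], 2L, rbinom(n, 2, 0.15))
  g <- cbind(a = a, b = b, c = c_)
  storage.mode(g) <- "integer"
  mf <- compute_maf(g)
  r_ab <- abs(genotype_correlation(mf$geno[, "a"], mf$geno[, "b"]))
  r_bc <- abs(genotype_correlation(mf$geno[, "b"], mf$geno[, "c"]))
  r_ac <- abs(genotype_correlation(mf$geno[, "a"], mf$geno[, "c"]))
  stopifnot(r_ab > 0.4, r_bc > 0.4, r_ac < 0.4,
            mf$maf[["b"]] < 0.15, mf$maf[["a"]] > 0.15)
  cls <- build_marker_classes(mf$geno, mf$maf)
  expect_false(cls[["a"]] == cls[["c"]])
  expect_true(cls[["b"]] %in% c(cls[["a"]], cls[["c"]]))
})

test_that("classes match a transitive-closure oracle on random matrices", {
  for (seed in 1:5) {
    g <- random_geno(150, 30, seed = seed)
    mf <- compute_maf(g)
    cls <- build_marker_classes(mf$geno, mf$maf)
    cm <- suppressWarnings(cor(mf$geno, use = "pairwise.complete.obs"))
    adj <- !is.na(cm) & abs(cm) > 0.4
    diag(adj) <- FALSE
    high <- !is.na(mf$maf) & mf$maf > 0.15
    # oracle components over high-MAF markers: repeated boolean closure
    reach <- adj & outer(high, high, "&")
    diag(reach) <- TRUE
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    co_class <- outer(cls, cls, "==")
    expect_identical(unname(co_class[high, high]),
                     unname(reach[high, high]),
                     info = paste("seed", seed))
    # low-MAF markers sit with their strongest admissible neighbour
    for (i in which(!high)) {
      nb <- which(adj[i, ])
      if (!length(nb)) next
      best <- nb[which.max(abs(cm[i, nb]))]
      expect_equal(cls[[i]], cls[[best]],
                   info = sprintf("seed %d low-MAF marker %d", seed, i))
    }
  }
})

test_that("class construction is invariant to marker order", {
  g <- random_geno(100, 20, seed = 42)
  mf <- compute_maf(g)
  cls <- build_marker_classes(mf$geno, mf$maf)
  perm <- sample(ncol(g))
  cls_p <- build_marker_classes(mf$geno[, perm], mf$maf[perm])
  # same partition: co-membership must agree for all pairs
  for (i in colnames(g)) for (j in colnames(g))
    expect_equal(cls[[i]] == cls[[j]], cls_p[[i]] == cls_p[[j]])
})

test_that("chromosome assignment uses a strict 95% majority", {
  mk_cls <- function(n) setNames(rep(1L, n), paste0("m", seq_len(n)))
  mk_map <- function(chroms) data.frame(
    marker_id = paste0("m", seq_along(chroms)), chrom = chroms,
    pos_mb = seq_along(chroms), known = TRUE, stringsAsFactors = FALSE)
  # 20 of 20 on chr 1 -> assigned
  expect_equal(unname(assign_class_chromosomes(mk_cls(20),
                                               mk_map(rep("1", 20)))), "1")
  # 18 of 20 (90%) -> unassigned
  expect_true(is.na(assign_class_chromosomes(
    mk_cls(20), mk_map(c(rep("1", 18), "2", "2")))))
  # 96 of 100 -> assigned (96% > 95%)
  expect_equal(unname(assign_class_chromosomes(
    mk_cls(100), mk_map(c(rep("3", 96), rep("2", 4))))), "3")
  # exactly 95% is not strictly more -> unassigned
  expect_true(is.na(assign_class_chromosomes(
    mk_cls(100), mk_map(c(rep("3", 95), rep("2", 5))))))
  # class without known members -> unassigned
  mp <- mk_map(rep("1", 3)); mp$known <- FALSE
  expect_true(is.na(assign_class_chromosomes(mk_cls(3), mp)))
})

test_that("positions come from the best-correlated known partner", {
  set.seed(31)
  n <- 300
  base <- rbinom(n, 2, 0.5)
  g <- cbind(u = base,                       # unknown position
             k1 = correlated_col(base, 0.2, 1),
             k2 = correlated_col(base, 0.6, 2),
             k3 = rbinom(n, 2, 0.5))
  storage.mode(g) <- "integer"
  map <- data.frame(marker_id = c("u", "k1", "k2", "k3"),
                    chrom = c(NA, "1", "1", "1"),
                    pos_mb = c(NA, 12.3, 40, 77), known = c(FALSE, TRUE,
                                                            TRUE, TRUE))
  mf <- compute_maf(g)
  res <- approximate_marker_positions(mf$geno, map, mf$maf)
  cm <- suppressWarnings(cor(mf$geno, use = "pairwise.complete.obs"))
  best <- c("k1", "k2", "k3")[which.max(abs(cm["u", c("k1", "k2", "k3")]))]
  expect_equal(best, "k1")                    # strongest partner by design
  got <- res$map[res$map$marker_id == "u", ]
  expect_equal(got$chrom, "1")
  expect_equal(got$pos_mb, 12.3)              # partner's known position
  expect_false(got$known)                     # u = 0.8 downstream
  expect_equal(res$report$partner, "k1")
})

test_that("singleton unknown markers stay unplaced", {
  g <- random_geno(100, 3, seed = 77)
  map <- toy_map(1, 3)
  map$chrom[2] <- NA; map$pos_mb[2] <- NA; map$known[2] <- FALSE
  mf <- compute_maf(g)
  cls <- build_marker_classes(mf$geno, mf$maf)
  stopifnot(cls[[1]] != cls[[2]], cls[[2]] != cls[[3]])
  res <- approximate_marker_positions(mf$geno, map, mf$maf)
  expect_true("m2" %in% res$unplaced)
  expect_true(is.na(res$map$pos_mb[2]))
})

test_that("no marker is placed on a chromosome other than its class's", {
  cfg <- sim_config(n_chrom = 2, markers_per_chrom = 60, n_founders = 60,
                    burnin_generations = 12, n_sires = 5, seed = 404)
  sim <- simulate_population(cfg)
  map <- sim$map
  set.seed(405)
  masked <- sample(nrow(map), 12)
  map$chrom[masked] <- NA; map$pos_mb[masked] <- NA; map$known[masked] <- FALSE
  mf <- compute_maf(sim$geno)
  res <- approximate_marker_positions(mf$geno, map, mf$maf)
  placed <- !is.na(res$map$chrom)
  cls_chrom <- res$class_chrom[as.character(res$classes)]
  idx <- which(placed & !is.na(cls_chrom))
  expect_true(all(res$map$chrom[idx] == cls_chrom[idx]))
})
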