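# Gene-dropping simulator producing pedigree-structured populations with
# the family design the imputation method assumes: high-density genotyped
# sires, low-density genotyped selection candidates, ungenotyped dams.

#' Simulation configuration
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome (equally spaced).
#' @param chrom_length_mb chromosome length in Mb.
#' @param cm_per_mb recombination rate (constant 1 cM/Mb by default).
#' @param maf_range founder minor-allele-frequency range, drawn uniformly
#'   per marker.
#' @param n_founders individuals per burn-in generation (half male, half
#'   female).
#' @param burnin_generations generations of random mating before the study
#'   families; builds up the linkage disequilibrium that library-based
#'   imputation and LD-based position approximation exploit.
#' @param n_sires,dams_per_sire,offspring_per_dam study family design:
#'   sires drawn from the last burn-in generation, each mated to
#'   `dams_per_sire` distinct dams producing `offspring_per_dam` offspring
#'   each.
#' @param n_traits,n_qtl trait simulation: traits each controlled by
#'   `n_qtl` random markers with standard-normal effects.
#' @param r_val,r_train target EBV accuracies (square roots of
#'   reliabilities) for validation offspring and training sires; scalars or
#'   length-`n_traits` vectors.
#' @param family_error if `TRUE`, sire and offspring EBV share a family
#'   error component, inducing the correlated prediction errors that arise
#'   when training and validation animals are evaluated together.
#' @param family_error_share fraction of EBV error variance shared within a
#'   sire family when `family_error` is on.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2, markers_per_chrom = 200,
                       chrom_length_mb = 100, cm_per_mb = 1,
                       maf_range = c(0.1, 0.5), n_founders = 100,
                       burnin_generations = 20, n_sires = 10,
                       dams_per_sire = 2, offspring_per_dam = 2,
                       n_traits = 1, n_qtl = 50, r_val = 0.7,
                       r_train = 0.85, family_error = FALSE,
                       family_error_share = 0.5, seed = NULL) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 2, chrom_length_mb > 0,
            n_founders >= 4, n_sires >= 1,
            all(r_val > 0 & r_val <= 1), all(r_train > 0 & r_train <= 1))
  structure(as.list(environment()), class = "sim_config")
}

# map with equally spaced markers; ids chr<k>_m<j>
sim_marker_map <- function(cfg) {
  per <- cfg$markers_per_chrom
  pos <- seq(0, cfg$chrom_length_mb, length.out = per)
  data.frame(
    marker_id = as.vector(vapply(seq_len(cfg$n_chrom), function(k)
      sprintf("chr%d_m%03d", k, seq_len(per)), character(per))),
    chrom = rep(as.character(seq_len(cfg$n_chrom)), each = per),
    pos_mb = rep(pos, cfg$n_chrom),
    known = TRUE, stringsAsFactors = FALSE)
}

#' Simulate founder haplotypes
#'
#' Founder alleles are drawn independently per marker at frequencies
#' uniform on `maf_range` (linkage equilibrium); LD is generated afterwards
#' by the burn-in generations of [simulate_population()].
#'
#' @param cfg a [sim_config()].
#' @return list: `lib` (founder [haplotype_library()]), `map`, `freq`
#'   (allele-1 frequencies used).
#' @export
simulate_founders <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- sim_marker_map(cfg)
  m <- nrow(map)
  freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  names(freq) <- map$marker_id
  ids <- sprintf("F%04d", seq_len(cfg$n_founders))
  draw <- function() {
    h <- matrix(stats::rbinom(cfg$n_founders * m, 1L,
                              rep(freq, each = cfg$n_founders)),
                cfg$n_founders, m, dimnames = list(ids, map$marker_id))
    storage.mode(h) <- "integer"
    h
  }
  list(lib = haplotype_library(draw(), draw()), map = map, freq = freq)
}

#' Drop one gamete from a phased parent
#'
#' Recombination follows the Haldane model: the number of crossovers per
#' chromosome is Poisson with mean equal to the chromosome's genetic length
#' in Morgans, crossover positions are uniform, there is no interference,
#' and the starting strand is random. The gamete alternates between the
#' parental haplotypes at the crossover points.
#'
#' @param pat,mat parental allele vectors over the map's markers.
#' @param map marker map.
#' @param cm_per_mb constant genetic map density.
#' @return integer allele vector (the gamete).
#' @export
drop_gamete <- function(pat, mat, map, cm_per_mb = 1) {
  gam <- integer(length(pat))
  names(gam) <- map$marker_id
  for (chr in unique(map$chrom)) {
    sel <- which(map$chrom == chr)
    pos <- map$pos_mb[sel]
    len_morgan <- (max(pos) - min(pos)) * cm_per_mb / 100
    n_x <- stats::rpois(1, len_morgan)
    xpos <- sort(stats::runif(n_x, min(pos), max(pos)))
    strand <- (sample(0:1, 1) + findInterval(pos, xpos)) %% 2
    gam[sel] <- ifelse(strand == 0, pat[sel], mat[sel])
  }
  gam
}

# gamete for one chromosome given precomputed positions (hot loop)
drop_gamete_chr <- function(pat, mat, pos, len_morgan) {
  n_x <- stats::rpois(1, len_morgan)
  if (n_x == 0L) {
    if (sample(0:1, 1) == 0L) return(pat) else return(mat)
  }
  xpos <- sort(stats::runif(n_x, pos[1], pos[length(pos)]))
  strand <- (sample(0:1, 1) + findInterval(pos, xpos)) %% 2
  ifelse(strand == 0, pat, mat)
}

#' Simulate a pedigree-structured study population
#'
#' Starts from linkage-equilibrium founders, runs `burnin_generations` of
#' random mating at constant size to build LD and co-ancestry, then mates
#' `n_sires` males from the last burn-in generation to distinct dams to
#' produce the selection candidates. Truth haplotypes are retained for the
#' last two burn-in generations (which contain the sires, dams and maternal
#' grandsires) and the offspring, so imputation output can be scored
#' against the truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `map`, `ped` (full pedigree back to the founders),
#'   `lib` (truth [haplotype_library()] of all retained individuals),
#'   `geno` (their dosage matrix) and `roles`: ids of `sires`, `dams`,
#'   `offspring`, `grandsires` (the dams' sires).
#' @export
simulate_population <- function(cfg) {
  fo <- simulate_founders(cfg)  # seeds the RNG from cfg$seed
  map <- fo$map
  chrs <- unique(map$chrom)
  chr_sel <- lapply(chrs, function(c) which(map$chrom == c))
  chr_pos <- lapply(chr_sel, function(s) map$pos_mb[s])
  chr_len <- vapply(chr_pos, function(p)
    (max(p) - min(p)) * cfg$cm_per_mb / 100, numeric(1))

  make_gamete <- function(pat, mat) {
    g <- integer(length(pat))
    for (k in seq_along(chrs)) {
      s <- chr_sel[[k]]
      g[s] <- drop_gamete_chr(pat[s], mat[s], chr_pos[[k]], chr_len[k])
    }
    g
  }
  breed <- function(par_pat, par_mat, sire_row, dam_row, ids) {
    n <- length(ids)
    pat <- matrix(0L, n, nrow(map), dimnames = list(ids, map$marker_id))
    mat <- pat
    for (i in seq_len(n)) {
      pat[i, ] <- make_gamete(par_pat[sire_row[i], ], par_mat[sire_row[i], ])
      mat[i, ] <- make_gamete(par_pat[dam_row[i], ], par_mat[dam_row[i], ])
    }
    list(pat = pat, mat = mat)
  }

  N <- cfg$n_founders
  males <- seq_len(floor(N / 2)); females <- setdiff(seq_len(N), males)
  cur <- list(pat = fo$lib$pat, mat = fo$lib$mat)
  cur_ids <- rownames(cur$pat)
  ped_id <- cur_ids
  ped_sire <- rep(NA_character_, N); ped_dam <- rep(NA_character_, N)
  prev <- NULL
  for (g in seq_len(cfg$burnin_generations)) {
    ids <- sprintf("G%02d_%04d", g, seq_len(N))
    sire_row <- sample(males, N, replace = TRUE)
    dam_row <- sample(females, N, replace = TRUE)
    nxt <- breed(cur$pat, cur$mat, sire_row, dam_row, ids)
    ped_id <- c(ped_id, ids)
    ped_sire <- c(ped_sire, cur_ids[sire_row])
    ped_dam <- c(ped_dam, cur_ids[dam_row])
    prev <- cur; prev_ids <- cur_ids
    cur <- nxt; cur_ids <- ids
  }

  # study families: sires are males, dams distinct females of the last
  # burn-in generation
  n_dams <- cfg$n_sires * cfg$dams_per_sire
  if (cfg$n_sires > length(males) || n_dams > length(females))
    stop("n_founders too small for the requested family design")
  sire_ids <- cur_ids[sample(males, cfg$n_sires)]
  dam_ids <- cur_ids[sample(females, n_dams)]
  fam_sire <- rep(sire_ids, each = cfg$dams_per_sire)

  off_sire <- rep(fam_sire, each = cfg$offspring_per_dam)
  off_dam <- rep(dam_ids, each = cfg$offspring_per_dam)
  off_ids <- sprintf("V%04d", seq_along(off_sire))
  offh <- breed(cur$pat, cur$mat,
                match(off_sire, cur_ids), match(off_dam, cur_ids), off_ids)

  ped <- pedigree(c(ped_id, off_ids), c(ped_sire, off_sire),
                  c(ped_dam, off_dam))

  keep_pat <- rbind(prev$pat, cur$pat, offh$pat)
  keep_mat <- rbind(prev$mat, cur$mat, offh$mat)
  lib <- haplotype_library(keep_pat, keep_mat)

  dam_sires <- ped$sire[match(dam_ids, ped$id)]
  list(map = map, ped = ped, lib = lib, geno = haplib_dosage(lib),
       roles = list(sires = sire_ids, dams = dam_ids, offspring = off_ids,
                    grandsires = unique(dam_sires)))
}

#' Simulate true breeding values and EBV with controllable accuracy
#'
#' Each trait is controlled by `n_qtl` markers drawn at random with
#' standard-normal allele substitution effects; TBV are centred and scaled
#' to unit variance. EBV are a shrinkage construction,
#' `EBV = r^2 TBV + r sqrt(1 - r^2) e`, so that `cor(EBV, TBV) = r` in
#' expectation, with r the target accuracy of the individual's set
#' (validation or training). With `family_error` on, the error `e` of a
#' sire and of his offspring share a common family component, emulating the
#' correlated prediction errors of a joint genetic evaluation.
#'
#' @param sim output of [simulate_population()].
#' @param cfg the [sim_config()] used.
#' @param seed optional seed for the trait layer only.
#' @return list: `tbv` (individuals x traits matrix), `records`
#'   (data.frame: `id`, `trait`, `ebv`, `reliability`), `qtl` (list of
#'   per-trait QTL ids).
#' @export
simulate_traits_and_ebv <- function(sim, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r_val <- rep_len(cfg$r_val, cfg$n_traits)
  r_train <- rep_len(cfg$r_train, cfg$n_traits)
  ids <- rownames(sim$geno)
  val <- sim$roles$offspring
  sires <- sim$roles$sires
  tbv <- matrix(0, length(ids), cfg$n_traits,
                dimnames = list(ids, paste0("trait", seq_len(cfg$n_traits))))
  qtl <- vector("list", cfg$n_traits)
  records <- vector("list", cfg$n_traits)
  sire_of <- sim$ped$sire[match(ids, sim$ped$id)]
  for (t in seq_len(cfg$n_traits)) {
    q <- sample(colnames(sim$geno), cfg$n_qtl)
    eff <- stats::rnorm(cfg$n_qtl)
    g <- sim$geno[, q, drop = FALSE] %*% eff
    g <- (g - mean(g)) / stats::sd(g)
    tbv[, t] <- g
    qtl[[t]] <- q

    r <- ifelse(ids %in% val, r_val[t], r_train[t])
    if (cfg$family_error) {
      fam <- stats::rnorm(length(sires))
      names(fam) <- sires
      share <- cfg$family_error_share
      own <- stats::rnorm(length(ids))
      fam_of <- ifelse(ids %in% sires, ids, sire_of)
      f <- fam[fam_of]
      f[is.na(f)] <- 0
      e <- sqrt(share) * f + sqrt(1 - share) * own
    } else {
      e <- stats::rnorm(length(ids))
    }
    ebv <- r^2 * tbv[, t] + r * sqrt(1 - r^2) * e
    records[[t]] <- data.frame(id = ids, trait = paste0("trait", t),
                               ebv = ebv, reliability = r^2,
                               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(tbv = tbv, records = do.call(rbind, records), qtl = qtl)
}
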