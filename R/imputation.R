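# Pedigree-aware imputation from low- to high-density genotypes.
#
# The method assumes every selection candidate has a high-density genotyped,
# phased sire and an ungenotyped dam. Paternal alleles are recovered by
# tracing which sire haplotype was transmitted (certain wherever the
# offspring is homozygous and the sire heterozygous), placing crossovers at
# interval midpoints. Maternal alleles are derived at the panel markers by
# subtraction and completed from a haplotype library in which haplotypes of
# closer relatives of the dam are favoured.

#' Determine the sire-haplotype origin of an offspring's paternal alleles
#'
#' At a panel marker the origin is certain iff the offspring is homozygous
#' (dosage 0 or 2) and the sire is heterozygous: the transmitted sire
#' haplotype is the one carrying the offspring's allele. All other
#' configurations are undetermined. An offspring homozygous for an allele
#' the sire does not carry is a Mendelian conflict; the marker is treated as
#' uninformative and counted.
#'
#' @param offspring dosage vector at the panel markers (0/1/2/NA).
#' @param sire_pat,sire_mat sire allele vectors (0/1/NA) at the same markers.
#' @return list: `which` (integer vector: 0 = sire's paternal haplotype,
#'   1 = sire's maternal haplotype, -1 = undetermined), `conflict` (logical,
#'   Mendelian impossibilities).
#' @export
determine_origins <- function(offspring, sire_pat, sire_mat) {
  n <- length(offspring)
  stopifnot(length(sire_pat) == n, length(sire_mat) == n)
  which_ <- rep(-1L, n)
  conflict <- rep(FALSE, n)
  ok <- !is.na(offspring) & !is.na(sire_pat) & !is.na(sire_mat)
  hom <- ok & offspring %in% c(0L, 2L)
  het <- sire_pat != sire_mat
  allele <- offspring / 2L                        # 0 or 1 where hom
  det <- hom & het
  which_[det & sire_pat == allele] <- 0L
  which_[det & sire_mat == allele] <- 1L
  conflict[hom & !het & sire_pat != allele] <- TRUE
  names(which_) <- names(conflict) <- names(offspring)
  list(which = which_, conflict = conflict)
}

#' Extend origins from panel markers to all high-density markers
#'
#' Between two determined panel markers of equal origin every interior
#' marker takes that origin. Between markers of different origin a single
#' crossover is assumed at the centre of the interval: markers left of the
#' midpoint take the left origin, markers at or right of it the right
#' origin. Beyond the outermost determined markers the nearest determined
#' origin extends to the chromosome end. Equivalently, each high-density
#' marker adopts the origin of its nearest determined panel marker, ties
#' resolved to the right. Chromosomes without any determined marker stay
#' undetermined (`NA`).
#'
#' @param which integer origins per panel marker (0/1/-1), named by marker.
#' @param map marker map covering the panel and high-density markers.
#' @param hd_markers ids of the high-density markers to fill.
#' @return integer vector (0/1/NA) named by `hd_markers`.
#' @export
extend_origins <- function(which, map, hd_markers) {
  out <- rep(NA_integer_, length(hd_markers))
  names(out) <- hd_markers
  pidx <- match(names(which), map$marker_id)
  hidx <- match(hd_markers, map$marker_id)
  det <- which >= 0
  for (chr in unique(map$chrom[hidx])) {
    if (is.na(chr)) next
    h <- which(map$chrom[hidx] == chr)
    d <- which(det & map$chrom[pidx] == chr)
    if (!length(d)) next
    dpos <- map$pos_mb[pidx[d]]
    o <- order(dpos)
    dpos <- dpos[o]; dorig <- which[d][o]
    hpos <- map$pos_mb[hidx[h]]
    k <- findInterval(hpos, dpos)     # index of nearest determined <= pos
    left <- pmax(k, 1L)
    right <- pmin(k + 1L, length(dpos))
    dl <- hpos - dpos[left]
    dr <- dpos[right] - hpos
    use_right <- k == 0L | (k < length(dpos) & dl >= dr)
    pick <- ifelse(use_right, right, left)
    out[h] <- as.integer(dorig[pick])
  }
  out
}

#' Impute the paternal allele vector from extended origins
#'
#' Copies the allele of the indicated sire haplotype at every marker with a
#' determined origin. On chromosomes where no origin could be determined the
#' whole sire haplotype with fewer conflicts against the offspring's
#' observed genotypes is used (tie: paternal), flagged as fallback.
#'
#' @param origin integer origins per high-density marker (0/1/NA), named.
#' @param sire_pat,sire_mat sire allele vectors over the same markers.
#' @param map marker map.
#' @param offspring_hd offspring dosages over the high-density markers
#'   (`NA` off panel), used only for the fallback conflict count.
#' @return list: `pat` (allele vector), `provenance` (`"origin"` or
#'   `"fallback"` per marker).
#' @export
impute_paternal <- function(origin, sire_pat, sire_mat, map, offspring_hd) {
  n <- length(origin)
  pat <- rep(NA_integer_, n)
  prov <- rep("origin", n)
  names(pat) <- names(origin)
  idx0 <- !is.na(origin) & origin == 0L
  idx1 <- !is.na(origin) & origin == 1L
  pat[idx0] <- sire_pat[idx0]
  pat[idx1] <- sire_mat[idx1]
  und <- is.na(origin)
  if (any(und)) {
    midx <- match(names(origin), map$marker_id)
    for (chr in unique(map$chrom[midx[und]])) {
      sel <- which(und & map$chrom[midx] == chr)
      d <- offspring_hd[sel]
      conf_p <- sum((d == 0 & sire_pat[sel] == 1) |
                    (d == 2 & sire_pat[sel] == 0), na.rm = TRUE)
      conf_m <- sum((d == 0 & sire_mat[sel] == 1) |
                    (d == 2 & sire_mat[sel] == 0), na.rm = TRUE)
      pat[sel] <- if (conf_m < conf_p) sire_mat[sel] else sire_pat[sel]
      prov[sel] <- "fallback"
    }
  }
  list(pat = pat, provenance = prov)
}

#' Derive the partial maternal haplotype at the panel markers
#'
#' The maternal allele is the observed dosage minus the imputed paternal
#' allele where that difference is a valid allele (0 or 1); otherwise it is
#' missing and a derivation conflict is counted.
#'
#' @param offspring dosage vector at panel markers.
#' @param pat imputed paternal alleles at the same markers.
#' @return list: `mat` (0/1/NA), `conflict` (logical).
#' @export
derive_partial_maternal <- function(offspring, pat) {
  m <- offspring - pat
  conflict <- !is.na(m) & !(m %in% c(0, 1))
  m[conflict | is.na(m)] <- NA_integer_
  list(mat = as.integer(m), conflict = conflict)
}

#' Conflict profile of a library haplotype against a partial maternal
#' haplotype
#'
#' For a focal panel marker m, `c(k)` counts the panel markers m2 on the
#' chromosome for which exactly k panel markers between m and m2 carry
#' conflicting alleles (library haplotype vs known maternal allele). In the
#' default `"open"` convention both endpoints are excluded from the
#' conflict count; `"half-open"` also counts a conflict at m2 itself.
#' Missing maternal alleles never conflict. Markers with more than 4
#' intervening conflicts contribute nothing.
#'
#' @param h library haplotype alleles at the chromosome's panel markers.
#' @param i partial maternal alleles at the same markers (NA = unknown).
#' @param focal index of the focal marker among the panel markers.
#' @param pos marker positions (Mb); markers are ranked by position (ties
#'   by index) before counting.
#' @param interval endpoint convention, `"open"` (default) or
#'   `"half-open"`.
#' @return integer vector `c(k)` for k = 0..4.
#' @export
conflict_counts <- function(h, i, focal, pos,
                            interval = c("open", "half-open")) {
  interval <- match.arg(interval)
  n <- length(h)
  stopifnot(length(i) == n, length(pos) == n, focal >= 1, focal <= n)
  o <- order(pos, seq_len(n))
  t <- match(focal, o)
  conf <- !is.na(i[o]) & !is.na(h[o]) & h[o] != i[o]
  cs <- cumsum(conf)
  cnt <- integer(0)
  if (t > 1L) {
    j <- seq_len(t - 1L)
    cnt <- c(cnt, if (interval == "open") cs[t - 1L] - cs[j]
                  else cs[t - 1L] - cs[j] + conf[j])
  }
  if (t < n) {
    j <- (t + 1L):n
    cnt <- c(cnt, if (interval == "open") cs[j - 1L] - cs[t]
                  else cs[j] - cs[t])
  }
  out <- vapply(0:4, function(k) sum(cnt == k), integer(1))
  names(out) <- paste0("c", 0:4)
  out
}

#' Score a library haplotype for maternal imputation
#'
#' `score = (1 + a) * sum_k c(k) * 0.75^k`, where a is the additive
#' relationship between the dam of the individual being imputed and the
#' carrier of the haplotype. Distant matches (separated by conflicts) still
#' contribute, discounted by 0.75 per intervening conflict, which makes the
#' score robust to sporadic phasing errors; the relationship factor favours
#' haplotypes of the dam's relatives, whose agreement is less likely to be
#' coincidental.
#'
#' @param counts `c(k)` vector from [conflict_counts()].
#' @param a additive relationship (>= 0; 0 for carriers of unknown
#'   ancestry).
#' @param decay per-conflict discount (default 0.75).
#' @return non-negative score.
#' @export
score_haplotype <- function(counts, a, decay = 0.75) {
  stopifnot(length(counts) == 5, a >= 0)
  (1 + a) * sum(counts * decay^(0:4))
}

# flatten a haplotype library into a (2H x markers) allele matrix with
# carrier ids and strand labels, in deterministic (id, strand) order
flatten_haplib <- function(lib) {
  ids <- sort(rownames(lib$pat))
  H <- matrix(NA_integer_, 2 * length(ids), ncol(lib$pat),
              dimnames = list(NULL, colnames(lib$pat)))
  H[seq(1, 2 * length(ids), by = 2), ] <- lib$pat[ids, , drop = FALSE]
  H[seq(2, 2 * length(ids), by = 2), ] <- lib$mat[ids, , drop = FALSE]
  list(alleles = H, carrier = rep(ids, each = 2),
       strand = rep(c("pat", "mat"), length(ids)))
}

#' Impute the full maternal haplotype from the haplotype library
#'
#' Panel markers are processed in ascending position. At each focal marker
#' still adjacent to unimputed positions, every library haplotype is scored
#' with [score_haplotype()] and the winner (ties: larger relationship, then
#' lowest carrier id, then paternal strand) is copied over the largest
#' window around the focal marker bounded exclusively by the nearest panel
#' markers at which it conflicts with the known maternal alleles (or the
#' chromosome ends). Only still-missing positions are written. Positions no
#' window reaches are filled from the best-scoring haplotype seen on the
#' chromosome, flagged as fallback. Chromosomes without a single known
#' maternal allele are filled entirely from the library haplotype of the
#' dam's closest relative.
#'
#' @param mat_partial maternal alleles at panel markers (0/1/NA), named by
#'   marker id.
#' @param lib a [haplotype_library()] over the high-density markers.
#' @param map marker map.
#' @param rel named numeric: additive relationship between the dam and each
#'   library individual (from [additive_relationship()]); missing names get
#'   0.
#' @param interval endpoint convention for [conflict_counts()].
#' @return list: `mat` (allele vector over the library's markers),
#'   `provenance` per marker (`"observed"`, `"library"`, `"fallback"`).
#' @export
impute_maternal <- function(mat_partial, lib, map, rel = numeric(0),
                            interval = c("open", "half-open")) {
  interval <- match.arg(interval)
  if (nrow(lib$pat) == 0L) stop("empty haplotype library")
  fl <- flatten_haplib(lib)
  a_h <- rel[fl$carrier]
  a_h[is.na(a_h)] <- 0
  hd_markers <- colnames(lib$pat)
  mat <- rep(NA_integer_, length(hd_markers))
  prov <- rep(NA_character_, length(hd_markers))
  names(mat) <- names(prov) <- hd_markers
  hidx <- match(hd_markers, map$marker_id)

  panel_ids <- names(mat_partial)
  pidx <- match(panel_ids, map$marker_id)

  for (chr in unique(map$chrom[hidx])) {
    if (is.na(chr)) next
    hsel <- which(map$chrom[hidx] == chr)
    hord <- hsel[order(map$pos_mb[hidx[hsel]], hsel)]
    hpos <- map$pos_mb[hidx[hord]]
    psel <- which(map$chrom[pidx] == chr)
    pord <- psel[order(map$pos_mb[pidx[psel]], psel)]
    ppos <- map$pos_mb[pidx[pord]]
    i_chr <- mat_partial[pord]
    P <- length(pord)

    # seed with the derived maternal alleles (panel markers are HD markers)
    known <- which(!is.na(i_chr))
    ppos_in_hd <- match(panel_ids[pord], hd_markers)
    mat[ppos_in_hd[known]] <- i_chr[known]
    prov[ppos_in_hd[known]] <- "observed"

    if (!length(known) || P == 0L) {
      # no maternal information: most related carrier, paternal strand first
      pick <- order(-a_h, seq_along(a_h))[1L]
      fill <- hord[is.na(mat[hord])]
      mat[fill] <- fl$alleles[pick, fill]
      prov[fill] <- "fallback"
      next
    }

    # conflict matrix of every haplotype vs known maternal alleles
    Hm <- fl$alleles[, ppos_in_hd, drop = FALSE]
    Cm <- !is.na(Hm) & matrix(!is.na(i_chr), nrow(Hm), P, byrow = TRUE) &
          Hm != matrix(i_chr, nrow(Hm), P, byrow = TRUE)
    Cm[is.na(Cm)] <- FALSE
    cs <- Cm * 1
    if (P > 1L) for (jj in 2:P) cs[, jj] <- cs[, jj - 1L] + Cm[, jj]

    best_score <- -Inf; best_row <- NA_integer_
    for (t in seq_len(P)) {
      if (!anyNA(mat[hord])) break
      # skip focal markers whose local neighbourhood is already filled
      lo <- if (t > 1L) ppos[t - 1L] else -Inf
      hi <- if (t < P) ppos[t + 1L] else Inf
      local <- hord[hpos >= lo & hpos <= hi]
      if (!anyNA(mat[local])) next

      cnt_cols <- vector("list", 2L)
      if (t > 1L) {
        j <- seq_len(t - 1L)
        base <- cs[, t - 1L] - cs[, j, drop = FALSE]
        if (interval == "half-open")
          base <- base + Cm[, j, drop = FALSE]
        cnt_cols[[1L]] <- base
      }
      if (t < P) {
        j <- (t + 1L):P
        cnt_cols[[2L]] <- if (interval == "open")
          cs[, j - 1L, drop = FALSE] - cs[, t]
        else cs[, j, drop = FALSE] - cs[, t]
      }
      cnt <- do.call(cbind, cnt_cols)
      sc <- if (is.null(cnt)) rep(0, nrow(Cm))
            else rowSums(0.75^cnt * (cnt <= 4))
      sc <- (1 + a_h) * sc
      mx <- max(sc)
      cand <- which(sc == mx)
      if (length(cand) > 1L) {
        amax <- max(a_h[cand])
        cand <- cand[a_h[cand] == amax]
      }
      pick <- cand[1L]
      if (mx > best_score) { best_score <- mx; best_row <- pick }

      # window bounded by the nearest conflicting panel markers
      confl <- which(Cm[pick, ])
      lo_b <- confl[confl < t]
      hi_b <- confl[confl > t]
      wlo <- if (length(lo_b)) ppos[max(lo_b)] else -Inf
      whi <- if (length(hi_b)) ppos[min(hi_b)] else Inf
      win <- hord[hpos > wlo & hpos < whi]
      fill <- win[is.na(mat[win])]
      if (length(fill)) {
        mat[fill] <- fl$alleles[pick, fill]
        prov[fill] <- "library"
      }
    }
    # residual gaps: globally best-scoring haplotype of the chromosome
    gaps <- hord[is.na(mat[hord])]
    if (length(gaps)) {
      if (is.na(best_row)) best_row <- order(-a_h, seq_along(a_h))[1L]
      mat[gaps] <- fl$alleles[best_row, gaps]
      prov[gaps] <- "fallback"
    }
  }
  list(mat = mat, provenance = prov)
}

#' Impute one low-density genotyped individual to high density
#'
#' Full pipeline: trace paternal allele origins through the sire, extend
#' origins with midpoint crossovers, copy the paternal alleles, derive the
#' maternal alleles at the panel markers, and complete the maternal
#' haplotype from the relationship-weighted library. Deterministic.
#'
#' @param offspring_ld named dosage vector at the panel markers (0/1/2/NA).
#' @param sire_id id of the sire; must be in the library.
#' @param lib a [haplotype_library()] over the high-density markers.
#' @param map marker map covering the library markers.
#' @param ped an [pedigree()] for relationship lookups; the individual's
#'   dam is taken from it via `dam_id` or the offspring id.
#' @param dam_id id of the dam (used only for relationships; the dam need
#'   not be genotyped). `NA` sets all relationships to 0.
#' @param rel optional precomputed named relationship vector (dam vs
#'   library individuals); overrides `ped`/`dam_id`.
#' @param interval endpoint convention for conflict counting.
#' @return list: `dosage` (imputed high-density dosages), `pat`, `mat`
#'   (allele vectors), `provenance_pat`, `provenance_mat`,
#'   `mendelian_conflicts`, `derivation_conflicts` (marker ids).
#' @export
impute_individual <- function(offspring_ld, sire_id, lib, map, ped = NULL,
                              dam_id = NA, rel = NULL,
                              interval = c("open", "half-open")) {
  interval <- match.arg(interval)
  if (!sire_id %in% rownames(lib$pat))
    stop("sire ", sire_id, " is not in the haplotype library")
  hd_markers <- colnames(lib$pat)
  panel_ids <- names(offspring_ld)
  if (is.null(panel_ids) || !all(panel_ids %in% hd_markers))
    stop("offspring genotypes must be named by (high-density) marker ids")
  if (all(is.na(offspring_ld)))
    warning("offspring has no called panel genotypes; output is all-fallback")

  sire_pat <- lib$pat[sire_id, ]
  sire_mat <- lib$mat[sire_id, ]

  org <- determine_origins(offspring_ld, sire_pat[panel_ids],
                           sire_mat[panel_ids])
  origin_hd <- extend_origins(org$which, map, hd_markers)

  offspring_hd <- rep(NA_integer_, length(hd_markers))
  names(offspring_hd) <- hd_markers
  offspring_hd[panel_ids] <- offspring_ld
  # conflicted panel markers are uninformative for fallback counting too
  offspring_hd[panel_ids[org$conflict]] <- NA_integer_

  pp <- impute_paternal(origin_hd, sire_pat, sire_mat, map, offspring_hd)

  dm <- derive_partial_maternal(offspring_hd[panel_ids], pp$pat[panel_ids])
  mat_partial <- dm$mat
  names(mat_partial) <- panel_ids

  if (is.null(rel)) {
    rel <- relationship_to_library(ped, dam_id, rownames(lib$pat))
  }
  mm <- impute_maternal(mat_partial, lib, map, rel, interval)

  list(dosage = pp$pat + mm$mat,
       pat = pp$pat, mat = mm$mat,
       provenance_pat = pp$provenance,
       provenance_mat = mm$provenance,
       mendelian_conflicts = panel_ids[org$conflict],
       derivation_conflicts = panel_ids[dm$conflict])
}

#' Relationships between a dam and the haplotype library individuals
#'
#' @param ped an [pedigree()] or `NULL`.
#' @param dam_id dam id (`NA` or absent from pedigree: all 0).
#' @param lib_ids library individual ids.
#' @return named numeric vector of additive relationships.
#' @export
relationship_to_library <- function(ped, dam_id, lib_ids) {
  rel <- rep(0, length(lib_ids))
  names(rel) <- lib_ids
  if (is.null(ped) || is.na(dam_id) || !dam_id %in% ped$id) return(rel)
  inped <- intersect(lib_ids, ped$id)
  if (length(inped)) {
    A <- pedigree_amatrix(ped, unique(c(dam_id, inped)))
    rel[inped] <- A[dam_id, inped]
  }
  rel
}

#' Impute a set of low-density genotyped offspring
#'
#' Vectorised driver over individuals sharing one panel, library and map.
#' Sires and dams are looked up in the pedigree; dam relationships to the
#' library are computed once.
#'
#' @param geno_ld dosage matrix, offspring x panel markers.
#' @param ped an [pedigree()] containing the offspring.
#' @param lib a [haplotype_library()].
#' @param map marker map.
#' @param interval endpoint convention.
#' @return list: `dosage` (offspring x high-density markers),
#'   `results` (per-individual lists from [impute_individual()]).
#' @export
impute_offspring_set <- function(geno_ld, ped, lib, map,
                                 interval = c("open", "half-open")) {
  interval <- match.arg(interval)
  ids <- rownames(geno_ld)
  sire <- ped$sire[match(ids, ped$id)]
  dam <- ped$dam[match(ids, ped$id)]
  if (anyNA(sire))
    stop("offspring without pedigree sire: ",
         paste(ids[is.na(sire)], collapse = ", "))
  lib_ids <- rownames(lib$pat)
  dams <- unique(stats::na.omit(dam))
  relmat <- matrix(0, length(dams), length(lib_ids),
                   dimnames = list(dams, lib_ids))
  inped <- intersect(lib_ids, ped$id)
  dams_in <- intersect(dams, ped$id)
  if (length(inped) && length(dams_in)) {
    A <- pedigree_amatrix(ped, unique(c(dams_in, inped)))
    relmat[dams_in, inped] <- A[dams_in, inped, drop = FALSE]
  }
  out <- matrix(NA_integer_, length(ids), ncol(lib$pat),
                dimnames = list(ids, colnames(lib$pat)))
  results <- vector("list", length(ids))
  names(results) <- ids
  for (k in seq_along(ids)) {
    rel <- if (!is.na(dam[k]) && dam[k] %in% dams) relmat[dam[k], ] else
      stats::setNames(rep(0, length(lib_ids)), lib_ids)
    res <- impute_individual(geno_ld[k, ], sire[k], lib, map,
                             rel = rel, interval = interval)
    out[k, ] <- res$dosage
    results[[k]] <- res
  }
  list(dosage = out, results = results)
}
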