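#' Marker equivalence classes from genotype correlation chains
#'
#' Groups markers into classes expected to lie on the same chromosome. Two
#' markers belong together when a chain of markers connects them in which
#' every adjacent pair has absolute genotype correlation above `r_threshold`
#' and every interior chain member has MAF above `maf_min`. The MAF
#' condition keeps rare markers, whose correlations are noisy, from gluing
#' unrelated chromosome segments together: they may terminate a chain but
#' not relay one.
#'
#' Because low-MAF markers may be linked to several classes without those
#' classes being linked to each other, the grouping is resolved
#' deterministically: connected components are built over the high-MAF
#' markers (edges where `|r| > r_threshold`), then each low-MAF marker joins
#' the class of its strongest admissible neighbour (ties broken by lowest
#' marker index). The result is invariant to marker input order.
#'
#' @param geno dosage matrix recoded to the minor allele.
#' @param maf named per-marker MAF (from [compute_maf()]).
#' @param r_threshold chain correlation threshold (absolute value).
#' @param maf_min interior-marker MAF threshold.
#' @param cor_mat optional precomputed correlation matrix (all pairs);
#'   supplied by callers that already have it.
#' @return integer vector of class ids, named by marker.
#' @export
build_marker_classes <- function(geno, maf, r_threshold = 0.4,
                                 maf_min = 0.15, cor_mat = NULL) {
  m <- ncol(geno)
  ids <- colnames(geno)
  stopifnot(!is.null(ids), length(maf) == m)
  maf <- maf[ids]
  if (is.null(cor_mat)) cor_mat <- genotype_cor_matrix(geno)
  adj <- !is.na(cor_mat) & abs(cor_mat) > r_threshold
  diag(adj) <- FALSE

  high <- !is.na(maf) & maf > maf_min
  parent <- seq_len(m)  # union-find
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  hi_idx <- which(high)
  if (length(hi_idx) > 1L) {
    ee <- which(adj[hi_idx, hi_idx, drop = FALSE], arr.ind = TRUE)
    ee <- ee[ee[, 1] < ee[, 2], , drop = FALSE]
    for (r in seq_len(nrow(ee)))
      union2(hi_idx[ee[r, 1]], hi_idx[ee[r, 2]])
  }
  for (i in which(!high)) {
    nb <- which(adj[i, ])
    if (!length(nb)) next
    r_nb <- abs(cor_mat[i, nb])
    best <- nb[which(r_nb == max(r_nb))]  # tie -> lowest index
    union2(i, min(best))
  }
  roots <- vapply(seq_len(m), find, integer(1))
  cls <- match(roots, sort(unique(roots)))
  names(cls) <- ids
  cls
}

#' Assign each marker class to a chromosome by majority of known positions
#'
#' A class is assigned to chromosome c iff strictly more than `majority`
#' (default 95%) of its known-position members lie on c. Classes failing
#' the majority rule, or containing no known-position marker, stay
#' unassigned (`NA`).
#'
#' @param classes integer class ids per marker (from
#'   [build_marker_classes()]).
#' @param map marker map (`marker_id`, `chrom`, `pos_mb`, `known`).
#' @param majority required fraction, strict.
#' @return named character vector: chromosome (or `NA`) per class id.
#' @export
assign_class_chromosomes <- function(classes, map, majority = 0.95) {
  map <- map[match(names(classes), map$marker_id), , drop = FALSE]
  known <- map$known & !is.na(map$chrom)
  out <- rep(NA_character_, length(unique(classes)))
  names(out) <- as.character(sort(unique(classes)))
  for (cl in sort(unique(classes))) {
    members <- classes == cl & known
    if (!any(members)) next
    tab <- table(map$chrom[members])
    frac <- max(tab) / sum(tab)
    if (frac > majority)
      out[as.character(cl)] <- names(tab)[which.max(tab)]
  }
  out
}

#' Approximate unknown marker positions from their best-correlated partner
#'
#' For every marker whose class received a chromosome assignment but whose
#' own position is unknown, the position is set to the known position of the
#' same-chromosome marker maximizing the absolute genotype correlation with
#' it, and the marker is flagged as having an estimated position
#' (`known = FALSE`, weight u = 0.8 downstream). Known-position markers
#' whose class chromosome contradicts their mapped chromosome are remapped
#' the same way and flagged (`remapped`). Markers in unassigned classes
#' remain unplaced.
#'
#' @param classes class ids from [build_marker_classes()].
#' @param class_chrom assignments from [assign_class_chromosomes()].
#' @param map marker map.
#' @param geno dosage matrix (minor-allele coded).
#' @param cor_mat optional precomputed correlation matrix.
#' @return list with `map` (updated), `report` (data.frame per changed
#'   marker: `marker_id`, `action` in `{approximated, remapped}`, `partner`,
#'   `chrom`, `pos_mb`), `unplaced` (marker ids left without position).
#' @export
approximate_positions <- function(classes, class_chrom, map, geno,
                                  cor_mat = NULL) {
  map <- map[match(names(classes), map$marker_id), , drop = FALSE]
  if (is.null(cor_mat)) cor_mat <- genotype_cor_matrix(geno)
  ids <- names(classes)
  assigned <- class_chrom[as.character(classes)]
  known0 <- map$known & !is.na(map$chrom)

  # anchors: markers whose mapped position stands (known and not contradicted)
  anchor <- known0 & (is.na(assigned) | assigned == map$chrom)
  need_pos <- !known0 & !is.na(assigned)                 # unknown position
  need_remap <- known0 & !is.na(assigned) & assigned != map$chrom

  report <- data.frame(marker_id = character(0), action = character(0),
                       partner = character(0), chrom = character(0),
                       pos_mb = numeric(0), stringsAsFactors = FALSE)
  unplaced <- character(0)
  for (i in which(need_pos | need_remap)) {
    chr <- assigned[i]
    cand <- which(anchor & map$chrom == chr)
    cand <- setdiff(cand, i)
    r <- abs(cor_mat[i, cand])
    r[is.na(r)] <- -Inf
    if (!length(cand) || all(r == -Inf)) {
      map$chrom[i] <- NA; map$pos_mb[i] <- NA; map$known[i] <- FALSE
      unplaced <- c(unplaced, ids[i])
      warning("no known-position partner on chromosome ", chr,
              " for marker ", ids[i], "; left unplaced")
      next
    }
    best <- cand[which.max(r)]  # which.max: first (lowest index) on ties
    action <- if (need_remap[i]) "remapped" else "approximated"
    map$chrom[i] <- chr
    map$pos_mb[i] <- map$pos_mb[best]
    map$known[i] <- FALSE
    report <- rbind(report, data.frame(
      marker_id = ids[i], action = action, partner = ids[best],
      chrom = chr, pos_mb = map$pos_mb[best], stringsAsFactors = FALSE))
  }
  # markers in unassigned classes with unknown position stay unplaced
  unplaced <- union(unplaced, ids[!known0 & is.na(assigned)])
  list(map = map, report = report, unplaced = unplaced)
}

#' One-call position approximation pipeline
#'
#' Runs [build_marker_classes()], [assign_class_chromosomes()] and
#' [approximate_positions()] with shared correlation matrix.
#'
#' @inheritParams build_marker_classes
#' @inheritParams assign_class_chromosomes
#' @param map marker map.
#' @return as [approximate_positions()], plus `classes` and `class_chrom`.
#' @export
approximate_marker_positions <- function(geno, map, maf = NULL,
                                         r_threshold = 0.4, maf_min = 0.15,
                                         majority = 0.95) {
  if (is.null(maf)) {
    mf <- compute_maf(geno)
    geno <- mf$geno
    maf <- mf$maf
  }
  cm <- genotype_cor_matrix(geno)
  cls <- build_marker_classes(geno, maf, r_threshold, maf_min, cor_mat = cm)
  cc <- assign_class_chromosomes(cls, map, majority)
  res <- approximate_positions(cls, cc, map, geno, cor_mat = cm)
  res$classes <- cls
  res$class_chrom <- cc
  res
}
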