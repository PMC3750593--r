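#' Build a validated pedigree
#'
#' Constructs a pedigree object from individual/sire/dam triples. Unknown
#' parents are coded as `NA` or `"0"`. Parents that appear only in the sire
#' or dam column are added as founders. The pedigree must be acyclic; a
#' topological order (parents before offspring) is computed at construction
#' time and reused by all relationship queries.
#'
#' @param id character vector of individual identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA` or `"0"`
#'   means unknown.
#' @return a `data.frame` of class `ld_pedigree` with columns `id`, `sire`,
#'   `dam` in topological order.
#' @examples
#' ped <- pedigree(c("A", "B", "X"), c(NA, NA, "A"), c(NA, NA, "B"))
#' additive_relationship(ped, "X", "A")
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have equal length")
  sire[sire %in% c("0", "")] <- NA
  dam[dam %in% c("0", "")] <- NA
  if (anyDuplicated(id))
    stop("duplicate individual ids in pedigree: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  # implicit founders: parents never listed as individuals
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  ord <- topo_order(id, sire, dam)
  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  class(ped) <- c("ld_pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors on cycles.
topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- idx[sire]; di <- idx[dam]  # NA where unknown
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n)
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(idx, out)], collapse = ", "))
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A for a set of
#' pedigree members with the recursive tabular method: for individual i with
#' parents s and d, `A[i,i] = 1 + 0.5 * A[s,d]` and
#' `A[i,j] = 0.5 * (A[s,j] + A[d,j])` for j preceding i, with unknown parents
#' contributing zero.
#'
#' @param ped an [pedigree()] object.
#' @param ids optional character vector restricting the returned matrix (the
#'   computation still uses all ancestors of `ids`).
#' @return symmetric numeric matrix with dimnames `ids`.
#' @export
pedigree_amatrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "ld_pedigree"))
  if (is.null(ids)) ids <- ped$id
  miss <- setdiff(ids, ped$id)
  if (length(miss))
    stop("ids not in pedigree: ", paste(miss, collapse = ", "))
  keep <- ancestors_of(ped, ids)
  sub <- ped[ped$id %in% keep, , drop = FALSE]
  n <- nrow(sub)
  pos <- seq_len(n); names(pos) <- sub$id
  si <- pos[sub$sire]; di <- pos[sub$dam]
  A <- matrix(0, n, n, dimnames = list(sub$id, sub$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (!is.na(s)) A[s, j] else 0) +
                    (if (!is.na(d)) A[d, j] else 0))
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A[ids, ids, drop = FALSE]
}

# all ancestors of ids (inclusive), by walking the parent links
ancestors_of <- function(ped, ids) {
  sire <- ped$sire; dam <- ped$dam
  names(sire) <- names(dam) <- ped$id
  seen <- character(0)
  frontier <- intersect(ids, ped$id)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    parents <- stats::na.omit(unique(c(sire[frontier], dam[frontier])))
    frontier <- setdiff(parents, seen)
  }
  seen
}

#' Additive genetic relationship between two individuals
#'
#' Pedigree-based numerator relationship `a_ij` computed by the tabular
#' method on the ancestor subgraph of the two individuals. For non-inbred
#' pedigrees this is 0.5 for parent-offspring, 0.25 for
#' grandparent-grandchild, and `a_ii = 1 + F_i` on the diagonal. Individuals
#' absent from the pedigree get relationship 0 with a warning, so that
#' haplotype carriers of unknown ancestry can still be scored.
#'
#' @param ped an [pedigree()] object.
#' @param i,j individual ids.
#' @return scalar relationship, >= 0.
#' @export
additive_relationship <- function(ped, i, j) {
  i <- as.character(i); j <- as.character(j)
  absent <- setdiff(c(i, j), ped$id)
  if (length(absent)) {
    warning("individual(s) not in pedigree, relationship set to 0: ",
            paste(absent, collapse = ", "))
    return(0)
  }
  A <- pedigree_amatrix(ped, unique(c(i, j)))
  A[i, j]
}
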