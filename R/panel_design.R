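#' Panel design configuration
#'
#' Settings for low-density panel selection. The distance between two
#' placed markers on the same chromosome is
#' `d = lambda * |dloc| + (1 - lambda) * kappa * (1 - corr_discount * |r|)`
#' with `lambda = min(1, |dloc| / kappa)`: beyond `kappa` Mb the distance is
#' purely physical, below it the genotype correlation takes over so that two
#' nearby markers in linkage equilibrium still count as usefully distinct.
#' Markers on different chromosomes are infinitely distant. `kappa = 0`
#' selects the naive equally-spaced limit `d = |dloc|`.
#'
#' @param kappa correlation-window width in Mb (default 5); 0 = naive mode.
#' @param corr_discount weight of the correlation inside the window
#'   (default 0.99, so co-located perfectly correlated markers keep a small
#'   positive distance).
#' @param score_mode one of `"maf_u"` (score = MAF x u), `"uniform"`
#'   (score = 1, the naive variant), `"variance"`
#'   (score = 2 MAF (1-MAF) x mean squared marker effect).
#' @param u_known,u_estimated position-confidence weights: markers with
#'   reliable physical positions get `u_known` (default 1), markers whose
#'   position was approximated from LD get `u_estimated` (default 0.8),
#'   penalising them during selection.
#' @param include_estimated_positions if `FALSE`, markers with estimated
#'   positions are excluded from candidacy altogether.
#' @param chrom_length_lambda if non-`NULL`, multiply scores by
#'   `((1 - l) * L_m + l * max(L)) / L_m` (L_m = length of the marker's
#'   chromosome) to shift panel markers toward short chromosomes.
#' @param score_power exponent reading of the score (`FALSE`, the default,
#'   multiplies MAF by u; `TRUE` uses `MAF ^ u` instead).
#' @param effects optional named per-marker mean squared effects for
#'   `score_mode = "variance"` (default 1 for all markers).
#' @return a `panel_config` list.
#' @export
panel_config <- function(kappa = 5, corr_discount = 0.99,
                         score_mode = c("maf_u", "uniform", "variance"),
                         u_known = 1, u_estimated = 0.8,
                         include_estimated_positions = TRUE,
                         chrom_length_lambda = NULL,
                         score_power = FALSE, effects = NULL) {
  stopifnot(kappa >= 0, corr_discount >= 0, corr_discount <= 1)
  structure(list(kappa = kappa, corr_discount = corr_discount,
                 score_mode = match.arg(score_mode),
                 u_known = u_known, u_estimated = u_estimated,
                 include_estimated_positions = include_estimated_positions,
                 chrom_length_lambda = chrom_length_lambda,
                 score_power = score_power, effects = effects),
            class = "panel_config")
}

#' Distance between two placed markers
#'
#' @param m1,m2 marker ids.
#' @param map marker map (both markers must be placed).
#' @param geno dosage matrix (minor-allele coded) for the correlation term.
#' @param cfg a [panel_config()].
#' @return non-negative distance, `Inf` across chromosomes.
#' @export
marker_distance <- function(m1, m2, map, geno, cfg = panel_config()) {
  i1 <- match(m1, map$marker_id); i2 <- match(m2, map$marker_id)
  if (is.na(map$chrom[i1]) || is.na(map$chrom[i2]))
    stop("marker_distance requires placed markers")
  if (map$chrom[i1] != map$chrom[i2]) return(Inf)
  dloc <- abs(map$pos_mb[i1] - map$pos_mb[i2])
  if (cfg$kappa == 0) return(dloc)
  lambda <- min(1, dloc / cfg$kappa)
  r <- if (lambda < 1) {
    rr <- genotype_correlation(geno[, m1], geno[, m2])
    if (is.na(rr)) 0 else abs(rr)
  } else 0
  lambda * dloc + (1 - lambda) * cfg$kappa * (1 - cfg$corr_discount * r)
}

#' Selection score of a marker
#'
#' In the default mode the score is MAF times the position-confidence
#' weight u (1 for reliable positions, 0.8 for LD-approximated ones), so
#' informative, well-placed markers are favoured.
#'
#' @param marker marker id (vectorised).
#' @param maf named per-marker MAF.
#' @param map marker map.
#' @param cfg a [panel_config()].
#' @return numeric score(s), >= 0.
#' @export
marker_score <- function(marker, maf, map, cfg = panel_config()) {
  i <- match(marker, map$marker_id)
  u <- ifelse(map$known[i], cfg$u_known, cfg$u_estimated)
  s <- switch(cfg$score_mode,
    uniform = rep(1, length(marker)),
    maf_u = if (cfg$score_power) maf[marker]^u else maf[marker] * u,
    variance = {
      a2 <- if (is.null(cfg$effects)) rep(1, length(marker))
            else cfg$effects[marker]
      2 * maf[marker] * (1 - maf[marker]) * a2
    })
  if (!is.null(cfg$chrom_length_lambda)) {
    lens <- tapply(map$pos_mb, map$chrom, max, na.rm = TRUE)
    Lm <- lens[map$chrom[i]]
    l <- cfg$chrom_length_lambda
    s <- s * ((1 - l) * Lm + l * max(lens)) / Lm
  }
  unname(s)
}

#' Greedy selection of a low-density marker panel
#'
#' Builds a panel of the requested size by greedy maximization: each step
#' adds the candidate maximizing score x (minimum distance to the markers
#' already selected). Candidates on chromosomes not yet represented in the
#' panel have infinite minimum distance and therefore outrank every
#' finite-objective candidate; among them the highest score wins. Ties are
#' broken by lowest marker index, making the procedure fully deterministic.
#'
#' With `panel_config(kappa = 0, score_mode = "uniform")` and candidates
#' restricted to known positions this reduces to the naive equally-spaced
#' design: each pick lands in the centre of the largest remaining gap.
#'
#' @param candidates marker ids eligible for selection (must be placed).
#' @param geno dosage matrix (minor-allele coded).
#' @param map marker map.
#' @param size panel size.
#' @param maf named per-marker MAF.
#' @param cfg a [panel_config()].
#' @return data.frame panel: `rank`, `marker_id`, `chrom`, `pos_mb`,
#'   `score`, `objective` (score x min-distance at pick time; `Inf` for
#'   chromosome-opening picks).
#' @export
select_panel <- function(candidates, geno, map, size, maf,
                         cfg = panel_config()) {
  map_idx <- match(candidates, map$marker_id)
  if (anyNA(map_idx)) stop("candidate markers missing from map")
  placed <- !is.na(map$chrom[map_idx])
  if (!all(placed)) stop("all candidates must be placed on a chromosome")
  if (!cfg$include_estimated_positions) {
    keep <- map$known[map_idx]
    candidates <- candidates[keep]; map_idx <- map_idx[keep]
  }
  n_cand <- length(candidates)
  if (size > n_cand)
    stop("panel size ", size, " exceeds ", n_cand, " candidates")

  score <- marker_score(candidates, maf, map, cfg)
  chrom <- map$chrom[map_idx]
  pos <- map$pos_mb[map_idx]
  ord0 <- order(match(candidates, map$marker_id))  # stable index order

  mind <- rep(Inf, n_cand)          # min distance to current panel
  selected <- integer(0)
  rank_ <- integer(size); obj_ <- numeric(size)
  avail <- rep(TRUE, n_cand)
  for (step in seq_len(size)) {
    objective <- score * mind
    objective[!avail] <- -Inf
    inf_cand <- avail & is.infinite(mind)
    if (any(inf_cand)) {
      # chromosome-opening picks: compare by score, tie -> lowest index
      best_sc <- max(score[inf_cand])
      pick <- which(inf_cand & score == best_sc)[1L]
      obj_[step] <- Inf
    } else {
      best_obj <- max(objective)
      pick <- which(avail & objective == best_obj)[1L]
      obj_[step] <- best_obj
    }
    selected <- c(selected, pick)
    avail[pick] <- FALSE
    # incremental min-distance update against the new panel member
    upd <- which(avail & chrom == chrom[pick])
    for (j in upd) {
      d <- pair_distance(pos[pick], pos[j], candidates[pick], candidates[j],
                         geno, cfg)
      if (d < mind[j]) mind[j] <- d
    }
  }
  data.frame(rank = seq_len(size),
             marker_id = candidates[selected],
             chrom = chrom[selected],
             pos_mb = pos[selected],
             score = score[selected],
             objective = obj_,
             stringsAsFactors = FALSE)
}

# same-chromosome distance without map lookup (positions already known)
pair_distance <- function(p1, p2, m1, m2, geno, cfg) {
  dloc <- abs(p1 - p2)
  if (cfg$kappa == 0) return(dloc)
  lambda <- min(1, dloc / cfg$kappa)
  r <- if (lambda < 1) {
    rr <- genotype_correlation(geno[, m1], geno[, m2])
    if (is.na(rr)) 0 else abs(rr)
  } else 0
  lambda * dloc + (1 - lambda) * cfg$kappa * (1 - cfg$corr_discount * r)
}

#' Write / read a panel TSV (`rank`, `marker_id`, `chrom`, `pos_mb`,
#' `score`, `objective`)
#' @param panel data.frame from [select_panel()].
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(marker_id = "character",
                                   chrom = "character"))
}
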