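#' Simple deregression of EBV
#'
#' Removes the shrinkage of a BLUP EBV by dividing by its reliability:
#' `dEBV = EBV / r2`. Precomputed deregressed proofs can be passed through
#' unchanged with `debv`.
#'
#' @param ebv numeric EBV.
#' @param r2 reliability in (0, 1].
#' @param debv optional precomputed deregressed EBV (pass-through).
#' @return deregressed records.
#' @export
deregress <- function(ebv, r2, debv = NULL) {
  if (!is.null(debv)) return(debv)
  if (any(r2 <= 0 | r2 > 1)) stop("reliability must be in (0, 1]")
  ebv / r2
}

#' Residual weight for heterogeneous error variances
#'
#' In the weighted GBLUP the error variance of individual i is proportional
#' to `V_A * (C + (1 - r2_i) / r2_i)`, where C is the fraction of additive
#' variance not captured by the markers (default 0.25) and r2_i the
#' reliability of the EBV underlying the record. The proportionality
#' constant is absorbed into the variance ratio, so the weight returned is
#' `w = C + (1 - r2) / r2`.
#'
#' @param r2 reliability in (0, 1].
#' @param C unexplained-variance fraction, default 0.25.
#' @param form `"garrick"` (default) reads the expression as
#'   `C + (1 - r2)/r2`; `"pooled"` as `(C + 1 - r2)/r2`.
#' @return positive weight, decreasing in r2.
#' @export
residual_weight <- function(r2, C = 0.25, form = c("garrick", "pooled")) {
  form <- match.arg(form)
  if (any(r2 <= 0 | r2 > 1)) stop("reliability must be in (0, 1]")
  switch(form,
         garrick = C + (1 - r2) / r2,
         pooled = (C + 1 - r2) / r2)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum p (1 - p))` with `Z` the dosage matrix centred by
#' twice the allele frequencies. Frequencies are computed from the supplied
#' individuals unless given. Missing dosages are imputed to the marker mean
#' with a warning.
#'
#' @param geno dosage matrix, individuals x markers.
#' @param freq optional named allele-1 frequencies used for centring.
#' @return list: `G` (symmetric matrix), `freq` (frequencies used).
#' @export
build_grm <- function(geno, freq = NULL) {
  stopifnot(is.matrix(geno))
  if (anyNA(geno)) {
    warning("missing dosages imputed to marker means for GRM")
    mu <- colMeans(geno, na.rm = TRUE)
    idx <- which(is.na(geno), arr.ind = TRUE)
    geno[idx] <- mu[idx[, 2]]
  }
  if (is.null(freq)) freq <- colMeans(geno) / 2
  poly <- freq > 0 & freq < 1
  if (sum(poly) < 2) stop("fewer than 2 polymorphic markers")
  Z <- sweep(geno[, poly, drop = FALSE], 2, 2 * freq[poly])
  denom <- 2 * sum(freq[poly] * (1 - freq[poly]))
  G <- tcrossprod(Z) / denom
  list(G = G, freq = freq)
}

#' GBLUP with heterogeneous residual variances
#'
#' Solves the mixed model `y = 1 mu + g + e` with `Var(g) = G sigma_g^2`
#' and `Var(e) = diag(w) sigma_e^2` by the mixed-model equations; `y` are
#' the (deregressed) records of the training individuals and `g` is
#' predicted for every individual in `G`, including record-free selection
#' candidates, through their genomic relationships. `variance_ratio` is
#' `sigma_e^2 / sigma_g^2`. A small ridge is added to G before inversion
#' because a GRM built from finitely many markers can be singular.
#'
#' @param y named numeric records (names = individual ids, must be rows of
#'   `G`).
#' @param G genomic relationship matrix (from [build_grm()]), covering
#'   training individuals and prediction candidates.
#' @param weights residual weights per record (see [residual_weight()]);
#'   default 1.
#' @param variance_ratio residual-to-genetic variance ratio (> 0).
#' @param ridge ridge factor relative to the mean diagonal of G.
#' @return list: `dgv` (named vector over all individuals of `G`), `mu`
#'   (intercept estimate).
#' @export
fit_gblup <- function(y, G, weights = rep(1, length(y)), variance_ratio = 1,
                      ridge = 1e-6) {
  ids <- names(y)
  all_ids <- rownames(G)
  if (is.null(ids) || !all(ids %in% all_ids))
    stop("all record individuals must appear in G")
  stopifnot(variance_ratio > 0, all(weights > 0),
            length(weights) == length(y))
  n <- length(y); q <- length(all_ids)
  Z <- matrix(0, n, q, dimnames = list(ids, all_ids))
  Z[cbind(seq_len(n), match(ids, all_ids))] <- 1
  Gr <- G + diag(ridge * mean(diag(G)), q)
  Ginv <- tryCatch(solve(Gr), error = function(e)
    stop("G is singular even after ridge; condition: ", conditionMessage(e)))
  rinv <- 1 / weights
  # MME: [ 1'R-1 1   1'R-1 Z      ] [mu]   [1'R-1 y]
  #      [ Z'R-1 1   Z'R-1 Z + G-1 k ] [g ] = [Z'R-1 y]
  XtX <- sum(rinv)
  XtZ <- colSums(Z * rinv)
  ZtZ <- crossprod(Z * rinv, Z)
  lhs <- rbind(c(XtX, XtZ),
               cbind(XtZ, ZtZ + Ginv * variance_ratio))
  rhs <- c(sum(rinv * y), crossprod(Z * rinv, y))
  sol <- tryCatch(solve(lhs, rhs), error = function(e)
    stop("singular mixed-model equations; condition: ", conditionMessage(e)))
  dgv <- sol[-1]
  names(dgv) <- all_ids
  list(dgv = dgv, mu = unname(sol[1]))
}

#' Direct solve of the same mixed model via the phenotypic covariance
#'
#' Independent closed form used for cross-checking [fit_gblup()]:
#' `mu = (1' V^-1 1)^-1 1' V^-1 y` and `g = k_g G Z' V^-1 (y - 1 mu)` with
#' `V = Z G Z' + k R`. Not used by the estimation path.
#'
#' @inheritParams fit_gblup
#' @return list: `dgv`, `mu`.
#' @export
gblup_direct <- function(y, G, weights = rep(1, length(y)),
                         variance_ratio = 1, ridge = 1e-6) {
  ids <- names(y)
  all_ids <- rownames(G)
  n <- length(y); q <- length(all_ids)
  Z <- matrix(0, n, q, dimnames = list(ids, all_ids))
  Z[cbind(seq_len(n), match(ids, all_ids))] <- 1
  Gr <- G + diag(ridge * mean(diag(G)), q)
  V <- Z %*% Gr %*% t(Z) + variance_ratio * diag(weights, n)
  Vinv <- solve(V)
  one <- rep(1, n)
  mu <- drop(solve(t(one) %*% Vinv %*% one, t(one) %*% Vinv %*% y))
  g <- drop(Gr %*% t(Z) %*% Vinv %*% (y - mu))
  names(g) <- all_ids
  list(dgv = g, mu = mu)
}
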