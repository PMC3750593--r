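#' Mask a genotype matrix down to a low-density panel
#'
#' Sets every marker outside the panel to missing, mimicking candidates
#' genotyped only at the panel markers. The mask index (markers removed) is
#' returned for error scoring.
#'
#' @param geno dosage matrix, individuals x markers.
#' @param panel_ids marker ids retained.
#' @return list: `geno` (masked matrix), `mask` (masked marker ids).
#' @export
mask_panel <- function(geno, panel_ids) {
  if (!all(panel_ids %in% colnames(geno)))
    stop("panel markers absent from genotype matrix")
  mask <- setdiff(colnames(geno), panel_ids)
  geno[, mask] <- NA_integer_
  list(geno = geno, mask = mask)
}

#' Genotype imputation error rate
#'
#' Proportion of masked genotypes (0/1/2 scale) that were not restored
#' correctly, over cells where the truth is non-missing. Breakdowns by
#' position class (known vs estimated) and by chromosome are reported when
#' a map is supplied.
#'
#' @param truth,imputed dosage matrices with identical dimnames.
#' @param mask masked marker ids (from [mask_panel()]).
#' @param map optional marker map for the breakdowns.
#' @return list: `error_rate`, `n` (cells scored), `per_marker` (named
#'   rates), and optionally `by_position_class`, `by_chromosome`.
#' @export
imputation_error_rate <- function(truth, imputed, mask, map = NULL) {
  if (!length(mask)) stop("empty mask: no genotypes to score")
  tt <- truth[, mask, drop = FALSE]
  ii <- imputed[, mask, drop = FALSE]
  ok <- !is.na(tt)
  err <- ok & (is.na(ii) | ii != tt)
  out <- list(error_rate = sum(err) / sum(ok), n = sum(ok),
              per_marker = colSums(err) / colSums(ok))
  if (!is.null(map)) {
    mi <- match(mask, map$marker_id)
    cls <- ifelse(map$known[mi], "known", "estimated")
    out$by_position_class <- vapply(split(seq_along(mask), cls),
      function(j) sum(err[, j]) / sum(ok[, j]), numeric(1))
    out$by_chromosome <- vapply(split(seq_along(mask), map$chrom[mi]),
      function(j) sum(err[, j]) / sum(ok[, j]), numeric(1))
  }
  out
}

#' Imputation accuracy as coding-invariant squared correlation
#'
#' Squared Pearson correlation between true and imputed dosages over the
#' masked markers of each individual (or marker). To remove the dependence
#' on which allele is labelled 1, every marker enters twice: once as coded
#' and once with the coding swapped (`g -> 2 - g` in both vectors), making
#' the statistic exactly invariant to per-marker coding swaps.
#'
#' @param truth,imputed dosage matrices with identical dimnames.
#' @param mask masked marker ids.
#' @param per `"individual"` (default) or `"marker"`.
#' @return named numeric vector of squared correlations in `[0, 1]`; `NA`
#'   where the doubled vectors are constant or fewer than 2 masked
#'   genotypes are scorable.
#' @export
imputation_accuracy <- function(truth, imputed, mask,
                                per = c("individual", "marker")) {
  per <- match.arg(per)
  tt <- truth[, mask, drop = FALSE]
  ii <- imputed[, mask, drop = FALSE]
  if (per == "marker") { tt <- t(tt); ii <- t(ii) }
  vapply(seq_len(nrow(tt)), function(k) {
    x <- tt[k, ]; y <- ii[k, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    xd <- c(x[ok], 2 - x[ok])
    yd <- c(y[ok], 2 - y[ok])
    if (stats::sd(xd) == 0 || stats::sd(yd) == 0) return(NA_real_)
    stats::cor(xd, yd)^2
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(rownames(tt))
}

#' Naive DGV accuracy from the EBV correlation
#'
#' `cor(DGV, TBV) = cor(DGV, EBV) / cor(TBV, EBV)`, taking the mean EBV
#' accuracy of the validation set for `cor(TBV, EBV)`. Valid only when DGV
#' errors and EBV prediction errors are uncorrelated; with correlated
#' prediction errors (training and validation evaluated together) it is
#' biased upwards, which is what [fit_accuracy_regression()] corrects.
#' Estimates above 1 are returned as-is with a flag.
#'
#' @param cor_dgv_ebv observed correlation(s) between DGV and EBV.
#' @param r_val mean EBV accuracy of the validation set, in (0, 1].
#' @return data.frame: `estimate`, `flagged` (TRUE where estimate > 1).
#' @export
accuracy_eq1 <- function(cor_dgv_ebv, r_val) {
  if (any(r_val <= 0)) stop("validation accuracy must be positive")
  est <- cor_dgv_ebv / r_val
  data.frame(estimate = est, flagged = est > 1)
}

#' Regression-based correction of cross-validation DGV accuracies
#'
#' Fits `cor(DGV, EBV)_t = a0 + a1 * r_val_t + a2 * r_train_t + e_t` by
#' ordinary least squares across traits. As the validation EBV accuracy
#' approaches 1 the EBV approach the true breeding values, so the fitted
#' value at `r_val = 1` estimates the expected DGV accuracy of a random
#' trait, `a0 + a1 + a2 * r_train`. Adding back the trait residual gives
#' the per-trait estimate `cor(DGV, EBV)_t - a1 * (r_val_t - 1)`. In
#' single-trait mode (replicates of one trait with varying validation
#' accuracy) the `a2` term is dropped.
#'
#' @param cor_t per-trait (or per-replicate) observed cor(DGV, EBV).
#' @param r_val_t per-trait mean validation EBV accuracy.
#' @param r_train_t per-trait mean training EBV accuracy (ignored in
#'   single-trait mode).
#' @param mode `"multi"` (default) or `"single"`.
#' @return object of class `accuracy_fit`: coefficients `a0`, `a1`, `a2`
#'   (NA in single mode), `residuals`, `cor_t`, `r_val_t`, `r_train_t`,
#'   `acc_random` (accuracy of a random trait at the mean `r_train`),
#'   `acc_t` (per-trait corrected accuracies), `lm` (the underlying fit).
#' @export
fit_accuracy_regression <- function(cor_t, r_val_t, r_train_t = NULL,
                                    mode = c("multi", "single")) {
  mode <- match.arg(mode)
  n <- length(cor_t)
  stopifnot(length(r_val_t) == n)
  if (mode == "multi") {
    if (is.null(r_train_t) || length(r_train_t) != n)
      stop("multi-trait mode needs r_train_t")
    if (n < 4) stop("multi-trait mode needs >= 4 traits")
    dat <- data.frame(cor_t = cor_t, r_val = r_val_t, r_train = r_train_t)
    fit <- stats::lm(cor_t ~ r_val + r_train, data = dat)
    if (anyNA(stats::coef(fit)))
      stop("collinear predictors: r_val and r_train do not vary ",
           "independently across traits")
    cf <- stats::coef(fit)
    a0 <- cf[[1]]; a1 <- cf[[2]]; a2 <- cf[[3]]
    acc_random <- a0 + a1 + a2 * mean(r_train_t)
  } else {
    if (n < 3) stop("single-trait mode needs >= 3 replicates")
    dat <- data.frame(cor_t = cor_t, r_val = r_val_t)
    fit <- stats::lm(cor_t ~ r_val, data = dat)
    if (anyNA(stats::coef(fit)))
      stop("collinear predictors: r_val constant across replicates")
    cf <- stats::coef(fit)
    a0 <- cf[[1]]; a1 <- cf[[2]]; a2 <- NA_real_
    acc_random <- a0 + a1
  }
  structure(list(a0 = a0, a1 = a1, a2 = a2,
                 residuals = unname(stats::residuals(fit)),
                 cor_t = cor_t, r_val_t = r_val_t, r_train_t = r_train_t,
                 acc_random = acc_random,
                 acc_t = cor_t - a1 * (r_val_t - 1),
                 lm = fit),
            class = "accuracy_fit")
}

#' @export
print.accuracy_fit <- function(x, ...) {
  cat("<accuracy_fit>  a0 =", signif(x$a0, 4), " a1 =", signif(x$a1, 4),
      " a2 =", signif(x$a2, 4), "\n")
  cat("accuracy of a random trait:", signif(x$acc_random, 4), "\n")
  invisible(x)
}

#' Mean EBV accuracy of a set of individuals
#'
#' Accuracy is the square root of the reliability; the set mean can be
#' taken over accuracies (default, matching how trait tables report them)
#' or over reliabilities before the square root.
#'
#' @param r2 reliabilities of the set.
#' @param average `"accuracy"` or `"reliability"`.
#' @return scalar mean accuracy.
#' @export
mean_accuracy <- function(r2, average = c("accuracy", "reliability")) {
  average <- match.arg(average)
  switch(average,
         accuracy = mean(sqrt(r2)),
         reliability = sqrt(mean(r2)))
}
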