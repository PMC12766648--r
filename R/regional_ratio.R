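#' Detection-sensitivity curve over alternate allele fraction
#'
#' Variant-discovery pipelines detect low-AAF mosaics with reduced
#' sensitivity, so raw regional counts must be divided by the sensitivity
#' at each variant's AAF before regions are compared.  `sensitivity_curve`
#' smooths a table of (AAF, sensitivity) pairs with a spline, then clamps
#' the result to (0, 1] and enforces monotonicity; the packaged
#' [default_sensitivity_curve()] is a logistic curve in log-AAF anchored so
#' that sensitivity is essentially 1 above 10% AAF.  It is a placeholder
#' shape, not a published calibration, and should be replaced with
#' pipeline-specific estimates when available.
#'
#' @param aaf,sens Numeric vectors of AAFs (fractions) and sensitivities.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()].
#' @return An object of class `sensitivity_curve`; call it like a function
#'   or use `predict()`.
#' @export
sensitivity_curve <- function(aaf, sens, spar = 0.5) {
  stopifnot(length(aaf) == length(sens), all(sens >= 0), all(sens <= 1))
  if (length(unique(aaf)) >= 4) {
    fit <- stats::smooth.spline(aaf, sens, spar = spar)
    grid <- seq(min(aaf), max(aaf), length.out = 512)
    vals <- stats::predict(fit, grid)$y
  } else {
    grid <- aaf[order(aaf)]
    vals <- sens[order(aaf)]
  }
  vals <- pmin(pmax(cummax(vals), 1e-6), 1)
  f <- stats::approxfun(grid, vals, rule = 2)
  structure(list(fun = f, table = data.frame(aaf = aaf, sens = sens),
                 spar = spar),
            class = "sensitivity_curve")
}

#' @rdname sensitivity_curve
#' @param steepness,midpoint Logistic slope (per log-AAF unit) and
#'   half-sensitivity AAF of the default curve.
#' @export
default_sensitivity_curve <- function(steepness = 3, midpoint = 0.02) {
  f <- function(a) {
    s <- stats::plogis(steepness * (log(pmax(a, 1e-8)) - log(midpoint)))
    pmin(pmax(s, 1e-6), 1)
  }
  structure(list(fun = f, table = NULL,
                 spar = NA, steepness = steepness, midpoint = midpoint),
            class = "sensitivity_curve")
}

#' @export
predict.sensitivity_curve <- function(object, aaf, ...) object$fun(aaf)

#' Constant sensitivity curve (mainly for tests and nulls)
#' @param value Sensitivity in (0, 1].
#' @export
flat_sensitivity_curve <- function(value = 1) {
  stopifnot(value > 0, value <= 1)
  structure(list(fun = function(a) rep(value, length(a)), table = NULL,
                 spar = NA), class = "sensitivity_curve")
}

#' Default AAF bins for regional ratio estimation
#'
#' Seven bins spanning (0, 0.5]: 1-2%, 2-3%, 3-4%, 4-5%, 5-10%, 10-20%
#' and 20-50% AAF.
#' @return Data frame with `lo`, `hi` (fractions) and `label`.
#' @export
default_aaf_bins <- function() {
  lo <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.10, 0.20)
  hi <- c(0.02, 0.03, 0.04, 0.05, 0.10, 0.20, 0.50)
  data.frame(lo = lo, hi = hi,
             label = sprintf("%g-%g%%", 100 * lo, 100 * hi),
             stringsAsFactors = FALSE)
}

## bin index of each AAF; bins are (lo, hi]
.bin_of <- function(aaf, bins) {
  idx <- rep(NA_integer_, length(aaf))
  for (b in seq_len(nrow(bins)))
    idx[aaf > bins$lo[b] & aaf <= bins$hi[b]] <- b
  idx
}

## variants long table -> wide per-variant AAF matrix (variants x regions)
.aaf_matrix <- function(variants) {
  stopifnot(all(c("variant", "region", "aaf") %in% names(variants)))
  if (any(variants$aaf > 0.5))
    warning("AAFs above 0.5 present (autosomal het mosaics should not ",
            "exceed 0.5); flagged but retained")
  tapply(variants$aaf, list(variants$variant, variants$region),
         mean, default = 0)
}

#' Per-bin minimum detection read threshold
#'
#' For every AAF bin, simulates for each member variant the number of
#' supporting reads in a shallow read model (binomial with
#' `read_model_n` trials at the variant's AAF) and takes the bin minimum
#' as the read count at which a variant of that bin is deemed detectable.
#' Variants are assigned to bins by their cross-region mean AAF.
#'
#' @param variants Long table with columns `variant`, `region`, `aaf`.
#' @param bins Bin table as from [default_aaf_bins()].
#' @param read_model_n Reads in the detection read model (default 250).
#' @param seed Optional RNG seed.
#' @return Data frame with `label`, `threshold` (NA for empty bins) and
#'   `n_variants`.
#' @export
bin_and_threshold <- function(variants, bins = default_aaf_bins(),
                              read_model_n = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amat <- .aaf_matrix(variants)
  mean_aaf <- rowMeans(amat)
  bin <- .bin_of(mean_aaf, bins)
  thr <- rep(NA_real_, nrow(bins))
  n <- integer(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    in_b <- which(bin == b)
    n[b] <- length(in_b)
    if (n[b])
      thr[b] <- min(stats::rbinom(n[b], read_model_n, mean_aaf[in_b]))
  }
  data.frame(label = bins$label, threshold = thr, n_variants = n,
             stringsAsFactors = FALSE)
}

#' Sensitivity-projected regional variant count
#'
#' Simulates, for every variant, the reads supporting it in `region`
#' (binomial, `read_model_n` trials at the regional AAF), retains variants
#' whose simulated reads strictly exceed their bin's threshold, and sums
#' `1/sensitivity(AAF)` over retained variants: the projected number of
#' variants of comparable AAF present in the region.
#'
#' @param variants Long table (`variant`, `region`, `aaf`).
#' @param region Region to project.
#' @param thresholds Result of [bin_and_threshold()].
#' @param curve A `sensitivity_curve`.
#' @param bins Bin table used for the thresholds.
#' @param read_model_n Reads in the detection read model.
#' @param seed Optional RNG seed.
#' @return List with `projected` (the sum), `retained` (count) and the
#'   per-variant table.
#' @export
project_counts <- function(variants, region, thresholds,
                           curve = default_sensitivity_curve(),
                           bins = default_aaf_bins(),
                           read_model_n = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amat <- .aaf_matrix(variants)
  stopifnot(region %in% colnames(amat))
  mean_aaf <- rowMeans(amat)
  bin <- .bin_of(mean_aaf, bins)
  aaf_r <- amat[, region]
  keep <- !is.na(bin) & !is.na(thresholds$threshold[bin])
  reads <- rep(0L, length(aaf_r))
  reads[keep] <- stats::rbinom(sum(keep), read_model_n, aaf_r[keep])
  retained <- keep & reads > thresholds$threshold[bin]
  sens <- predict(curve, aaf_r)
  if (any(retained & sens <= 0))
    stop("non-positive sensitivity at retained AAF for variant(s): ",
         paste(rownames(amat)[retained & sens <= 0], collapse = ", "))
  tab <- data.frame(variant = rownames(amat), aaf = aaf_r, bin = bin,
                    reads = reads, retained = retained,
                    weight = ifelse(retained, 1 / sens, 0),
                    stringsAsFactors = FALSE)
  list(projected = sum(tab$weight), retained = sum(retained), table = tab)
}

#' Regional sSNV-count ratio with Monte-Carlo confidence intervals
#'
#' Repeats the detection-threshold and sensitivity-projection simulation
#' `n_iter` times and forms, per AAF bin and overall, the ratio of
#' projected counts in `region_a` over `region_b`.  The uniform-mixing
#' null replaces every variant's regional AAFs by its mean AAF across all
#' tested regions before simulating, modelling a cortex with no regional
#' structure.  Significance of an observed excess is summarised by an
#' upper-tail empirical p value of the observed point ratio against the
#' null ratio distribution.
#'
#' @param variants Long table (`variant`, `region`, `aaf`).
#' @param region_a,region_b Numerator and denominator regions.
#' @param curve A `sensitivity_curve`.
#' @param bins AAF bin table.
#' @param n_iter Iterations (>= 100; default 1000).
#' @param ci_level Confidence level for the percentile intervals
#'   (default 0.95; the companion interval at 0.99 can be requested
#'   instead).
#' @param mode `"both"` (default) runs observed and null simulations;
#'   `"observed"` or `"null"` runs one arm.
#' @param read_model_n Reads in the detection read model.
#' @param seed RNG seed.
#' @return Object of class `ratio_estimate`: a data frame with one row per
#'   bin plus an `all` row, columns for observed and null median ratios,
#'   percentile CI bounds, empirical p, and undefined-iteration counts.
#' @export
estimate_ratio_ci <- function(variants, region_a, region_b,
                              curve = default_sensitivity_curve(),
                              bins = default_aaf_bins(),
                              n_iter = 1000, ci_level = 0.95,
                              mode = c("both", "observed", "null"),
                              read_model_n = 250, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_iter >= 100)
  set.seed(seed)
  amat <- .aaf_matrix(variants)
  stopifnot(region_a %in% colnames(amat), region_b %in% colnames(amat))

  run_arm <- function(aaf_a, aaf_b, mean_aaf) {
    bin <- .bin_of(mean_aaf, bins)
    labs <- c(bins$label, "all")
    sums_a <- matrix(0, n_iter, length(labs),
                     dimnames = list(NULL, labs))
    sums_b <- sums_a
    sens_a <- predict(curve, aaf_a)
    sens_b <- predict(curve, aaf_b)
    if (any(sens_a <= 0) || any(sens_b <= 0))
      stop("non-positive sensitivity encountered")
    nv <- length(mean_aaf)
    for (it in seq_len(n_iter)) {
      thr <- rep(NA_real_, nrow(bins))
      for (b in seq_len(nrow(bins))) {
        in_b <- which(bin == b)
        if (length(in_b))
          thr[b] <- min(stats::rbinom(length(in_b), read_model_n,
                                      mean_aaf[in_b]))
      }
      ok <- !is.na(bin) & !is.na(thr[bin])
      ra <- rb <- rep(-1L, nv)
      ra[ok] <- stats::rbinom(sum(ok), read_model_n, aaf_a[ok])
      rb[ok] <- stats::rbinom(sum(ok), read_model_n, aaf_b[ok])
      keep_a <- ok & ra > thr[bin]
      keep_b <- ok & rb > thr[bin]
      wa <- ifelse(keep_a, 1 / sens_a, 0)
      wb <- ifelse(keep_b, 1 / sens_b, 0)
      for (b in seq_len(nrow(bins))) {
        in_b <- which(bin == b)
        sums_a[it, b] <- sum(wa[in_b])
        sums_b[it, b] <- sum(wb[in_b])
      }
      sums_a[it, "all"] <- sum(wa)
      sums_b[it, "all"] <- sum(wb)
    }
    list(ratio = ifelse(sums_b > 0, sums_a / sums_b, NA_real_))
  }

  mean_aaf <- rowMeans(amat)
  probs <- c((1 - ci_level) / 2, 0.5, (1 + ci_level) / 2)
  summarise <- function(rmat) {
    t(apply(rmat, 2, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) return(c(NA, NA, NA, 0))
      c(stats::quantile(r, probs, names = FALSE), length(r))
    }))
  }

  obs <- nul <- NULL
  if (mode %in% c("both", "observed"))
    obs <- run_arm(amat[, region_a], amat[, region_b], mean_aaf)
  if (mode %in% c("both", "null"))
    nul <- run_arm(mean_aaf, mean_aaf, mean_aaf)

  labs <- c(bins$label, "all")
  out <- data.frame(bin = labs, stringsAsFactors = FALSE)
  if (!is.null(obs)) {
    s <- summarise(obs$ratio)
    out$observed_lo <- s[, 1]; out$observed <- s[, 2]
    out$observed_hi <- s[, 3]; out$observed_n_defined <- s[, 4]
  }
  if (!is.null(nul)) {
    s <- summarise(nul$ratio)
    out$expected_lo <- s[, 1]; out$expected <- s[, 2]
    out$expected_hi <- s[, 3]; out$expected_n_defined <- s[, 4]
  }
  if (!is.null(obs) && !is.null(nul)) {
    out$p_empirical <- vapply(seq_along(labs), function(i) {
      r0 <- nul$ratio[, i]; r0 <- r0[!is.na(r0)]
      pt <- out$observed[i]
      if (!length(r0) || is.na(pt)) return(NA_real_)
      (1 + sum(r0 >= pt)) / (length(r0) + 1)
    }, numeric(1))
    out$significant <- !is.na(out$p_empirical) & out$p_empirical < 0.05
  }
  structure(out, n_iter = n_iter, ci_level = ci_level,
            regions = c(region_a, region_b),
            class = c("ratio_estimate", "data.frame"))
}
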