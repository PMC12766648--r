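#' Mosaic fraction from alternate allele fraction
#'
#' A heterozygous somatic variant carried by a fraction `f` of cells puts
#' its alternate allele on half the sampled chromosomes, so the mosaic
#' (cell) fraction is twice the alternate allele fraction.
#'
#' @param aaf Alternate allele fraction(s); any scale (fraction or
#'   percent) -- the result is on the same scale.
#' @return `2 * aaf`.
#' @export
mf_from_aaf <- function(aaf) 2 * aaf

#' Cells represented by a DNA input mass
#'
#' @param input_ng DNA input in nanograms (default 50).
#' @param pg_per_cell DNA content per diploid cell in picograms.
#' @return Whole number of cell equivalents (floor).
#' @export
cells_from_dna_input <- function(input_ng = 50, pg_per_cell = 6.5) {
  stopifnot(input_ng > 0, pg_per_cell > 0)
  floor(input_ng * 1000 / pg_per_cell)
}

#' Mosaic fraction and background error from replicate amplicons
#'
#' Per variant and region, averages the per-primer alternate allele
#' fractions (MF percent = 200 x mean AAF) and the flanking-position error
#' rates; primers with zero total reads are excluded with a warning.  The
#' site read depth is the summed depth across replicate primers (equal to
#' the single primer's depth when only one was designed).
#'
#' @param readouts Amplicon table with columns `variant`, `region`,
#'   `primer`, `depth`, `alt_reads` and optionally `flank_error` (mean
#'   flanking AAF).
#' @return Data frame of class `mosaic_estimates`: one row per
#'   variant/region with `n_primers`, `mean_aaf`, `mf_pct`,
#'   `bg_error_rate` (AAF scale), `bg_error_mf_pct` and `reads`.
#' @export
estimate_mf_and_error <- function(readouts) {
  need <- c("variant", "region", "primer", "depth", "alt_reads")
  stopifnot(all(need %in% names(readouts)))
  bad <- readouts$depth <= 0
  if (any(bad)) {
    warning(sum(bad), " primer(s) with zero total reads excluded")
    readouts <- readouts[!bad, , drop = FALSE]
  }
  if (!nrow(readouts)) stop("no usable primers")
  readouts$aaf <- readouts$alt_reads / readouts$depth
  if (is.null(readouts$flank_error)) readouts$flank_error <- NA_real_
  sp <- split(readouts, paste(readouts$variant, readouts$region, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(variant = d$variant[1], region = d$region[1],
               n_primers = nrow(d),
               mean_aaf = mean(d$aaf),
               mf_pct = 200 * mean(d$aaf),
               bg_error_rate = mean(d$flank_error),
               reads = sum(d$depth),
               stringsAsFactors = FALSE)
  }))
  out$bg_error_mf_pct <- 200 * out$bg_error_rate
  rownames(out) <- NULL
  class(out) <- c("mosaic_estimates", "data.frame")
  out
}

#' Classify regional detection status of amplicon-estimated variants
#'
#' A site is `inconclusive` below the minimum read depth, `detected` when
#' it reaches the depth, carries the expected alternate allele and its MF
#' clears the detection floor, and `absent` otherwise.
#'
#' @param estimates A `mosaic_estimates` table (or any table with
#'   `variant`, `region`, `reads`, `mf_pct`).
#' @param alt_matches Logical vector (recycled): observed alternate allele
#'   equals the one called in discovery (default `TRUE`).
#' @param min_reads Minimum site depth (default 10000).
#' @param mf_floor_pct Detection floor in MF percent (default 0.1,
#'   i.e. 0.05% AAF).
#' @return Input with a `status` factor column
#'   (`detected`/`absent`/`inconclusive`).
#' @export
classify_detection <- function(estimates, alt_matches = TRUE,
                               min_reads = 10000, mf_floor_pct = 0.1) {
  stopifnot(all(c("reads", "mf_pct") %in% names(estimates)))
  alt_matches <- rep_len(alt_matches, nrow(estimates))
  status <- ifelse(
    estimates$reads < min_reads, "inconclusive",
    ifelse(alt_matches & estimates$mf_pct >= mf_floor_pct,
           "detected", "absent"))
  estimates$status <- factor(status,
                             levels = c("detected", "absent", "inconclusive"))
  estimates
}

#' Mosaicism category of a variant
#'
#' Germline when the average AAF is at least 45%; otherwise ultra-low
#' (MF <= 2%), low (2-10%] or higher (10-90%] mosaic by the average MF,
#' with boundaries closed on the lower category.
#'
#' @param mean_mf_pct Average mosaic fraction, percent.
#' @param mean_aaf_pct Average alternate allele fraction, percent
#'   (defaults to `mean_mf_pct / 2`).
#' @return Factor with levels `ultra-low`, `low`, `higher`, `germline`.
#' @export
classify_category <- function(mean_mf_pct, mean_aaf_pct = mean_mf_pct / 2) {
  stopifnot(all(is.finite(mean_mf_pct)), all(is.finite(mean_aaf_pct)))
  if (any(mean_mf_pct < 0) || any(mean_aaf_pct < 0))
    stop("negative mosaic or allele fraction")
  out <- ifelse(mean_aaf_pct >= 45, "germline",
         ifelse(mean_mf_pct <= 2, "ultra-low",
         ifelse(mean_mf_pct <= 10, "low",
         ifelse(mean_mf_pct <= 90, "higher", "germline"))))
  factor(out, levels = c("ultra-low", "low", "higher", "germline"))
}

#' Expected number of regions under the uniform-mixing null
#'
#' Simulates the deep-amplicon experiment for a variant uniformly mixed
#' across the cortex: per replicate and region, mutant reads are binomial
#' from `reads` trials at the read fraction implied by the cortex-wide
#' average MF, error reads binomial at the average background error rate,
#' and the variant is "detected" in the region when mutant reads exceed
#' error reads and the mutant fraction clears the detection floor.
#'
#' The printed floor ("0.1%") is interpreted on the MF scale (mutant read
#' fraction > 0.05%, i.e. more than `reads/2000` mutant reads); set
#' `floor_scale = "aaf"` for the literal read-fraction reading.
#'
#' @param mean_mf_pct Cortex-wide average MF, percent.
#' @param mean_error_rate Average background error rate on the allele
#'   fraction scale (a fraction, e.g. 5e-4).
#' @param n_regions Number of candidate regions.
#' @param n_reps Replicates (>= 100; default 1000).
#' @param reads Theoretical reads per region (default 10000).
#' @param mf_floor_pct Detection floor in MF percent (default 0.1).
#' @param floor_scale `"mf"` (default) or `"aaf"`.
#' @param seed Optional RNG seed.
#' @return List with `expected` (mean detected-region count), `range`
#'   (min-max envelope) and `counts` (per-replicate counts).
#' @export
expected_regions_null <- function(mean_mf_pct, mean_error_rate = 0,
                                  n_regions, n_reps = 1000, reads = 10000,
                                  mf_floor_pct = 0.1,
                                  floor_scale = c("mf", "aaf"),
                                  seed = NULL) {
  floor_scale <- match.arg(floor_scale)
  stopifnot(n_reps >= 100, n_regions >= 1)
  if (mean_mf_pct > 100) stop("mosaic fraction above 100%")
  if (!is.null(seed)) set.seed(seed)
  p_mut <- mean_mf_pct / 200          # reads sample alleles, not cells
  floor_frac <- if (floor_scale == "mf") mf_floor_pct / 200 else
    mf_floor_pct / 100
  n <- n_reps * n_regions
  mut <- stats::rbinom(n, reads, p_mut)
  err <- stats::rbinom(n, reads, mean_error_rate)
  det <- mut > err & mut / reads > floor_frac
  counts <- rowSums(matrix(det, n_reps, n_regions))
  list(expected = mean(counts), range = range(counts), counts = counts)
}

#' Poisson test for regional restriction
#'
#' Tests whether each variant occupies fewer regions than its
#' uniform-mixing expectation: lower-tail Poisson probability
#' `P(K <= observed)` at rate equal to the simulated expected count, with
#' Benjamini-Hochberg adjustment across the variant family (one-sided,
#' fewer-than-expected direction).
#'
#' @param tests Data frame with columns `variant`, `observed_count`,
#'   `expected_count`; optionally `n_regions` for validation.
#' @return Input with `p` and `q` columns, class `restriction_tests`.
#' @export
region_restriction_test <- function(tests) {
  stopifnot(all(c("variant", "observed_count", "expected_count") %in%
                  names(tests)))
  if (!is.null(tests$n_regions) &&
      any(tests$observed_count > tests$n_regions))
    stop("observed region count exceeds the number of regions")
  if (any(tests$expected_count < 0)) stop("negative expected count")
  tests$p <- stats::ppois(tests$observed_count, tests$expected_count)
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  class(tests) <- c("restriction_tests", "data.frame")
  tests
}

#' Tukey-style outlier flags for mosaic fractions
#'
#' Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7).  Mild outliers lie strictly beyond 1.5
#' IQRs from the quartiles but within 3; extreme outliers strictly beyond
#' 3 IQRs.
#'
#' @param values Numeric vector (>= 4 values).
#' @return Factor of flags `none`/`mild`/`extreme`, one per value.
#' @export
flag_outliers <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo_m <- q[1] - 1.5 * iqr; lo_x <- q[1] - 3 * iqr
  hi_m <- q[2] + 1.5 * iqr; hi_x <- q[2] + 3 * iqr
  out <- ifelse(values < lo_x | values > hi_x, "extreme",
         ifelse(values < lo_m | values > hi_m, "mild", "none"))
  factor(out, levels = c("none", "mild", "extreme"))
}
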