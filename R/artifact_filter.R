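#' Single-base-substitution records with sequence context
#'
#' Builds the record table used by the position-weight-matrix artifact
#' filter: one row per substitution with its 41-base reference window
#' centred on the mutated position.  Purine-reference records (A>*, G>*)
#' are reverse-complemented into the pyrimidine frame so that, e.g., A>C
#' and T>G calls pool into one substitution class.
#'
#' @param chrom,pos,ref,alt Vectors describing the substitutions.
#' @param window Character vector of 41-base uppercase windows (characters
#'   outside ACGT are treated as masked).
#' @param source Source label, e.g. `"test"` or `"control"`.
#' @param normalize_strand Reverse-complement purine-reference records.
#' @return Data frame of class `sbs_records` with a `sbs_class` column
#'   (`"<ref>><alt>"` after strand normalisation).
#' @export
sbs_records <- function(chrom, pos, ref, alt, window, source,
                        normalize_strand = TRUE) {
  window <- toupper(window)
  if (any(nchar(window) != 41))
    stop("every window must be exactly 41 bases")
  ref <- toupper(ref); alt <- toupper(alt)
  mid <- substr(window, 21, 21)
  if (any(mid != ref & mid %in% c("A", "C", "G", "T")))
    stop("window center must equal the reference base")
  if (normalize_strand) {
    flip <- ref %in% c("A", "G")
    if (any(flip)) {
      window[flip] <- revcomp(window[flip])
      ref[flip] <- revcomp(ref[flip])
      alt[flip] <- revcomp(alt[flip])
    }
  }
  structure(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               window = window, source = source,
               sbs_class = paste0(ref, ">", alt),
               stringsAsFactors = FALSE),
    class = c("sbs_records", "data.frame"))
}

#' Reverse complement of ACGT strings (non-ACGT characters preserved as N)
#' @param x Character vector.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    out <- comp[ch]
    out[is.na(out)] <- "N"
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a position weight matrix from substitution windows
#'
#' Column j of the PWM is the pseudocount-smoothed base distribution at
#' window position j over all records of the substitution class; masked
#' (non-ACGT) characters are excluded from that column's counts.
#'
#' @param records An `sbs_records` table.
#' @param sbs_class Substitution class to select (`NULL` uses all rows).
#' @param pseudocount Added to each base count per column (default 0.5).
#' @return Object of class `pwm`: probability matrix (4 x 41, rows ACGT),
#'   the pseudocount, class and source labels, and record count.
#' @export
build_pwm <- function(records, sbs_class = NULL, pseudocount = 0.5) {
  if (!is.null(sbs_class))
    records <- records[records$sbs_class == sbs_class, , drop = FALSE]
  if (!nrow(records)) stop("no records for PWM construction")
  bases <- c("A", "C", "G", "T")
  chars <- do.call(rbind, strsplit(records$window, "", fixed = TRUE))
  counts <- matrix(0, 4, 41, dimnames = list(bases, NULL))
  for (j in 1:41)
    counts[, j] <- table(factor(chars[, j], levels = bases))
  n_eff <- colSums(counts)
  mat <- sweep(counts + pseudocount, 2, n_eff + 4 * pseudocount, "/")
  structure(list(prob = mat, counts = counts, n_eff = n_eff,
                 pseudocount = pseudocount,
                 sbs_class = if (is.null(sbs_class))
                   paste(unique(records$sbs_class), collapse = ",")
                 else sbs_class,
                 source = paste(unique(records$source), collapse = ","),
                 n = nrow(records)),
            class = "pwm")
}

#' Joint multinomial log likelihood ratio over the central window
#'
#' Scores each record's bases in a `2*window_half_width + 1` window
#' centred on the substitution under the test versus the control PWM:
#' `sum(log p_test(base) - log p_control(base))`.  Masked characters are
#' skipped in the sum.
#'
#' @param records `sbs_records` table (or a character vector of windows).
#' @param test_pwm,control_pwm `pwm` objects aligned to the same center.
#' @param window_half_width Default 4 (9-base window).
#' @return Numeric vector of log likelihood ratios.
#' @export
window_loglik_ratio <- function(records, test_pwm, control_pwm,
                                window_half_width = 4) {
  windows <- if (is.character(records)) records else records$window
  cols <- (21 - window_half_width):(21 + window_half_width)
  bases <- c("A", "C", "G", "T")
  vapply(windows, function(w) {
    ch <- strsplit(w, "", fixed = TRUE)[[1]][cols]
    keep <- ch %in% bases
    if (!any(keep)) return(0)
    i <- match(ch[keep], bases)
    j <- cols[keep]
    pt <- test_pwm$prob[cbind(i, j)]
    pc <- control_pwm$prob[cbind(i, j)]
    if (any(pt == 0) || any(pc == 0))
      stop("zero PWM probability; use a positive pseudocount")
    sum(log(pt) - log(pc))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Empirical-p artifact filtering of substitution calls
#'
#' For each substitution class present in the test set, builds a test PWM
#' (from the test records) and a control PWM (from control records of the
#' same class), scores every record's central window log likelihood ratio,
#' and computes for each test record an empirical p value against the
#' control records' ratio distribution:
#' `p = (1 + #{control LR >= observed LR}) / (n_control + 1)`.
#' Test records with `p < alpha` are deemed platform artifacts and removed.
#'
#' Every record is scored out-of-sample with respect to the PWM it
#' contributed to (its own base counts are removed from the columns
#' before computing its likelihood); without this leave-one-out
#' correction the empirical p values are anti-conservative for small
#' record sets, because each record inflates its own likelihood under
#' "its" PWM.  The correction vanishes as the record sets grow.
#'
#' @param test_records,control_records `sbs_records` tables.
#' @param alpha Removal threshold on the empirical p (default 0.05).
#' @param window_half_width Scoring half-width (default 4).
#' @param pseudocount PWM pseudocount (default 0.5).
#' @return List with `kept`, `removed` (both `sbs_records` with `log_lr`
#'   and `p` columns) and the per-class summary `summary`.
#' @export
filter_by_empirical_p <- function(test_records, control_records,
                                  alpha = 0.05, window_half_width = 4,
                                  pseudocount = 0.5) {
  stopifnot(nrow(test_records) > 0, nrow(control_records) > 0)
  test_records$log_lr <- NA_real_
  test_records$p <- NA_real_
  summary <- NULL
  for (cls in unique(test_records$sbs_class)) {
    ti <- which(test_records$sbs_class == cls)
    ci <- which(control_records$sbs_class == cls)
    if (!length(ci)) {
      warning("no control records for class ", cls, "; class kept as-is")
      test_records$p[ti] <- 1
      next
    }
    if (length(ci) < 20)
      warning("only ", length(ci), " control records for class ", cls,
              "; empirical p resolution is coarse")
    tp <- build_pwm(test_records[ti, ], pseudocount = pseudocount)
    cp <- build_pwm(control_records[ci, ], pseudocount = pseudocount)
    lr_t <- .pwm_loglik(test_records$window[ti], tp, window_half_width,
                        exclude_self = TRUE) -
      .pwm_loglik(test_records$window[ti], cp, window_half_width)
    lr_c <- .pwm_loglik(control_records$window[ci], tp,
                        window_half_width) -
      .pwm_loglik(control_records$window[ci], cp, window_half_width,
                  exclude_self = TRUE)
    p <- vapply(lr_t, function(x) (1 + sum(lr_c >= x)) / (length(lr_c) + 1),
                numeric(1))
    test_records$log_lr[ti] <- lr_t
    test_records$p[ti] <- p
    summary <- rbind(summary, data.frame(
      sbs_class = cls, n_test = length(ti), n_control = length(ci),
      n_removed = sum(p < alpha), stringsAsFactors = FALSE))
  }
  removed <- test_records$p < alpha
  list(kept = test_records[!removed, , drop = FALSE],
       removed = test_records[removed, , drop = FALSE],
       summary = summary)
}

## log multinomial likelihood of each window's central bases under a PWM,
## optionally removing the window's own counts (leave-one-out)
.pwm_loglik <- function(windows, pwm, window_half_width = 4,
                        exclude_self = FALSE) {
  cols <- (21 - window_half_width):(21 + window_half_width)
  bases <- c("A", "C", "G", "T")
  pc <- pwm$pseudocount
  vapply(windows, function(w) {
    ch <- strsplit(w, "", fixed = TRUE)[[1]][cols]
    keep <- ch %in% bases
    if (!any(keep)) return(0)
    i <- match(ch[keep], bases)
    j <- cols[keep]
    cnt <- pwm$counts[cbind(i, j)]
    n <- pwm$n_eff[j]
    if (exclude_self) {
      cnt <- cnt - 1
      n <- n - 1
    }
    p <- (cnt + pc) / (n + 4 * pc)
    if (any(p <= 0))
      stop("zero PWM probability; use a positive pseudocount")
    sum(log(p))
  }, numeric(1), USE.NAMES = FALSE)
}
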