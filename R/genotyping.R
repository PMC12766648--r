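#' Fit single-cell genotyping parameters from control sites
#'
#' The two binomial parameters of the genotyping model are estimated from
#' controls carried on the panel: the expected mutant-read fraction in a
#' carrier cell (`p_mut`, ideally 0.5 but shifted by amplification allele
#' imbalance) from heterozygous germline SNPs, and the per-read
#' non-reference error rate (`error_rate`) from reference-homozygous
#' sites (e.g. off-target amplifications).
#'
#' @param het_alt,het_total Alternate and total read counts at
#'   heterozygous control SNPs (vectors over observations).
#' @param refhom_nonref,refhom_total Non-reference and total read counts
#'   at reference-homozygous control sites.
#' @return Object of class `genotyping_params`: `p_mut`, `error_rate` and
#'   their binomial standard errors.
#' @export
fit_genotyping_params <- function(het_alt, het_total,
                                  refhom_nonref, refhom_total) {
  stopifnot(length(het_alt) == length(het_total),
            length(refhom_nonref) == length(refhom_total))
  if (length(het_alt) < 10 || length(refhom_nonref) < 10)
    warning("fewer than 10 control observations of a kind; ",
            "parameter estimates will be unstable")
  if (sum(het_total) == 0 || sum(refhom_total) == 0)
    stop("degenerate controls: zero total depth")
  p_mut <- sum(het_alt) / sum(het_total)
  error_rate <- sum(refhom_nonref) / sum(refhom_total)
  if (!(error_rate < p_mut))
    stop("estimated error rate is not below the carrier read fraction")
  structure(list(
    p_mut = p_mut,
    error_rate = max(error_rate, 1e-6),
    p_mut_se = sqrt(p_mut * (1 - p_mut) / sum(het_total)),
    error_rate_se = sqrt(error_rate * (1 - error_rate) / sum(refhom_total)),
    n_het = length(het_alt), n_refhom = length(refhom_nonref)),
    class = "genotyping_params")
}

#' @export
print.genotyping_params <- function(x, ...) {
  cat(sprintf("genotyping_params: p_mut = %.4f (se %.1g), error_rate = %.2g (se %.1g)\n",
              x$p_mut, x$p_mut_se, x$error_rate, x$error_rate_se))
  invisible(x)
}

#' Posterior probability that a cell carries a variant
#'
#' Two-component binomial model: with prior carrier probability `pi`
#' (the site prior), the posterior is
#' `pi * Binom(a; d, p_mut) / [pi * Binom(a; d, p_mut) +
#' (1 - pi) * Binom(a; d, error_rate)]`.  Cells with zero depth carry no
#' information and return the prior.
#'
#' @param alt_reads,total_reads Read counts (vectors).
#' @param params A [fit_genotyping_params()] result (or any list with
#'   `p_mut` and `error_rate`).
#' @param site_prior Prior carrier probability in (0, 1); recycled.
#' @return Numeric posterior vector; the attribute `no_data` flags
#'   zero-depth entries.
#' @export
posterior_genotype <- function(alt_reads, total_reads, params, site_prior) {
  stopifnot(all(alt_reads <= total_reads), all(alt_reads >= 0))
  site_prior <- rep_len(site_prior, length(alt_reads))
  stopifnot(all(site_prior > 0), all(site_prior < 1))
  l1 <- stats::dbinom(alt_reads, total_reads, params$p_mut, log = TRUE)
  l0 <- stats::dbinom(alt_reads, total_reads, params$error_rate, log = TRUE)
  log_odds <- log(site_prior) - log1p(-site_prior) + l1 - l0
  post <- stats::plogis(log_odds)
  post[total_reads == 0] <- site_prior[total_reads == 0]
  attr(post, "no_data") <- total_reads == 0
  post
}

#' Site prior from the pooled mutant-read fraction
#'
#' The prior carrier probability of a site is proportional to the mutant
#' read fraction pooled over all cells; for a heterozygous variant the
#' pooled AAF maps to a carrier fraction of twice its value, clamped away
#' from 0 and 1.
#'
#' @param alt_reads,total_reads Read counts per cell at the site.
#' @param floor,ceiling Clamping bounds.
#' @return Scalar prior in (0, 1).
#' @export
site_prior_from_reads <- function(alt_reads, total_reads,
                                  floor = 1e-3, ceiling = 1 - 1e-3) {
  d <- sum(total_reads)
  aaf <- if (d > 0) sum(alt_reads) / d else 0
  min(max(2 * aaf, floor), ceiling)
}

#' Genotype one batch of panel single-cell data
#'
#' Applies [posterior_genotype()] per site with the pooled-read site
#' prior, returning a long genotype table.
#'
#' @param batch Data frame with `cell`, `site`, `alt_reads`, `total_reads`
#'   (or `ref_reads`).
#' @param params `genotyping_params`.
#' @param call_threshold Posterior for a hard mutant call (default 0.9).
#' @return Data frame of class `genotype_calls` with `posterior`, `call`
#'   and `site_prior` columns.
#' @export
genotype_batch <- function(batch, params, call_threshold = 0.9) {
  if (is.null(batch$total_reads))
    batch$total_reads <- batch$ref_reads + batch$alt_reads
  stopifnot(all(c("cell", "site", "alt_reads", "total_reads") %in%
                  names(batch)))
  out <- do.call(rbind, lapply(split(batch, batch$site), function(d) {
    prior <- site_prior_from_reads(d$alt_reads, d$total_reads)
    d$site_prior <- prior
    d$posterior <- as.numeric(
      posterior_genotype(d$alt_reads, d$total_reads, params, prior))
    d
  }))
  out$call <- out$posterior >= call_threshold
  rownames(out) <- NULL
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Consensus genotypes across sequencing batches
#'
#' Combines per-batch binomial evidence multiplicatively under a shared
#' prior given by the variant's estimated mosaic (cell) fraction:
#' posterior odds = prior odds x likelihood ratios of all batches with
#' data.  Cells whose batches disagree with near-certainty (both
#' single-batch posteriors beyond 0.99 on opposite sides) are flagged
#' discordant and their call withheld.
#'
#' @param batches List of batch tables (`cell`, `site`, `alt_reads`,
#'   `total_reads`/`ref_reads`).
#' @param site_mfs Named vector: site -> mosaic cell fraction in [0, 1],
#'   used as the prior carrier probability (clamped to (1e-3, 1 - 1e-3);
#'   an MF of 0 forces posterior 0).
#' @param params A single `genotyping_params` or a list, one per batch.
#' @param call_threshold Posterior for a hard call (default 0.9).
#' @return Data frame of class `genotype_calls`: one row per cell x site
#'   with `posterior`, `call` (NA when discordant or MF prior 0 leaves no
#'   carrier), `discordant`, `n_batches` and total read support.
#' @export
consensus_matrix <- function(batches, site_mfs, params,
                             call_threshold = 0.9) {
  if (inherits(params, "genotyping_params") ||
      all(c("p_mut", "error_rate") %in% names(params)))
    params <- rep(list(params), length(batches))
  stopifnot(length(params) == length(batches))
  long <- do.call(rbind, lapply(seq_along(batches), function(b) {
    d <- batches[[b]]
    if (is.null(d$total_reads)) d$total_reads <- d$ref_reads + d$alt_reads
    d$batch <- b
    d[, c("cell", "site", "alt_reads", "total_reads", "batch")]
  }))
  stopifnot(all(long$site %in% names(site_mfs)))

  sp <- split(long, paste(long$cell, long$site, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(d) {
    mf <- unname(site_mfs[d$site[1]])
    if (mf <= 0)
      return(data.frame(cell = d$cell[1], site = d$site[1], posterior = 0,
                        call = FALSE, discordant = FALSE,
                        n_batches = nrow(d),
                        alt_reads = sum(d$alt_reads),
                        total_reads = sum(d$total_reads),
                        stringsAsFactors = FALSE))
    prior <- min(max(mf, 1e-3), 1 - 1e-3)
    lo <- log(prior) - log1p(-prior)
    per_batch <- numeric(nrow(d))
    for (i in seq_len(nrow(d))) {
      pr <- params[[d$batch[i]]]
      llr <- stats::dbinom(d$alt_reads[i], d$total_reads[i], pr$p_mut,
                           log = TRUE) -
        stats::dbinom(d$alt_reads[i], d$total_reads[i], pr$error_rate,
                      log = TRUE)
      lo <- lo + llr
      per_batch[i] <- stats::plogis(log(prior) - log1p(-prior) + llr)
    }
    post <- stats::plogis(lo)
    disc <- nrow(d) >= 2 && max(per_batch) > 0.99 && min(per_batch) < 0.01
    data.frame(cell = d$cell[1], site = d$site[1], posterior = post,
               call = if (disc) NA else post >= call_threshold,
               discordant = disc, n_batches = nrow(d),
               alt_reads = sum(d$alt_reads),
               total_reads = sum(d$total_reads),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Pivot long genotype calls into a cells-by-sites matrix
#'
#' @param calls A `genotype_calls` table.
#' @param value Column to spread (default `"posterior"`).
#' @return Numeric matrix, cells x sites.
#' @export
genotype_matrix <- function(calls, value = "posterior") {
  cells <- sort(unique(calls$cell))
  sites <- sort(unique(calls$site))
  m <- matrix(NA_real_, length(cells), length(sites),
              dimnames = list(cells, sites))
  m[cbind(match(calls$cell, cells), match(calls$site, sites))] <-
    as.numeric(calls[[value]])
  m
}
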