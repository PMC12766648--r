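#' Normalized shared-variant counts between cell-type pairs
#'
#' For each unordered pair of cell types (including self-pairs), counts
#' the sSNVs whose mutant allele is supported by at least
#' `min_cells_per_type` distinct cells of each type, and normalizes by the
#' number of cross-type cell pairs that share at least one mutant allele
#' (controlling for how many cells of the pair capture mutations at all).
#'
#' Cells with zero UMIs at a variant are non-informative; a cell supports
#' a variant when it has at least one mutant UMI.
#'
#' @param tally Long table: `cell`, `variant`, `total_umis`, `mut_umis`.
#' @param cell_types Named vector: cell -> cell type.
#' @param min_cells_per_type Default 2.
#' @return Data frame of class `shared_variant_stats`: `type_a`,
#'   `type_b`, `n_shared`, `n_pairs` (denominator), `normalized`, and the
#'   per-variant contribution table as attribute `"per_variant"`.
#' @export
shared_variant_counts <- function(tally, cell_types,
                                  min_cells_per_type = 2) {
  stopifnot(all(c("cell", "variant", "mut_umis") %in% names(tally)))
  mut <- tally[tally$mut_umis >= 1, , drop = FALSE]
  if (!nrow(mut))
    return(structure(data.frame(type_a = character(),
                                type_b = character(),
                                n_shared = integer(), n_pairs = integer(),
                                normalized = numeric()),
                     class = c("shared_variant_stats", "data.frame")))
  stopifnot(all(mut$cell %in% names(cell_types)))
  mut$type <- unname(cell_types[mut$cell])
  types <- sort(unique(unname(cell_types)))

  ## mutant cells per variant x type (distinct cells)
  mut <- unique(mut[, c("variant", "cell", "type")])
  tab <- table(mut$variant, factor(mut$type, levels = types))

  pairs <- expand.grid(a = seq_along(types), b = seq_along(types))
  pairs <- pairs[pairs$a <= pairs$b, ]
  per_variant <- list()
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    a <- types[pairs$a[k]]; b <- types[pairs$b[k]]
    qual <- if (a == b) tab[, a] >= min_cells_per_type else
      tab[, a] >= min_cells_per_type & tab[, b] >= min_cells_per_type
    ## denominator: cell pairs of this type pair sharing >= 1 mutant allele
    shared_any <- if (a == b) tab[, a] >= 1 else
      tab[, a] >= 1 & tab[, b] >= 1
    n_pairs <- if (a == b)
      sum(choose(tab[shared_any, a], 2)) else
      sum(tab[shared_any, a] * tab[shared_any, b])
    n_shared <- sum(qual)
    stopifnot(n_pairs > 0 || n_shared == 0)
    per_variant[[k]] <<- data.frame(
      type_a = rep(a, n_shared), type_b = rep(b, n_shared),
      variant = rownames(tab)[qual],
      contribution = rep(if (n_pairs > 0) 1 / n_pairs else NA_real_,
                         n_shared),
      stringsAsFactors = FALSE)
    data.frame(type_a = a, type_b = b, n_shared = n_shared,
               n_pairs = n_pairs,
               normalized = if (n_pairs > 0) n_shared / n_pairs else 0,
               stringsAsFactors = FALSE)
  }))
  attr(out, "per_variant") <- do.call(rbind, per_variant)
  class(out) <- c("shared_variant_stats", "data.frame")
  out
}

#' Bootstrap test comparing observed and expected shared-variant counts
#'
#' Tests whether sample-matched ("observed") sSNVs yield a larger
#' normalized shared count than sample-unmatched ("expected") control
#' sSNVs for a cell-type pair.  The null distribution is built by pooling
#' the per-sSNV normalized contributions of both sources and drawing
#' `n_boot` pairs of bootstrap resamples from the pool; the p value is
#' the upper-tail probability of the observed difference in means.
#'
#' @param observed,expected Numeric vectors of per-sSNV normalized
#'   contributions for the pair (e.g. from the `"per_variant"` attribute
#'   of [shared_variant_counts()]).
#' @param n_boot Bootstrap pairs (default 10000; < 1000 warns).
#' @param seed Optional RNG seed.
#' @return List: `p`, `difference` (observed mean - expected mean),
#'   `null_differences`.
#' @export
shared_count_test <- function(observed, expected, n_boot = 10000,
                              seed = NULL) {
  stopifnot(length(observed) > 0, length(expected) > 0)
  if (n_boot < 1000) warning("fewer than 1000 bootstrap pairs")
  if (!is.null(seed)) set.seed(seed)
  d_obs <- mean(observed) - mean(expected)
  pool <- c(observed, expected)
  n1 <- length(observed); n2 <- length(expected)
  null_d <- replicate(n_boot,
    mean(sample(pool, n1, replace = TRUE)) -
      mean(sample(pool, n2, replace = TRUE)))
  p <- (1 + sum(null_d >= d_obs)) / (n_boot + 1)
  list(p = p, difference = d_obs, null_differences = null_d)
}

#' Minimum mosaic fraction shared by two cell types, with bootstrap CI
#'
#' Under neutral growth the most recent variant in the common ancestor of
#' two cell types has the smallest mosaic fraction among their shared
#' variants, so the minimum shared MF estimates the MF at their
#' divergence.  Requires at least three shared sSNVs; the confidence
#' interval is the percentile interval of bootstrap minima.
#'
#' @param shared_mfs Mosaic fractions (percent) of the shared sSNVs.
#' @param n_boot Bootstrap samples (default 10000).
#' @param ci Confidence level (default 0.90).
#' @param seed Optional RNG seed.
#' @return Object of class `minmf_estimate`: `minmf`, `ci_lo`, `ci_hi`,
#'   `n`, `boot`.
#' @export
minmf_bootstrap <- function(shared_mfs, n_boot = 10000, ci = 0.90,
                            seed = NULL) {
  if (length(shared_mfs) < 3)
    stop("at least three shared sSNVs are required for a minMF estimate")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    min(sample(shared_mfs, length(shared_mfs), replace = TRUE)),
    numeric(1))
  qs <- stats::quantile(boot, c((1 - ci) / 2, (1 + ci) / 2), names = FALSE)
  structure(list(minmf = min(shared_mfs), ci_lo = qs[1], ci_hi = qs[2],
                 n = length(shared_mfs), boot = boot),
            class = "minmf_estimate")
}

#' @export
print.minmf_estimate <- function(x, ...) {
  cat(sprintf("minMF = %.3g%% (CI %.3g-%.3g) from %d shared sSNVs\n",
              x$minmf, x$ci_lo, x$ci_hi, x$n))
  invisible(x)
}

#' Group cells into clones by shared somatic variants
#'
#' Builds a weighted graph over mutant-bearing cells (edge weight = number
#' of variants shared by the two cells) and applies Louvain community
#' detection at the given resolution.  Cells sharing no variant with any
#' other cell form singleton clones.
#'
#' @param tally Long table: `cell`, `variant`, `mut_umis`.
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed (default 1; Louvain is seed-dependent).
#' @return Data frame `cell`, `clone` (integer labels).
#' @export
louvain_clones <- function(tally, resolution = 1, seed = 1L) {
  mut <- unique(tally[tally$mut_umis >= 1, c("cell", "variant")])
  stopifnot(nrow(mut) > 0)
  cells <- sort(unique(mut$cell))
  vars <- sort(unique(mut$variant))
  inc <- matrix(0L, length(cells), length(vars),
                dimnames = list(cells, vars))
  inc[cbind(match(mut$cell, cells), match(mut$variant, vars))] <- 1L
  adj <- tcrossprod(inc)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  data.frame(cell = cells,
             clone = as.integer(igraph::membership(comm)),
             stringsAsFactors = FALSE)
}

#' Empirical-Bayes clone cell-type composition
#'
#' Clone sizes span orders of magnitude, so raw per-clone cell-type
#' proportions are noisy for small clones.  For each focal cell-type
#' group the count `X` of group cells in a clone of size `N` is modelled
#' as beta-binomial; a beta-binomial regression of `(X, N - X)` on the
#' number of variants represented in the clone and on `log10(N)` yields a
#' per-clone prior mean `mu0` and a shared precision `sigma0`
#' (`alpha0 = mu0 * sigma0`, `beta0 = (1 - mu0) * sigma0`), and the
#' posterior proportion is `(alpha0 + X) / (sigma0 + N)` with a Beta
#' posterior interval.  Aggregate proportions are size-weighted means of
#' the per-clone posteriors with Monte-Carlo intervals.
#'
#' @param clones Data frame `cell`, `clone` (e.g. [louvain_clones()]).
#' @param cell_types Named vector: cell -> cell type.
#' @param tally Long tally used to count variants represented per clone.
#' @param groups Named list mapping focal group -> member cell types;
#'   default GluN (upper + other layer) and GABN (CGE + MGE).
#' @param min_clone_size Minimum clone size analysed (default 10).
#' @param ci Credible level for per-clone and aggregate intervals
#'   (default 0.95).
#' @param seed Seed for the aggregate Monte-Carlo interval.
#' @return List of class `clone_composition`: `per_clone` (clone, group,
#'   N, X, mu0, sigma0, posterior, lo, hi), `aggregate` (group, estimate,
#'   lo, hi), `converged` (regression diagnostics per group).
#' @export
eb_composition <- function(clones, cell_types, tally,
                           groups = list(
                             GluN = c("GluN_upper", "GluN_other"),
                             GABN = c("CGE_GABN", "MGE_GABN")),
                           min_clone_size = 10, ci = 0.95, seed = 1L) {
  stopifnot(all(clones$cell %in% names(cell_types)))
  clones$type <- unname(cell_types[clones$cell])
  size <- table(clones$clone)
  keep <- names(size)[size >= min_clone_size]
  if (length(keep) < 5)
    stop("need at least 5 clones of size >= ", min_clone_size,
         " for the empirical-Bayes regression")
  cl <- clones[clones$clone %in% keep, , drop = FALSE]

  mut <- unique(tally[tally$mut_umis >= 1, c("cell", "variant")])
  nvar <- vapply(keep, function(k) {
    cells_k <- cl$cell[cl$clone == k]
    length(unique(mut$variant[mut$cell %in% cells_k]))
  }, numeric(1))

  alpha <- (1 - ci) / 2
  per_clone <- NULL
  aggregate <- NULL
  converged <- list()
  set.seed(seed)
  for (g in names(groups)) {
    N <- as.numeric(size[keep])
    X <- vapply(keep, function(k)
      sum(cl$clone == k & cl$type %in% groups[[g]]), numeric(1))
    dat <- data.frame(X = X, N = N, nvar = nvar, logN = log10(N))
    fit <- .betabin_fit(dat)
    converged[[g]] <- fit$method
    mu0 <- fit$mu0
    sigma0 <- fit$sigma0
    a0 <- mu0 * sigma0; b0 <- (1 - mu0) * sigma0
    post <- (a0 + X) / (sigma0 + N)
    lo <- stats::qbeta(alpha, a0 + X, b0 + N - X)
    hi <- stats::qbeta(1 - alpha, a0 + X, b0 + N - X)
    per_clone <- rbind(per_clone, data.frame(
      clone = keep, group = g, N = N, X = X, n_variants = nvar,
      mu0 = mu0, sigma0 = sigma0, posterior = post, lo = lo, hi = hi,
      stringsAsFactors = FALSE))
    ## aggregate: size-weighted mean of per-clone posterior draws, with
    ## regression-parameter uncertainty propagated into the prior
    nsim <- 4000
    mu0d <- fit$mu0_draws(nsim)
    a0d <- pmax(mu0d * sigma0, 1e-6)
    b0d <- pmax((1 - mu0d) * sigma0, 1e-6)
    Xm <- matrix(X, nsim, length(X), byrow = TRUE)
    Nm <- matrix(N, nsim, length(N), byrow = TRUE)
    th <- matrix(stats::rbeta(nsim * length(X), a0d + Xm,
                              b0d + Nm - Xm), nsim)
    draws <- as.numeric(th %*% N) / sum(N)
    aggregate <- rbind(aggregate, data.frame(
      group = g, estimate = sum(post * N) / sum(N),
      lo = stats::quantile(draws, alpha, names = FALSE),
      hi = stats::quantile(draws, 1 - alpha, names = FALSE),
      stringsAsFactors = FALSE))
  }
  rownames(per_clone) <- rownames(aggregate) <- NULL
  structure(list(per_clone = per_clone, aggregate = aggregate,
                 converged = converged, ci = ci),
            class = "clone_composition")
}

#' @export
print.clone_composition <- function(x, ...) {
  cat("Empirical-Bayes clone composition (size-weighted aggregates):\n")
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %s: %.1f%% (%.0f%% CI %.1f-%.1f%%)\n",
                x$aggregate$group[i], 100 * x$aggregate$estimate[i],
                100 * x$ci, 100 * x$aggregate$lo[i],
                100 * x$aggregate$hi[i]))
  invisible(x)
}

## beta-binomial regression with graceful degradation:
## covariate model -> intercept-only -> direct ML.  Besides the point
## prior (mu0 per clone, shared sigma0), returns a sampler of mu0 draws
## reflecting regression-parameter uncertainty, so aggregate intervals
## stay honest when the prior dominates (large sigma0).
.betabin_fit <- function(dat) {
  try_glmmTMB <- function(formula) {
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(formula,
                                        family = glmmTMB::betabinomial(),
                                        data = dat)),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$fit$convergence == 0)) return(NULL)
    V <- tryCatch(stats::vcov(fit)$cond, error = function(e) NULL)
    if (is.null(V) || anyNA(V)) return(NULL)
    mm <- stats::model.matrix(stats::delete.response(stats::terms(formula)),
                              dat)
    b <- glmmTMB::fixef(fit)$cond
    draws <- function(nsim) {
      L <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(L)) return(matrix(stats::plogis(as.numeric(mm %*% b)),
                                    nsim, nrow(dat), byrow = TRUE))
      Z <- matrix(stats::rnorm(nsim * length(b)), nsim)
      eta <- Z %*% L %*% t(mm) +
        matrix(as.numeric(mm %*% b), nsim, nrow(dat), byrow = TRUE)
      stats::plogis(eta)
    }
    list(mu0 = as.numeric(stats::plogis(mm %*% b)),
         sigma0 = stats::sigma(fit), mu0_draws = draws)
  }
  res <- try_glmmTMB(cbind(X, N - X) ~ nvar + logN)
  if (!is.null(res)) return(c(res, method = "covariate"))
  res <- try_glmmTMB(cbind(X, N - X) ~ 1)
  if (!is.null(res)) {
    warning("beta-binomial regression with covariates did not converge; ",
            "using intercept-only model")
    return(c(res, method = "intercept"))
  }
  warning("glmmTMB beta-binomial fits failed; using direct ML fit")
  nll <- function(par) {
    mu <- stats::plogis(par[1]); s <- exp(par[2])
    a <- mu * s; b <- (1 - mu) * s
    -sum(lchoose(dat$N, dat$X) + lbeta(dat$X + a, dat$N - dat$X + b) -
           lbeta(a, b))
  }
  opt <- stats::optim(c(stats::qlogis(max(min(sum(dat$X) / sum(dat$N),
                                              1 - 1e-3), 1e-3)), log(10)),
                      nll, method = "Nelder-Mead", hessian = TRUE)
  mu0 <- stats::plogis(opt$par[1])
  se_link <- tryCatch(sqrt(solve(opt$hessian)[1, 1]),
                      error = function(e) NA_real_)
  if (!is.finite(se_link))
    se_link <- sqrt(1 / max(sum(dat$N) * mu0 * (1 - mu0), 1))
  draws <- function(nsim)
    matrix(stats::plogis(stats::rnorm(nsim, opt$par[1], se_link)),
           nsim, nrow(dat))
  list(mu0 = rep(mu0, nrow(dat)), sigma0 = exp(opt$par[2]),
       mu0_draws = draws, method = "direct")
}
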