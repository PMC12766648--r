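#' Impute a perfect phylogeny from posterior genotypes
#'
#' Under the neutral infinite-sites model every pair of sites must be
#' compatible in the rooted sense: their carrier sets nested or disjoint
#' (no cells exhibiting all of the patterns 11, 10 and 01).  This function
#' returns a compatible binary matrix minimizing the total
#' posterior-weighted flip cost (flipping an entry to value `v` costs
#' `|posterior - v|`), optionally constrained so that each site's implied
#' carrier cell fraction stays within `mf_tol` of its mosaic fraction.
#'
#' Instances with at most `max_exact_sites` sites are solved exactly by
#' branch and bound over conflict witness triples.  Larger instances use
#' tree-guided assignment: a site tree is estimated from carrier-set
#' overlaps (each site's parent is the smallest earlier site containing
#' most of its carriers), and every cell is assigned the root-chain of
#' sites minimizing its total posterior disagreement.  Carrier sets of a
#' site tree's chains are laminar, so the result is always compatible and
#' the procedure terminates in one pass.
#'
#' @param posterior Numeric matrix (cells x sites) of posterior mutant
#'   probabilities in [0, 1] (a hard binary matrix is also accepted).
#' @param site_mfs Optional named vector of mosaic cell fractions per site
#'   used as the imputation constraint.
#' @param mf_tol Absolute tolerance on the implied carrier fraction.
#' @param threshold Posterior cut for the initial hard calls (default 0.5).
#' @param max_exact_sites Exact-search limit (default 12).
#' @return Object of class `imputed_matrix`: `genotypes` (binary matrix),
#'   `changed` (logical matrix of imputed entries), `cost` and `method`.
#' @export
impute_perfect_phylogeny <- function(posterior, site_mfs = NULL,
                                     mf_tol = 0.2, threshold = 0.5,
                                     max_exact_sites = 12) {
  stopifnot(is.matrix(posterior), all(posterior >= 0), all(posterior <= 1))
  M0 <- (posterior >= threshold) * 1L
  if (!is.null(site_mfs)) {
    stopifnot(!is.null(colnames(posterior)),
              all(colnames(posterior) %in% names(site_mfs)))
    site_mfs <- site_mfs[colnames(posterior)]
  }
  flip_cost <- function(M, i, j) abs(posterior[i, j] - (1 - M[i, j]))
  mf_ok <- function(M) {
    if (is.null(site_mfs)) return(TRUE)
    all(abs(colMeans(M) - site_mfs) <= mf_tol)
  }

  if (ncol(M0) <= max_exact_sites) {
    res <- .pp_exact(M0, posterior, mf_ok)
    if (is.null(res))
      stop("no compatible matrix satisfies the mosaic-fraction constraint")
    M <- res$M; cost <- res$cost; method <- "exact"
  } else {
    M <- .pp_chain_impute(posterior, M0)
    cost <- sum(abs(posterior - M)[M != M0])
    if (!is.null(.pp_find_conflict(M)))
      stop("tree-guided imputation produced an incompatible matrix")
    if (!mf_ok(M))
      warning("imputed matrix violates the mosaic-fraction constraint")
    method <- "tree-guided"
  }
  structure(list(genotypes = M, changed = M != M0, cost = cost,
                 posterior = posterior, method = method),
            class = "imputed_matrix")
}

## first pair of sites exhibiting the forbidden {11, 10, 01} patterns
.pp_find_conflict <- function(M) {
  ns <- ncol(M)
  if (ns < 2) return(NULL)
  ## cross-products give pattern counts for all pairs at once
  n11 <- crossprod(M)
  n1. <- matrix(colSums(M), ns, ns)
  n10 <- n1. - n11          # [i,j]: cells 1 at i, 0 at j
  bad <- n11 > 0 & n10 > 0 & t(n10) > 0
  bad[lower.tri(bad, diag = TRUE)] <- FALSE
  hit <- which(bad, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  list(i = hit[1, 1], j = hit[1, 2])
}

## tree-guided maximum-agreement assignment: estimate the site tree from
## carrier-set overlaps, then give each cell the root-chain of sites that
## minimizes its total |posterior - genotype| disagreement
.pp_chain_impute <- function(posterior, M0) {
  n <- nrow(M0); m <- ncol(M0)
  cnt <- colSums(M0)
  ord <- order(colSums(posterior), decreasing = TRUE)
  n11 <- crossprod(M0)
  parent <- rep(0L, m)                     # 0 = root
  for (k in seq_len(m)[-1]) {
    t <- ord[k]
    if (cnt[t] == 0) next
    cand <- ord[seq_len(k - 1)]
    frac <- n11[cand, t] / cnt[t]
    ok <- cand[frac >= 0.5]
    ## the latest-ordered qualifying superset approximates the direct
    ## parent and strings near-identical sites into a chain rather than
    ## a star
    if (length(ok)) parent[t] <- ok[length(ok)]
  }
  chains <- vector("list", m)
  for (s in seq_len(m)) {
    ch <- integer(0); v <- s
    while (v != 0L) { ch <- c(ch, v); v <- parent[v] }
    chains[[s]] <- ch
  }
  ## cost of the empty chain per cell, plus per-site deltas for adding a
  ## site to a cell's chain
  base <- rowSums(posterior)
  delta <- 1 - 2 * posterior               # cost change when set to 1
  best_cost <- base                        # empty chain
  best_chain <- rep(0L, n)
  for (s in seq_len(m)) {
    cc <- base + rowSums(delta[, chains[[s]], drop = FALSE])
    better <- cc < best_cost - 1e-12
    best_cost[better] <- cc[better]
    best_chain[better] <- s
  }
  M <- matrix(0L, n, m, dimnames = dimnames(M0))
  for (i in seq_len(n))
    if (best_chain[i] > 0L) M[i, chains[[best_chain[i]]]] <- 1L
  M
}

## exact branch and bound over witness triples
.pp_exact <- function(M0, posterior, mf_ok) {
  best <- list(M = NULL, cost = Inf)
  recurse <- function(M, locked, cost) {
    if (cost >= best$cost) return()
    cf <- .pp_find_conflict(M)
    if (is.null(cf)) {
      if (mf_ok(M) && cost < best$cost)
        best <<- list(M = M, cost = cost)
      return()
    }
    i <- cf$i; j <- cf$j
    w11 <- which(M[, i] == 1 & M[, j] == 1)[1]
    w10 <- which(M[, i] == 1 & M[, j] == 0)[1]
    w01 <- which(M[, i] == 0 & M[, j] == 1)[1]
    cand <- cbind(row = c(w11, w11, w10, w10, w01, w01),
                  col = c(i, j, i, j, i, j))
    ## inclusion/exclusion: branch k flips candidate k and forbids
    ## flipping candidates 1..k-1 (they keep their current value)
    newly_locked <- integer(0)
    for (k in seq_len(nrow(cand))) {
      e <- (cand[k, "col"] - 1L) * nrow(M) + cand[k, "row"]
      if (!locked[e]) {
        dc <- abs(posterior[e] - (1 - M[e]))
        if (cost + dc < best$cost) {
          M2 <- M; M2[e] <- 1L - M2[e]
          locked2 <- locked; locked2[c(e, newly_locked)] <- TRUE
          recurse(M2, locked2, cost + dc)
        }
        newly_locked <- c(newly_locked, e)
      }
    }
  }
  recurse(M0, rep(FALSE, length(M0)), 0)
  if (is.null(best$M)) NULL else best
}

#' Build the lineage tree from a compatible genotype matrix
#'
#' On a pairwise-compatible matrix the rooted perfect phylogeny is unique
#' up to the ordering of zero-length branches and is constructed directly
#' from the nesting of carrier sets; the parsimony score equals the number
#' of segregating sites (each site mutates exactly once).  Sites carried
#' by every cell map to the root branch; sites carried by no cell are
#' dropped (reported in `unplaced`).
#'
#' @param imputed An `imputed_matrix` or a binary cells x sites matrix
#'   with dimnames.
#' @return Object of class `lineage_tree`: `phylo` (an [ape] tree whose
#'   edge lengths are per-branch mutation counts), `variants` (site ->
#'   tree node whose parent edge carries it), `root_sites`, `unplaced`,
#'   and `n_tips`.
#' @export
build_tree <- function(imputed) {
  M <- if (inherits(imputed, "imputed_matrix")) imputed$genotypes else imputed
  stopifnot(is.matrix(M), all(M %in% c(0, 1)))
  if (is.null(rownames(M))) rownames(M) <- paste0("cell", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("site", seq_len(ncol(M)))
  if (!is.null(.pp_find_conflict(M)))
    stop("matrix is not compatible with a perfect phylogeny; impute first")
  n <- nrow(M)
  counts <- colSums(M)
  unplaced <- colnames(M)[counts == 0]
  root_sites <- colnames(M)[counts == n]
  seg <- which(counts > 0 & counts < n)

  ## unique carrier sets, largest first so parents precede children
  keys <- vapply(seg, function(s) paste(which(M[, s] == 1), collapse = ","),
                 character(1))
  uniq <- !duplicated(keys)
  sets <- lapply(seg[uniq], function(s) which(M[, s] == 1))
  set_sites <- lapply(keys[uniq], function(k)
    colnames(M)[seg][keys == k])
  ord <- order(vapply(sets, length, integer(1)), decreasing = TRUE)
  sets <- sets[ord]; set_sites <- set_sites[ord]

  ## separate singleton sets: their sites sit on terminal edges
  single <- vapply(sets, length, integer(1)) == 1L
  tip_sites <- stats::setNames(vector("list", n), rownames(M))
  for (k in which(single))
    tip_sites[[sets[[k]][1]]] <- set_sites[[k]]
  sets <- sets[!single]; set_sites <- set_sites[!single]
  n_int <- length(sets) + 1L            # + root

  ## parent of each internal set = smallest proper superset (or root)
  node_id <- function(k) n + 1L + k     # set k -> phylo node id
  parent_of_set <- integer(length(sets))
  for (k in seq_along(sets)) {
    parent_of_set[k] <- n + 1L          # root
    if (k > 1) for (q in (k - 1):1) {
      if (all(sets[[k]] %in% sets[[q]]) &&
          length(sets[[q]]) > length(sets[[k]])) {
        parent_of_set[k] <- node_id(q)
        break
      }
    }
  }
  ## tip parents: smallest set containing the tip
  parent_of_tip <- rep(n + 1L, n)
  for (k in seq_along(sets))            # sets ordered large -> small
    parent_of_tip[sets[[k]]] <- node_id(k)

  edge <- rbind(cbind(parent_of_set, n + 1L + seq_along(sets)),
                cbind(parent_of_tip, seq_len(n)))
  storage.mode(edge) <- "integer"
  dimnames(edge) <- NULL
  edge_sites <- c(set_sites, tip_sites)
  edge_len <- vapply(edge_sites, length, integer(1))

  phy <- structure(list(edge = edge, edge.length = as.numeric(edge_len),
                        Nnode = n_int, tip.label = rownames(M)),
                   class = "phylo", order = "cladewise")
  phy <- ape::reorder.phylo(phy, "cladewise")

  variants <- data.frame(
    site = c(unlist(edge_sites), root_sites),
    node = c(rep(edge[, 2], edge_len), rep(n + 1L, length(root_sites))),
    stringsAsFactors = FALSE)
  structure(list(phylo = phy, variants = variants,
                 root_sites = root_sites, unplaced = unplaced,
                 n_tips = n, parsimony = length(seg) + length(root_sites)),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d cells, %d placed sites (%d on root), parsimony %d\n",
              x$n_tips, nrow(x$variants), length(x$root_sites),
              x$parsimony))
  invisible(x)
}

#' Growth table mapping generations to post-MRCA weeks
#'
#' Default: exponential growth from one founder to `2^log2_final` cells
#' over `span_weeks` weeks, i.e. `log2`(population) linear in the week.
#'
#' @param log2_final Doublings at the end of the span (default 26,
#'   about sixty million cells).
#' @param span_weeks Weeks spanned (default 16).
#' @return Data frame with `week` and `log2_cells`.
#' @export
default_growth_table <- function(log2_final = 26, span_weeks = 16) {
  week <- seq(0, span_weeks, length.out = 33)
  data.frame(week = week, log2_cells = week / span_weeks * log2_final)
}

#' Convert coalescent generations to post-MRCA weeks
#'
#' The post-MRCA week (PMW) of generation `g` is the week at which the
#' cumulative number of doublings reaches `g`, by monotone interpolation
#' of the growth table; values beyond the table are clamped with a
#' warning.
#'
#' @param g Generations (vector).
#' @param growth_table Data frame with `week` and `log2_cells`, both
#'   monotone.
#' @return Weeks (PMW).
#' @export
generations_to_pmw <- function(g, growth_table = default_growth_table()) {
  stopifnot(all(diff(growth_table$week) >= 0),
            all(diff(growth_table$log2_cells) >= 0))
  if (any(g > max(growth_table$log2_cells) | g < min(growth_table$log2_cells)))
    warning("generations outside the growth table range were clamped")
  stats::approx(growth_table$log2_cells, growth_table$week, xout = g,
                rule = 2, ties = "ordered")$y
}

#' Fit the coalescent time-of-origin model to a lineage tree
#'
#' Canonical model: the founder population doubles every generation up to
#' the final size `N = 2^G`; mutations arise at `mu` per generation
#' population-wide, placed uniformly on extant lineages, so a branch from
#' time `t_u` to `t_v` carries Poisson(`mu * (2^-t_u - 2^-t_v)`)
#' mutations; sample genealogy node times follow the binary-division
#' coalescent with pairwise intensity `ln(2) * 2^-t`.  The posterior over
#' (`N`, `mu`, node times) is sampled by random-walk MCMC (priors:
#' `log2 N` uniform on [log2 1e6, log2 1e9]; `mu` gets a Jeffreys-type
#' scale prior `1/mu` with an exponential tail of mean `mu_mean`,
#' default 10).  Each variant's time of origin (TOO) is the posterior midpoint of
#' its branch, converted to post-MRCA weeks via the growth table.
#'
#' `N` is only weakly informed by the data (it enters through terms of
#' order `2^-G`); its posterior is largely prior-driven, and is reported
#' as such.
#'
#' @param tree A `lineage_tree`.
#' @param growth_table Growth table for the PMW conversion.
#' @param n_chains,n_iter,n_warmup MCMC settings (defaults 4 chains,
#'   2000 kept draws after 1000 warmup each).
#' @param cred Credible level for intervals (default 0.9).
#' @param priors List overriding `log2N_min`, `log2N_max`, `mu_mean`.
#' @param rhat_limit Split-chain convergence threshold (default 1.01).
#' @param on_nonmixing `"error"` (default) or `"warn"` when the
#'   diagnostic exceeds `rhat_limit`.
#' @param seed RNG seed.
#' @return Object of class `coalescent_fit`: posterior `draws` for `mu`,
#'   `G` and `N`; `variant_too` (per-variant TOO in generations and PMW
#'   with credible intervals); `node_times`; `rhat`.
#' @export
fit_coalescent_too <- function(tree, growth_table = default_growth_table(),
                               n_chains = 4, n_iter = 2000,
                               n_warmup = 1000, cred = 0.9,
                               priors = list(), rhat_limit = 1.01,
                               on_nonmixing = c("error", "warn"),
                               seed = 1L) {
  on_nonmixing <- match.arg(on_nonmixing)
  stopifnot(inherits(tree, "lineage_tree"))
  pr <- utils::modifyList(
    list(log2N_min = log2(1e6), log2N_max = log2(1e9), mu_mean = 10),
    priors)

  phy <- tree$phylo
  n_tips <- tree$n_tips
  n_nodes <- n_tips + phy$Nnode
  parent <- rep(-1L, n_nodes)
  m <- rep(0, n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  m[phy$edge[, 2]] <- phy$edge.length
  root <- n_tips + 1L
  m_root <- length(tree$root_sites)
  internal <- root:n_nodes

  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(as.integer(seed) + ch * 1000L)
    run_coalescent_chain(
      parent - 1L, n_tips, m, m_root,
      n_iter, n_warmup,
      pr$log2N_min, pr$log2N_max, 1 / pr$mu_mean)
  })
  ## columns: mu, G, then internal node times (root first)
  draws <- do.call(rbind, chains)
  chain_id <- rep(seq_len(n_chains), each = n_iter)

  rhat <- c(mu = .split_rhat(draws[, 1], chain_id),
            G = .split_rhat(draws[, 2], chain_id))
  if (any(rhat > rhat_limit, na.rm = TRUE)) {
    msg <- sprintf("chains may not have mixed: Rhat(mu) = %.3f, Rhat(G) = %.3f (limit %.3f)",
                   rhat["mu"], rhat["G"], rhat_limit)
    if (on_nonmixing == "error") stop(msg) else warning(msg)
  }

  qs <- c((1 - cred) / 2, 0.5, (1 + cred) / 2)
  mu_q <- stats::quantile(draws[, 1], qs, names = FALSE)
  G_q <- stats::quantile(draws[, 2], qs, names = FALSE)

  t_of <- function(node) {           # per-draw time of a node
    if (node >= root) draws[, 2 + (node - root + 1)] else draws[, 2]
  }
  variants <- tree$variants
  too <- t(vapply(seq_len(nrow(variants)), function(i) {
    v <- variants$node[i]
    tu <- if (v == root) 0 else t_of(parent[v])
    mid <- (tu + t_of(v)) / 2
    stats::quantile(mid, qs, names = FALSE)
  }, numeric(3)))
  variant_too <- data.frame(
    site = variants$site, node = variants$node,
    too_lo = too[, 1], too = too[, 2], too_hi = too[, 3],
    pmw_lo = generations_to_pmw(too[, 1], growth_table),
    pmw = generations_to_pmw(too[, 2], growth_table),
    pmw_hi = generations_to_pmw(too[, 3], growth_table),
    stringsAsFactors = FALSE)

  node_times <- t(apply(draws[, -(1:2), drop = FALSE], 2,
                        stats::quantile, probs = qs, names = FALSE))
  dimnames(node_times) <- list(internal, c("lo", "median", "hi"))

  structure(list(
    draws = data.frame(chain = chain_id, mu = draws[, 1], G = draws[, 2],
                       N = 2^draws[, 2]),
    mu = stats::setNames(mu_q, c("lo", "median", "hi")),
    G = stats::setNames(G_q, c("lo", "median", "hi")),
    N = stats::setNames(2^G_q, c("lo", "median", "hi")),
    variant_too = variant_too, node_times = node_times,
    rhat = rhat, cred = cred, growth_table = growth_table,
    settings = list(n_chains = n_chains, n_iter = n_iter,
                    n_warmup = n_warmup, priors = pr, seed = seed)),
    class = "coalescent_fit")
}

#' @export
print.coalescent_fit <- function(x, ...) {
  cat(sprintf(
    "coalescent_fit: mu = %.2f (%.0f%% CI %.2f-%.2f), N = %.2g (CI %.2g-%.2g)\n",
    x$mu["median"], 100 * x$cred, x$mu["lo"], x$mu["hi"],
    x$N["median"], x$N["lo"], x$N["hi"]))
  cat(sprintf("  %d variants dated; Rhat(mu) = %.3f, Rhat(G) = %.3f\n",
              nrow(x$variant_too), x$rhat["mu"], x$rhat["G"]))
  invisible(x)
}

## split-chain potential scale reduction factor
.split_rhat <- function(x, chain_id) {
  halves <- lapply(split(x, chain_id), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  })
  sub <- unlist(halves, recursive = FALSE)
  means <- vapply(sub, mean, numeric(1))
  vars <- vapply(sub, stats::var, numeric(1))
  n <- length(sub[[1]]); mchains <- length(sub)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Regional restriction statistic of a clade
#'
#' Ratio of the mean phylogenetic (patristic) distance between
#' cross-region cell pairs to the mean distance between same-region pairs
#' within a clade; values above 1 mean clade-mates in the same region are
#' more closely related than across regions (regional restriction).
#' Confidence intervals are bootstrapped over the clade's cells.
#'
#' @param tree A `lineage_tree` or `phylo`.
#' @param regions Named vector: cell -> region.
#' @param cells Cells defining the clade (default all tips).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param ci Confidence level (default 0.95).
#' @param orientation `"restriction"` (default; > 1 = restricted) or
#'   `"within_over_cross"` for the reciprocal.
#' @param seed Optional RNG seed.
#' @return Object of class `rrs_result` (list with `rrs`, `ci_lo`,
#'   `ci_hi`, pair counts, bootstrap draws); `rrs` is `NA` when the clade
#'   has no within- or no cross-region pair.
#' @export
compute_rrs <- function(tree, regions, cells = NULL, n_boot = 1000,
                        ci = 0.95, orientation = c("restriction",
                                                   "within_over_cross"),
                        seed = NULL) {
  orientation <- match.arg(orientation)
  if (!is.null(seed)) set.seed(seed)
  phy <- if (inherits(tree, "lineage_tree")) tree$phylo else tree
  D <- ape::cophenetic.phylo(phy)
  if (is.null(cells)) cells <- phy$tip.label
  stopifnot(all(cells %in% phy$tip.label), all(cells %in% names(regions)))
  reg <- regions[cells]

  ratio_of <- function(idx) {
    r <- reg[idx]
    d <- D[cells[idx], cells[idx], drop = FALSE]
    same <- outer(r, r, "==")
    ut <- upper.tri(d)
    dup <- outer(idx, idx, "==")            # identical resampled cells
    w <- d[ut & same & !dup]; x <- d[ut & !same]
    if (!length(w) || !length(x)) return(NA_real_)
    if (orientation == "restriction") mean(x) / mean(w) else mean(w) / mean(x)
  }
  idx0 <- seq_along(cells)
  point <- ratio_of(idx0)
  r <- reg
  n_within <- sum(outer(r, r, "==")[upper.tri(diag(length(r)))])
  n_cross <- choose(length(r), 2) - n_within
  if (is.na(point)) {
    message("RRS undefined: clade lacks within- or cross-region pairs")
    return(structure(list(rrs = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, n_within = n_within,
                          n_cross = n_cross, boot = numeric(0)),
                     class = "rrs_result"))
  }
  boot <- replicate(n_boot, ratio_of(
    sample.int(length(cells), length(cells), replace = TRUE)))
  boot <- boot[!is.na(boot)]
  qs <- stats::quantile(boot, c((1 - ci) / 2, (1 + ci) / 2), names = FALSE)
  structure(list(rrs = point, ci_lo = qs[1], ci_hi = qs[2],
                 n_within = n_within, n_cross = n_cross, boot = boot),
            class = "rrs_result")
}

#' @export
print.rrs_result <- function(x, ...) {
  cat(sprintf("RRS = %.3f (CI %.3f-%.3f); %d within- / %d cross-region pairs\n",
              x$rrs, x$ci_lo, x$ci_hi, x$n_within, x$n_cross))
  invisible(x)
}

#' Cluster variants into spatial dispersion modes
#'
#' Standard k-means (multiple restarts, fixed seed) on the matrix of
#' variants by per-region mosaic fractions.  When the matrix has fewer
#' distinct rows than `k` the effective number of clusters is reduced
#' accordingly.
#'
#' @param variant_region_mf Numeric matrix, variants x regions.
#' @param k Number of dispersion modes (default 5).
#' @param seed RNG seed (default 1).
#' @param nstart Restarts (default 25).
#' @return Object of class `dispersion_clusters`: `cluster` (named
#'   assignment), `centers`, `k`.
#' @export
kmeans_dispersion <- function(variant_region_mf, k = 5, seed = 1L,
                              nstart = 25) {
  stopifnot(is.matrix(variant_region_mf))
  if (k > nrow(variant_region_mf))
    stop("k exceeds the number of variants")
  set.seed(seed)
  k_eff <- min(k, nrow(unique(variant_region_mf)))
  if (k_eff < k)
    message("only ", k_eff, " distinct profiles; using k = ", k_eff)
  if (k_eff == 1) {
    cl <- rep(1L, nrow(variant_region_mf))
    centers <- matrix(colMeans(variant_region_mf), 1,
                      dimnames = list(NULL, colnames(variant_region_mf)))
  } else {
    km <- stats::kmeans(variant_region_mf, centers = k_eff,
                        nstart = nstart)
    cl <- km$cluster
    centers <- km$centers
  }
  structure(list(cluster = stats::setNames(cl, rownames(variant_region_mf)),
                 centers = centers, k = k_eff),
            class = "dispersion_clusters")
}
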