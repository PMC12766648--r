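#' Simulate a developmental cell lineage with regional and cell-type
#' structure
#'
#' Grows a genealogy from one founder by synchronous binary division until
#' the configured final population size.  The genealogy is explicit up to
#' the tracked-lineage cap; beyond that generation each tracked lineage is
#' a clone whose mass is carried analytically.  Each generation receives
#' Poisson(`mutations_per_generation`) new mutations placed uniformly on
#' extant lineages (neutral, infinite sites), so a mutation arising in
#' generation `g` has true mosaic fraction `2^-g`.  Clones are committed to
#' regions at the configured restriction generations; clades arising before
#' a region's restriction time span regions (dispersion), later clades are
#' region-confined.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#'
#' @return An object of class `true_population`: a list with the tracked
#'   genealogy depth `D`, total generations `G`, a `leaves` table (tracked
#'   clone, region, dorsal origin flag), and a `mutations` table (id,
#'   origin generation, origin branch at depth `min(g, D)`, within-clone
#'   carrier fraction `subfrac`, true mosaic fraction).
#' @export
simulate_population <- function(config, seed = NULL) {
  validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed else seed)

  G <- ceiling(log2(config$final_population_size))
  D <- min(as.integer(log2(config$tracked_lineages)), G)
  n_leaves <- 2L^D

  ## --- mutations: Poisson(mu) per generation, uniform over extant lineages
  mut <- NULL
  if (config$mutations_per_generation > 0) {
    per_gen <- stats::rpois(G, config$mutations_per_generation)
    gens <- rep.int(seq_len(G), per_gen)
    if (length(gens)) {
      node_depth <- pmin(gens, D)
      node <- vapply(node_depth, function(d)
        sample.int(2L^d, 1L), integer(1))
      mut <- data.frame(
        mut_id = paste0("m", seq_along(gens)),
        gen = gens,
        node_depth = node_depth,
        node = node,
        subfrac = 2^-(pmax(gens - D, 0)),
        true_mf = 2^-gens,
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(mut))
    mut <- data.frame(mut_id = character(), gen = integer(),
                      node_depth = integer(), node = integer(),
                      subfrac = numeric(), true_mf = numeric(),
                      stringsAsFactors = FALSE)

  ## --- region commitment by clade at each region's restriction generation
  regions <- config$region_names
  depth_of <- pmin(pmax(ceiling(config$region_restriction_times), 0L), D)
  region_of_leaf <- rep(NA_character_, n_leaves)
  w <- stats::setNames(rep(1 / length(regions), length(regions)), regions)
  for (d in sort(unique(depth_of))) {
    now <- regions[depth_of == d]
    later <- regions[depth_of > d]
    block <- 2L^(D - d)
    node_of_leaf <- (seq_len(n_leaves) - 1L) %/% block + 1L
    free_nodes <- unique(node_of_leaf[is.na(region_of_leaf)])
    if (!length(free_nodes)) break
    probs <- c(w[now], remain = sum(w[later]))
    pick <- sample(c(now, if (length(later)) ".later"), length(free_nodes),
                   replace = TRUE, prob = probs[probs > 0])
    for (i in seq_along(free_nodes)) {
      if (pick[i] == ".later") next
      region_of_leaf[node_of_leaf == free_nodes[i]] <- pick[i]
    }
  }
  stopifnot(!anyNA(region_of_leaf))

  ## --- dorsal/ventral clone origin controlling GluN:GABN co-generation
  p <- config$celltype_proportions
  neuron_frac <- sum(p[c("GluN_upper", "GluN_other", "CGE_GABN", "MGE_GABN")])
  glun_frac <- sum(p[c("GluN_upper", "GluN_other")])
  r <- config$dorsal_glun_gabn_ratio
  p_dorsal <- if (neuron_frac > 0) glun_frac / (neuron_frac * r / (r + 1)) else 0
  if (p_dorsal > 1) {
    warning("dorsal_glun_gabn_ratio incompatible with celltype_proportions; ",
            "clamping dorsal clone fraction to 1")
    p_dorsal <- 1
  }
  leaves <- data.frame(
    leaf = seq_len(n_leaves),
    region = region_of_leaf,
    dorsal = stats::runif(n_leaves) < p_dorsal,
    stringsAsFactors = FALSE)

  structure(list(config = config, D = D, G = G,
                 n_leaves = n_leaves, leaves = leaves,
                 mutations = mut, p_dorsal = p_dorsal),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf(
    "true_population: %d tracked clones (depth %d of %d generations), %d mutations, %d regions\n",
    x$n_leaves, x$D, x$G, nrow(x$mutations), x$config$n_regions))
  invisible(x)
}

## leaves below mutation i (indices into 1:n_leaves)
carrier_leaves <- function(pop, i) {
  m <- pop$mutations[i, ]
  block <- 2L^(pop$D - m$node_depth)
  ((m$node - 1L) * block + 1L):(m$node * block)
}

## is each of `leaf` below mutation i?
leaf_is_carrier <- function(pop, i, leaf) {
  m <- pop$mutations[i, ]
  block <- 2L^(pop$D - m$node_depth)
  (leaf - 1L) %/% block + 1L == m$node
}

#' True regional mosaic fractions of every mutation
#'
#' Cell fractions (not allele fractions) of each mutation in each region,
#' computed from the tracked clone structure; `subfrac` accounts for
#' mutations arising after the tracked phase.
#'
#' @param pop A `true_population`.
#' @return Matrix of cell fractions, mutations x regions.
#' @export
regional_true_mf <- function(pop) {
  regs <- pop$config$region_names
  n_r <- table(factor(pop$leaves$region, levels = regs))
  out <- matrix(0, nrow(pop$mutations), length(regs),
                dimnames = list(pop$mutations$mut_id, regs))
  for (i in seq_len(nrow(pop$mutations))) {
    cl <- carrier_leaves(pop, i)
    cnt <- table(factor(pop$leaves$region[cl], levels = regs))
    out[i, ] <- as.numeric(cnt) * pop$mutations$subfrac[i] / as.numeric(n_r)
  }
  out
}

#' Simulate the bulk whole-genome sequencing readout
#'
#' Per region and mutation, draws a Poisson depth around the configured
#' WGS coverage and binomial alternate reads at the regional alternate
#' allele fraction (half the regional cell fraction for a heterozygous
#' variant).
#'
#' @param pop A `true_population`.
#' @param config The simulator configuration (defaults to `pop$config`).
#' @param drop_undetected Drop rows with zero alternate reads.
#' @param seed RNG seed (default derived from the configuration seed).
#'
#' @return Data frame with columns `variant`, `region`, `depth`,
#'   `alt_reads`, `aaf`, and the generating truth `true_regional_mf`.
#' @export
simulate_bulk_wgs <- function(pop, config = pop$config,
                              drop_undetected = FALSE, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  mfr <- regional_true_mf(pop)
  if (!nrow(mfr))
    return(data.frame(variant = character(), region = character(),
                      depth = integer(), alt_reads = integer(),
                      aaf = numeric(), true_regional_mf = numeric()))
  long <- expand.grid(variant = rownames(mfr), region = colnames(mfr),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$true_regional_mf <- as.vector(mfr)
  long$depth <- stats::rpois(nrow(long), config$wgs_depth)
  long$alt_reads <- stats::rbinom(nrow(long), long$depth,
                                  pmin(long$true_regional_mf / 2, 1))
  long$aaf <- ifelse(long$depth > 0, long$alt_reads / long$depth, 0)
  if (drop_undetected) long <- long[long$alt_reads > 0, , drop = FALSE]
  long[order(long$variant, long$region),
       c("variant", "region", "depth", "alt_reads", "aaf",
         "true_regional_mf")]
}

#' Simulate the deep replicate-amplicon readout
#'
#' For each variant/region, draws 1-3 replicate primer pairs, each with a
#' total depth of at least the configured amplicon depth, binomial mutant
#' reads at the regional allele fraction with Beta-distributed
#' amplification imbalance around 0.5, and error tallies over 100 flanking
#' positions at the configured error rate.
#'
#' @param pop A `true_population`.
#' @param config Simulator configuration.
#' @param variants Table with `variant` and `region` columns (e.g. from
#'   [simulate_bulk_wgs()]); regional truth is looked up in `pop`.
#' @param n_primer_range Integer range of replicate primers per site.
#' @param seed RNG seed.
#'
#' @return Data frame with columns `variant`, `region`, `primer`, `depth`,
#'   `alt_reads`, `flank_err_reads`, `flank_error` (mean flanking allele
#'   fraction over 100 positions).
#' @export
simulate_amplicons <- function(pop, config = pop$config, variants,
                               n_primer_range = 1:3, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 2L else seed)
  mfr <- regional_true_mf(pop)
  key <- unique(variants[, c("variant", "region")])
  n_primers <- sample(n_primer_range, nrow(key), replace = TRUE)
  idx <- rep(seq_len(nrow(key)), n_primers)
  out <- key[idx, , drop = FALSE]
  out$primer <- unlist(lapply(n_primers, seq_len))
  n <- nrow(out)
  out$depth <- config$amplicon_depth +
    stats::rpois(n, 0.25 * config$amplicon_depth)
  f <- mfr[cbind(out$variant, out$region)]
  q <- stats::rbeta(n, config$amplicon_imbalance_shape,
                    config$amplicon_imbalance_shape)
  out$alt_reads <- stats::rbinom(n, out$depth, pmin(f * q, 1))
  flank_bases <- 100 * out$depth
  out$flank_err_reads <- stats::rbinom(n, flank_bases,
                                       config$amplicon_error_rate)
  out$flank_error <- out$flank_err_reads / flank_bases
  rownames(out) <- NULL
  out
}

#' Simulate the single-cell readout layers
#'
#' Samples `n_cells` cells (stratified by region), assigns cell types with
#' dorsal clones producing GluN and GABN at the configured ratio, and emits
#' two layers: a single-cell amplification panel (read counts per cell and
#' site with allelic dropout and amplification imbalance) and a sparse
#' single-nucleus UMI tally (Poisson UMIs per site, binomial mutant UMIs
#' given the cell's true genotype).
#'
#' @param pop A `true_population`.
#' @param config Simulator configuration.
#' @param panel Character vector of mutation ids to genotype.
#' @param n_cells Number of cells to sample.
#' @param stratify_by_region Split cells evenly across regions.
#' @param seed RNG seed.
#'
#' @return List with `cells` (cell, leaf, region, cell_type), `panel`
#'   (cell, site, ref_reads, alt_reads), `tally` (cell, variant,
#'   total_umis, mut_umis), and the logical truth matrix `genotypes`
#'   (cells x panel sites).
#' @export
simulate_single_cell_readouts <- function(pop, config = pop$config, panel,
                                          n_cells,
                                          stratify_by_region = TRUE,
                                          seed = NULL) {
  if (!all(panel %in% pop$mutations$mut_id))
    stop("panel references unknown mutation id(s): ",
         paste(setdiff(panel, pop$mutations$mut_id), collapse = ", "))
  if (n_cells > pop$config$final_population_size)
    stop("cannot sample more cells than the final population size")
  set.seed(if (is.null(seed)) config$seed + 3L else seed)

  ## --- sample cells (clones with replacement; clone masses are equal)
  if (stratify_by_region) {
    regs <- pop$config$region_names
    per <- diff(round(seq(0, n_cells, length.out = length(regs) + 1)))
    leaf <- unlist(lapply(seq_along(regs), function(i) {
      pool <- pop$leaves$leaf[pop$leaves$region == regs[i]]
      if (!length(pool)) stop("region has no clones: ", regs[i])
      pool[sample.int(length(pool), per[i], replace = TRUE)]
    }))
  } else {
    leaf <- sample.int(pop$n_leaves, n_cells, replace = TRUE)
  }
  cells <- data.frame(cell = sprintf("c%04d", seq_len(n_cells)),
                      leaf = leaf,
                      region = pop$leaves$region[leaf],
                      dorsal = pop$leaves$dorsal[leaf],
                      stringsAsFactors = FALSE)
  cells$cell_type <- draw_cell_types(cells$dorsal, config)
  cells$dorsal <- NULL

  ## --- true genotypes
  pidx <- match(panel, pop$mutations$mut_id)
  geno <- matrix(FALSE, n_cells, length(panel),
                 dimnames = list(cells$cell, panel))
  for (j in seq_along(pidx)) {
    below <- leaf_is_carrier(pop, pidx[j], leaf)
    sf <- pop$mutations$subfrac[pidx[j]]
    geno[, j] <- below & (sf == 1 | stats::runif(n_cells) < sf)
  }

  ## --- panel layer (MDA-amplified targeted reads)
  grid <- expand.grid(cell = cells$cell, site = panel,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  depth <- stats::rpois(n, config$panel_depth)
  carrier <- as.vector(geno)
  ado <- stats::runif(n) < config$panel_ado_rate
  q <- stats::rbeta(n, config$amplicon_imbalance_shape,
                    config$amplicon_imbalance_shape)
  p_alt <- ifelse(carrier & !ado, q, config$panel_error_rate)
  alt <- stats::rbinom(n, depth, p_alt)
  panel_tab <- data.frame(cell = grid$cell, site = grid$site,
                          ref_reads = depth - alt, alt_reads = alt,
                          stringsAsFactors = FALSE)

  ## --- single-nucleus UMI layer
  umis <- stats::rpois(n, config$snrna_umi_rate)
  p_mut <- ifelse(carrier, 0.5, config$snrna_error_rate)
  mut_umis <- stats::rbinom(n, umis, p_mut)
  tally <- data.frame(cell = grid$cell, variant = grid$site,
                      total_umis = umis, mut_umis = mut_umis,
                      stringsAsFactors = FALSE)

  list(cells = cells, panel = panel_tab, tally = tally, genotypes = geno)
}

## neuron/glia draw respecting dorsal GluN:GABN co-generation
draw_cell_types <- function(dorsal, config) {
  p <- config$celltype_proportions
  glia <- c("astrocyte", "oligodendrocyte", "microglia")
  glia_frac <- sum(p[glia])
  r <- config$dorsal_glun_gabn_ratio
  n <- length(dorsal)
  out <- character(n)
  is_glia <- stats::runif(n) < glia_frac
  if (any(is_glia))
    out[is_glia] <- sample(glia, sum(is_glia), replace = TRUE,
                           prob = p[glia])
  neu <- which(!is_glia)
  if (length(neu)) {
    glun <- dorsal[neu] & stats::runif(length(neu)) < r / (r + 1)
    g_sub <- sample(c("GluN_upper", "GluN_other"), sum(glun),
                    replace = TRUE, prob = p[c("GluN_upper", "GluN_other")])
    b_sub <- sample(c("CGE_GABN", "MGE_GABN"), sum(!glun),
                    replace = TRUE, prob = p[c("CGE_GABN", "MGE_GABN")])
    out[neu[glun]] <- g_sub
    out[neu[!glun]] <- b_sub
  }
  out
}
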