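#' Configuration for the developmental-lineage simulator
#'
#' Collects the parameters of the synthetic ground truth: a single founder
#' cell grows by synchronous binary division to `final_population_size`
#' cells over the neurogenic window, accruing on average
#' `mutations_per_generation` new somatic SNVs per generation placed
#' uniformly on extant lineages (neutral, infinite sites).  Clones become
#' confined to cortical regions at per-region restriction generations, and
#' cells are assigned neuronal/glial types, with dorsal clones producing
#' glutamatergic and GABAergic neurons at `dorsal_glun_gabn_ratio`.
#'
#' The genealogy is simulated explicitly only for `tracked_lineages`
#' lineages (a power of two); beyond that generation each tracked lineage
#' is treated as a clone whose mass is scaled analytically to the final
#' population size.  Mutations arising after the tracked phase are carried
#' as within-clone subclonal fractions, so every generation still receives
#' Poisson(`mutations_per_generation`) mutations and true mosaic fractions
#' remain exactly `2^-g` for a mutation of origin generation `g`.
#'
#' @param final_population_size Final number of mutation-bearing cells
#'   (default 6e7).
#' @param mutations_per_generation Expected new population-level mutations
#'   per generation (default 7).
#' @param neurogenesis_span_weeks Weeks spanned by the lineage (default 16).
#' @param n_regions Number of cortical regions.
#' @param region_names Region labels; defaults to `BA17`, `BA18`, `BA9`
#'   (padded with `R<k>` when `n_regions > 3`).
#' @param region_restriction_times Named vector mapping region to the
#'   generation at which clones become region-confined.
#' @param celltype_proportions Named fractions over the grouped cell types
#'   (upper-layer GluN, other-layer GluN, CGE-GABN, MGE-GABN, astrocyte,
#'   oligodendrocyte, microglia); must sum to 1.
#' @param dorsal_glun_gabn_ratio GluN:GABN ratio within dorsal clones
#'   (default 12).
#' @param wgs_depth Mean bulk WGS depth in reads (default 210).
#' @param amplicon_depth Minimum deep-amplicon depth in reads (default 1e4).
#' @param amplicon_error_rate Per-base flanking error rate (allele-fraction
#'   scale, default 5e-4).
#' @param amplicon_imbalance_shape Shape of the symmetric Beta distribution
#'   modelling amplification imbalance of the mutant-read fraction around
#'   0.5; larger is tighter (default 200).
#' @param panel_depth Mean read depth per cell and site in the single-cell
#'   panel layer (default 30).
#' @param panel_ado_rate Allelic-dropout probability per cell and site
#'   (default 0.2).
#' @param panel_error_rate Per-read non-reference error rate at non-carrier
#'   sites in the panel layer (default 2e-3).
#' @param snrna_umi_rate Expected UMIs covering a site per cell in the
#'   single-nucleus layer (default 2).
#' @param snrna_error_rate Per-UMI error rate in the single-nucleus layer
#'   (default 1e-3).
#' @param tracked_lineages Cap on explicitly tracked lineages; rounded down
#'   to a power of two (default 8192).
#' @param seed Integer seed making every emitted table reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(final_population_size = 6e7,
                       mutations_per_generation = 7,
                       neurogenesis_span_weeks = 16,
                       n_regions = 3,
                       region_names = NULL,
                       region_restriction_times = NULL,
                       celltype_proportions = c(
                         GluN_upper = 0.30, GluN_other = 0.30,
                         CGE_GABN = 0.10, MGE_GABN = 0.10,
                         astrocyte = 0.10, oligodendrocyte = 0.07,
                         microglia = 0.03),
                       dorsal_glun_gabn_ratio = 12,
                       wgs_depth = 210,
                       amplicon_depth = 10000,
                       amplicon_error_rate = 5e-4,
                       amplicon_imbalance_shape = 200,
                       panel_depth = 30,
                       panel_ado_rate = 0.2,
                       panel_error_rate = 2e-3,
                       snrna_umi_rate = 2,
                       snrna_error_rate = 1e-3,
                       tracked_lineages = 8192,
                       seed = 1L) {
  if (is.null(region_names)) {
    base <- c("BA17", "BA18", "BA9")
    region_names <- if (n_regions <= 3) base[seq_len(n_regions)] else
      c(base, paste0("R", seq_len(n_regions - 3)))
  }
  stopifnot(length(region_names) == n_regions)
  if (is.null(region_restriction_times)) {
    # BA9 clones commit early; the visual-border regions later
    region_restriction_times <- stats::setNames(
      rep(8, n_regions), region_names)
    if ("BA9" %in% region_names) region_restriction_times["BA9"] <- 4
  }
  stopifnot(all(region_names %in% names(region_restriction_times)))
  region_restriction_times <- region_restriction_times[region_names]

  cfg <- list(
    final_population_size = final_population_size,
    mutations_per_generation = mutations_per_generation,
    neurogenesis_span_weeks = neurogenesis_span_weeks,
    n_regions = as.integer(n_regions),
    region_names = region_names,
    region_restriction_times = region_restriction_times,
    celltype_proportions = celltype_proportions,
    dorsal_glun_gabn_ratio = dorsal_glun_gabn_ratio,
    wgs_depth = wgs_depth,
    amplicon_depth = amplicon_depth,
    amplicon_error_rate = amplicon_error_rate,
    amplicon_imbalance_shape = amplicon_imbalance_shape,
    panel_depth = panel_depth,
    panel_ado_rate = panel_ado_rate,
    panel_error_rate = panel_error_rate,
    snrna_umi_rate = snrna_umi_rate,
    snrna_error_rate = snrna_error_rate,
    tracked_lineages = 2L^floor(log2(tracked_lineages)),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      final_population_size >= 2,
      mutations_per_generation >= 0,
      neurogenesis_span_weeks > 0,
      n_regions >= 1,
      wgs_depth > 0, amplicon_depth > 0, panel_depth > 0,
      tracked_lineages >= 2,
      amplicon_error_rate >= 0, amplicon_error_rate <= 1,
      panel_ado_rate >= 0, panel_ado_rate <= 1,
      panel_error_rate >= 0, panel_error_rate <= 1,
      snrna_error_rate >= 0, snrna_error_rate <= 1,
      snrna_umi_rate >= 0,
      dorsal_glun_gabn_ratio > 0,
      all(celltype_proportions >= 0), all(celltype_proportions <= 1),
      all(region_restriction_times >= 0))
    if (abs(sum(celltype_proportions) - 1) > 1e-9)
      stop("celltype_proportions must sum to 1")
  })
  invisible(cfg)
}

#' Write / read a simulator configuration as a key-value text file
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  flat <- unlist(cfg[setdiff(names(cfg), "class")])
  writeLines(paste(names(flat), vapply(flat, as.character, ""),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  get1 <- function(k) as.numeric(kv$value[kv$key == k])
  getv <- function(prefix) {
    sel <- startsWith(kv$key, paste0(prefix, "."))
    stats::setNames(as.numeric(kv$value[sel]),
                    sub(paste0("^", prefix, "\\."), "", kv$key[sel]))
  }
  regions <- kv$value[startsWith(kv$key, "region_names")]
  sim_config(
    final_population_size = get1("final_population_size"),
    mutations_per_generation = get1("mutations_per_generation"),
    neurogenesis_span_weeks = get1("neurogenesis_span_weeks"),
    n_regions = get1("n_regions"),
    region_names = regions,
    region_restriction_times = getv("region_restriction_times"),
    celltype_proportions = getv("celltype_proportions"),
    dorsal_glun_gabn_ratio = get1("dorsal_glun_gabn_ratio"),
    wgs_depth = get1("wgs_depth"),
    amplicon_depth = get1("amplicon_depth"),
    amplicon_error_rate = get1("amplicon_error_rate"),
    amplicon_imbalance_shape = get1("amplicon_imbalance_shape"),
    panel_depth = get1("panel_depth"),
    panel_ado_rate = get1("panel_ado_rate"),
    panel_error_rate = get1("panel_error_rate"),
    snrna_umi_rate = get1("snrna_umi_rate"),
    snrna_error_rate = get1("snrna_error_rate"),
    tracked_lineages = get1("tracked_lineages"),
    seed = get1("seed"))
}
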