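test_that("degenerate configurations behave as constructed", {
  cfg <- sim_config(mutations_per_generation = 0, tracked_lineages = 64,
                    final_population_size = 4096, seed = 1)
  pop <- simulate_population(cfg)
  expect_identical(nrow(pop$mutations), 0L)

  cfg1 <- sim_config(n_regions = 1, tracked_lineages = 64,
                     final_population_size = 4096, seed = 2)
  pop1 <- simulate_population(cfg1)
  mfr <- regional_true_mf(pop1)
  expect_equal(ncol(mfr), 1L)
  # single region: every mutation's carriers are single-region
  expect_true(all(rowSums(mfr > 0) <= 1))
})

test_that("mutation accrual matches the Poisson rate", {
  cfg <- sim_config(tracked_lineages = 1024, seed = 11)
  pop <- simulate_population(cfg)
  per_gen <- tabulate(pop$mutations$gen, nbins = 20)
  se <- sqrt(7 / 20)
  expect_lt(abs(mean(per_gen) - 7), 3 * se)
})

test_that("seeded simulation is byte-for-byte reproducible", {
  cfg <- sim_config(tracked_lineages = 128, seed = 5)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$mutations, p2$mutations)
  expect_identical(p1$leaves, p2$leaves)
  expect_identical(simulate_bulk_wgs(p1), simulate_bulk_wgs(p2))
  v <- simulate_bulk_wgs(p1)
  expect_identical(simulate_amplicons(p1, variants = v),
                   simulate_amplicons(p2, variants = v))
})

test_that("true mosaic fractions obey lineage invariants", {
  cfg <- sim_config(tracked_lineages = 256, seed = 9)
  pop <- simulate_population(cfg)
  mut <- pop$mutations
  # MF non-increasing in origin generation
  expect_true(all(diff(mut$true_mf[order(mut$gen)]) <= 1e-12))
  # regional MFs weighted by region sizes average to the global MF
  mfr <- regional_true_mf(pop)
  w <- table(factor(pop$leaves$region,
                    levels = pop$config$region_names)) / pop$n_leaves
  expect_equal(as.numeric(mfr %*% as.numeric(w)), mut$true_mf,
               tolerance = 1e-12)
  # infinite sites: a mutation's carrier clade is a single node
  # (by construction each mutation has exactly one origin branch)
  expect_true(all(mut$node >= 1 & mut$node <= 2^mut$node_depth))
})

test_that("bulk WGS readout follows binomial sampling at the regional AAF", {
  cfg <- sim_config(tracked_lineages = 512, seed = 21)
  pop <- simulate_population(cfg)
  wgs <- simulate_bulk_wgs(pop)
  # zero regional MF implies zero alternate reads
  expect_true(all(wgs$alt_reads[wgs$true_regional_mf == 0] == 0))
  # fixation: a mutation carried by (nearly) all cells reads out near 0.5
  top <- wgs[wgs$true_regional_mf >= 0.999, ]
  if (nrow(top)) expect_true(all(abs(top$aaf - 0.5) < 0.15))
  # standardized residuals of alt reads against Binomial(depth, mf/2)
  rows <- wgs[wgs$true_regional_mf > 0 & wgs$depth > 0, ]
  p <- rows$true_regional_mf / 2
  z <- (rows$alt_reads - rows$depth * p) / sqrt(rows$depth * p * (1 - p))
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(rows)))
})

test_that("amplicon readout error and signal scale as configured", {
  cfg <- sim_config(tracked_lineages = 64, amplicon_error_rate = 0,
                    final_population_size = 2^20, seed = 31)
  pop <- simulate_population(cfg)
  v <- simulate_bulk_wgs(pop)
  amp <- simulate_amplicons(pop, variants = v)
  expect_true(all(amp$flank_error == 0))          # error rate 0
  expect_true(all(amp$depth >= cfg$amplicon_depth))
  mfr <- regional_true_mf(pop)
  zero <- mfr[cbind(amp$variant, amp$region)] == 0
  expect_true(all(amp$alt_reads[zero] == 0))      # MF 0, error 0

  # mean alternate fraction across replicate primers matches f/2
  cfg2 <- sim_config(tracked_lineages = 64, seed = 32)
  pop2 <- simulate_population(cfg2)
  v2 <- simulate_bulk_wgs(pop2)
  amp2 <- simulate_amplicons(pop2, variants = v2)
  f <- regional_true_mf(pop2)[cbind(amp2$variant, amp2$region)]
  keep <- f >= 0.01
  ratio <- (amp2$alt_reads / amp2$depth)[keep] / (f[keep] / 2)
  expect_lt(abs(mean(ratio) - 1), 3 * stats::sd(ratio) / sqrt(sum(keep)))
})

test_that("single-cell layers respect dropout, errors and UMI sampling", {
  cfg <- sim_config(tracked_lineages = 128, panel_ado_rate = 1,
                    panel_error_rate = 0, snrna_error_rate = 0,
                    seed = 41)
  pop <- simulate_population(cfg)
  panel <- pop$mutations$mut_id[pop$mutations$gen <= 4]
  sc <- simulate_single_cell_readouts(pop, panel = panel, n_cells = 60)
  # complete dropout and no errors: no mutant alleles in the panel layer
  expect_true(all(sc$panel$alt_reads == 0))
  # non-carrier cells with zero error rate have zero mutant UMIs
  carrier <- as.vector(sc$genotypes)
  expect_true(all(sc$tally$mut_umis[!carrier] == 0))
  expect_error(
    simulate_single_cell_readouts(pop, panel = "nope", n_cells = 5),
    "unknown mutation")

  # carriers with >= 1 mutant UMI match 1 - exp(-rate * p_mut)
  cfg2 <- sim_config(tracked_lineages = 64, snrna_umi_rate = 2, seed = 42)
  pop2 <- simulate_population(cfg2)
  panel2 <- pop2$mutations$mut_id[which.min(pop2$mutations$gen)]
  sc2 <- simulate_single_cell_readouts(pop2, panel = panel2,
                                       n_cells = 10000)
  car <- sc2$genotypes[, 1]
  obs <- tapply(sc2$tally$mut_umis >= 1, sc2$tally$cell, any)[
    rownames(sc2$genotypes)]
  frac <- mean(obs[car])
  expected <- 1 - exp(-2 * 0.5)
  se <- sqrt(expected * (1 - expected) / sum(car))
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("cell types follow the configured proportions and dorsal ratio", {
  cfg <- sim_config(tracked_lineages = 256, seed = 51)
  pop <- simulate_population(cfg)
  sc <- simulate_single_cell_readouts(pop, panel = pop$mutations$mut_id[1],
                                      n_cells = 6000)
  p_obs <- table(sc$cells$cell_type) / nrow(sc$cells)
  p_cfg <- cfg$celltype_proportions
  for (ct in names(p_cfg))
    expect_lt(abs(p_obs[[ct]] - p_cfg[[ct]]),
              3 * sqrt(p_cfg[[ct]] * (1 - p_cfg[[ct]]) / 6000) + 0.02)
  # within dorsal clones GluN:GABN is near 12:1
  dorsal_cells <- sc$cells[pop$leaves$dorsal[sc$cells$leaf], ]
  glun <- sum(dorsal_cells$cell_type %in% c("GluN_upper", "GluN_other"))
  gabn <- sum(dorsal_cells$cell_type %in% c("CGE_GABN", "MGE_GABN"))
  expect_gt(glun / gabn, 8)
  expect_lt(glun / gabn, 18)
})

test_that("config and tables survive a write/read round trip", {
  cfg <- sim_config(tracked_lineages = 64, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$final_population_size, cfg$final_population_size)
  expect_equal(cfg2$region_restriction_times, cfg$region_restriction_times)
  expect_equal(cfg2$celltype_proportions, cfg$celltype_proportions)

  pop <- simulate_population(cfg)
  wgs <- simulate_bulk_wgs(pop)
  f2 <- tempfile(fileext = ".tsv")
  write_table_tsv(wgs, f2)
  back <- read_table_tsv(f2)
  expect_equal(back$alt_reads, wgs$alt_reads)
  expect_equal(back$aaf, wgs$aaf, tolerance = 1e-12)
})
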