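tally_row <- function(cell, variant, mut = 1, tot = 2)
  data.frame(cell = cell, variant = rep_len(variant, length(cell)),
             total_umis = rep_len(tot, length(cell)),
             mut_umis = rep_len(mut, length(cell)))

test_that("shared-variant counts follow the two-cells-per-type rule", {
  types <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B")
  # one variant in 2 A cells and 2 B cells
  tal <- rbind(tally_row(c("a1", "a2", "b1", "b2"), "v1"))
  st <- shared_variant_counts(tal, types)
  ab <- st[st$type_a == "A" & st$type_b == "B", ]
  expect_equal(ab$n_shared, 1L)
  expect_equal(ab$n_pairs, 4L)           # 2 x 2 cross-type cell pairs
  expect_equal(ab$normalized, 0.25)

  # 2 A cells and 1 B cell: does not qualify
  tal2 <- tally_row(c("a1", "a2", "b1"), "v1")
  st2 <- shared_variant_counts(tal2, types)
  expect_equal(st2$n_shared[st2$type_a == "A" & st2$type_b == "B"], 0L)
  # within-type pair needs two distinct cells of that type
  expect_equal(st2$n_shared[st2$type_a == "A" & st2$type_b == "A"], 1L)
  expect_equal(st2$n_pairs[st2$type_a == "A" & st2$type_b == "A"], 1L)

  # empty tally gives an empty table
  st0 <- shared_variant_counts(tally_row(character(0), character(0)),
                               types)
  expect_equal(nrow(st0), 0L)
})

test_that("the bootstrap difference test is symmetric and calibrated", {
  set.seed(1)
  x <- rexp(40, 10)
  r <- shared_count_test(x, x, n_boot = 2000, seed = 2)
  expect_gt(r$p, 0.3); expect_lt(r$p, 0.7)   # identical sets: p near 0.5

  shifted <- x + 10 * sd(x)
  r2 <- shared_count_test(shifted, x, n_boot = 2000, seed = 3)
  expect_lt(r2$p, 1e-3)

  # calibration under a common distribution
  rej <- vapply(1:200, function(i) {
    a <- rexp(25, 10); b <- rexp(25, 10)
    shared_count_test(a, b, n_boot = 1000, seed = 100 + i)$p < 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(rej), 0.05 + 3 * mc_se)
  expect_gte(mean(rej), max(0, 0.05 - 3 * mc_se - 0.02))
})

test_that("minMF point, degenerate and enumerated bootstrap cases agree", {
  expect_equal(minmf_bootstrap(c(10, 4, 2), seed = 1)$minmf, 2)
  deg <- minmf_bootstrap(c(2, 2, 2), seed = 1)
  expect_equal(deg$ci_lo, 2); expect_equal(deg$ci_hi, 2)
  expect_error(minmf_bootstrap(c(1, 2)), "three")

  # exhaustive enumeration for {1,2,3}: P(min=1) = 19/27, P(2) = 7/27,
  # P(3) = 1/27
  mb <- minmf_bootstrap(c(1, 2, 3), n_boot = 30000, seed = 4)
  tab <- table(factor(mb$boot, levels = 1:3)) / 30000
  expect_equal(as.numeric(tab), c(19, 7, 1) / 27, tolerance = 0.015)

  # anti-monotone in set inclusion
  sub <- c(5, 7, 9); sup <- c(sub, 3)
  expect_lte(minmf_bootstrap(sup, n_boot = 10, seed = 1)$minmf,
             minmf_bootstrap(sub, n_boot = 10, seed = 1)$minmf)
})

test_that("clone detection recovers shared-variant structure", {
  # two disjoint variant-sharing groups -> exactly 2 clones
  tal <- rbind(tally_row(c("c1", "c2", "c3"), "v1"),
               tally_row(c("c4", "c5"), "v2"))
  cl <- louvain_clones(tal)
  expect_equal(length(unique(cl$clone)), 2L)
  expect_equal(length(unique(cl$clone[cl$cell %in% c("c1", "c2", "c3")])),
               1L)

  # a single shared variant across 5 cells -> one clone of 5
  tal2 <- tally_row(paste0("c", 1:5), "v1")
  cl2 <- louvain_clones(tal2)
  expect_equal(length(unique(cl2$clone)), 1L)

  # planted partition with cross-edges
  set.seed(5)
  cells <- paste0("c", 1:60)
  truth <- rep(1:2, each = 30)
  rows <- list()
  for (v in 1:40) {
    grp <- sample(1:2, 1)
    members <- sample(cells[truth == grp], 6)
    rows[[v]] <- tally_row(members, paste0("pv", v))
  }
  for (v in 1:4) {    # ~5% cross-group contamination
    members <- c(sample(cells[truth == 1], 2), sample(cells[truth == 2], 2))
    rows[[40 + v]] <- tally_row(members, paste0("xv", v))
  }
  tal3 <- do.call(rbind, rows)
  cl3 <- louvain_clones(tal3, seed = 6)
  ari <- adjusted_rand(cl3$clone, truth[match(cl3$cell, cells)])
  expect_gte(ari, 0.9)
})

test_that("empirical-Bayes composition shrinks and covers planted truth", {
  # symmetric check: mu0 = 0.5, sigma0 = 2, X = 5, N = 10 -> 0.5
  expect_equal((0.5 * 2 + 5) / (2 + 10), 0.5)

  set.seed(7)
  n_clones <- 60
  N <- pmin(2^sample(1:10, n_clones, replace = TRUE), 1024) + 1
  p_glun <- 0.5; p_gabn <- 0.04
  s0 <- 60   # clone-to-clone composition spread (beta-binomial)
  cells <- list(); clones <- list()
  for (k in seq_len(n_clones)) {
    pg <- rbeta(1, p_glun * s0, (1 - p_glun) * s0)
    pb <- rbeta(1, p_gabn * s0, (1 - p_gabn) * s0)
    probs <- c(GluN_upper = pg / 2, GluN_other = pg / 2,
               CGE_GABN = pb, astrocyte = max(1 - pg - pb, 0.01))
    type <- sample(names(probs), N[k], replace = TRUE, prob = probs)
    nm <- paste0("k", k, "_", seq_len(N[k]))
    cells[[k]] <- setNames(type, nm)
    clones[[k]] <- data.frame(cell = nm, clone = k)
  }
  cell_types <- unlist(cells)
  clones <- do.call(rbind, clones)
  # variants represented per clone: proportional to clone size
  tally <- do.call(rbind, lapply(seq_len(n_clones), function(k) {
    nv <- max(1, round(log2(N[k])))
    do.call(rbind, lapply(seq_len(nv), function(v)
      tally_row(sample(clones$cell[clones$clone == k],
                       max(2, N[k] %/% 2)), paste0("cv", k, "_", v))))
  }))
  comp <- eb_composition(clones, cell_types, tally, min_clone_size = 10,
                         ci = 0.95, seed = 8)
  ## the realized composition of the analyzed clones is the estimand
  analyzed <- clones$clone %in% comp$per_clone$clone
  truth_glun <- mean(cell_types[clones$cell[analyzed]] %in%
                       c("GluN_upper", "GluN_other"))
  truth_gabn <- mean(cell_types[clones$cell[analyzed]] %in%
                       c("CGE_GABN", "MGE_GABN"))
  glun <- comp$aggregate[comp$aggregate$group == "GluN", ]
  gabn <- comp$aggregate[comp$aggregate$group == "GABN", ]
  expect_gt(glun$hi, truth_glun); expect_lt(glun$lo, truth_glun)
  expect_gt(gabn$hi, truth_gabn); expect_lt(gabn$lo, truth_gabn)
  expect_lt(abs(glun$estimate - p_glun), 0.1)
  expect_lt(abs(gabn$estimate - p_gabn), 0.03)

  # shrinkage: posterior strictly between prior mean and raw fraction
  pc <- comp$per_clone
  raw <- pc$X / pc$N
  off <- abs(raw - pc$mu0) > 1e-8
  between <- (pc$posterior[off] - pc$mu0[off]) *
    (pc$posterior[off] - raw[off]) < 0
  expect_true(all(between))

  # small clones are excluded
  expect_true(all(pc$N >= 10))
})

test_that("sample-unmatched tallies yield pair-independent minMFs", {
  # control sSNVs (noise hits) have no lineage structure: minMF estimates
  # should not depend on the cell-type pair beyond bootstrap noise
  set.seed(9)
  types <- setNames(rep(c("A", "B", "C"), each = 40),
                    paste0("c", 1:120))
  # noise: every variant hits random cells regardless of type
  tal <- do.call(rbind, lapply(1:60, function(v)
    tally_row(sample(names(types), 8), paste0("nv", v))))
  mfs <- setNames(runif(60, 1, 20), paste0("nv", 1:60))
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  ests <- vapply(pairs, function(pr) {
    mut <- tal[tal$mut_umis >= 1, ]
    mut$type <- types[mut$cell]
    qual <- vapply(split(mut, mut$variant), function(d)
      sum(d$type == pr[1]) >= 2 && sum(d$type == pr[2]) >= 2, logical(1))
    shared <- names(qual)[qual]
    minmf_bootstrap(mfs[shared], n_boot = 500, seed = 10)$minmf
  }, numeric(1))
  expect_lt(diff(range(ests)), 5)   # pair means within bootstrap noise
})
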