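test_that("already-compatible matrices pass through imputation unchanged", {
  M <- cbind(s1 = c(1, 1, 0, 0), s2 = c(1, 0, 0, 0), s3 = c(0, 0, 1, 1))
  rownames(M) <- paste0("c", 1:4)
  imp <- impute_perfect_phylogeny(M)
  expect_equal(imp$genotypes, M, ignore_attr = FALSE,
               tolerance = 0)
  expect_equal(imp$cost, 0)
  expect_false(any(imp$changed))
})

test_that("the three-gamete conflict is resolved at exhaustive minimum cost", {
  # 3 cells x 2 sites exhibiting {01, 10, 11}
  post <- cbind(a = c(0.95, 0.9, 0.1), b = c(0.9, 0.05, 0.95))
  rownames(post) <- paste0("c", 1:3)
  imp <- impute_perfect_phylogeny(post)
  expect_null(mosaiclineage:::.pp_find_conflict(imp$genotypes))
  expect_equal(sum(imp$changed), 1L)
  expect_equal(imp$cost, oracle_min_flip_cost(post), tolerance = 1e-12)
})

test_that("exact imputation matches the brute-force oracle on random instances", {
  set.seed(20)
  for (r in 1:25) {
    post <- matrix(runif(12, 0.02, 0.98), nrow = sample(3:4, 1))
    colnames(post) <- paste0("s", seq_len(ncol(post)))
    rownames(post) <- paste0("c", seq_len(nrow(post)))
    imp <- impute_perfect_phylogeny(post)
    expect_null(mosaiclineage:::.pp_find_conflict(imp$genotypes))
    expect_equal(imp$cost, oracle_min_flip_cost(post), tolerance = 1e-9,
                 label = sprintf("replicate %d cost", r))
  }
})

test_that("imputation mostly corrects true genotyping errors on noisy data", {
  set.seed(21)
  cfg <- sim_config(tracked_lineages = 128, panel_depth = 30,
                    panel_ado_rate = 0.15, panel_error_rate = 5e-3,
                    seed = 210)
  pop <- simulate_population(cfg)
  panel <- pop$mutations$mut_id[pop$mutations$gen <= 7][1:20]
  sc <- simulate_single_cell_readouts(pop, panel = panel, n_cells = 200)
  truth <- sc$genotypes * 1
  params <- list(p_mut = 0.5, error_rate = cfg$panel_error_rate)
  calls <- genotype_batch(sc$panel, params)
  post <- genotype_matrix(calls)[rownames(truth), colnames(truth)]
  imp <- impute_perfect_phylogeny(post, max_exact_sites = 0)
  expect_null(mosaiclineage:::.pp_find_conflict(imp$genotypes))
  # the entries the imputation rewrites should be genuine call errors
  call_errors <- (post >= 0.5) != (truth == 1)
  if (sum(imp$changed) > 0) {
    frac_true_errors <- mean(call_errors[imp$changed])
    expect_gte(frac_true_errors, 0.9)
  }
  # and the imputed matrix should be closer to the truth than the calls
  expect_lte(sum(imp$genotypes != truth), sum(call_errors))
})

test_that("tree construction realizes carrier sets as clades", {
  # one site carried by cells {1,2} of 4: a single cherry, parsimony 1
  M <- cbind(sA = c(1, 1, 0, 0))
  rownames(M) <- paste0("c", 1:4)
  tr <- build_tree(M)
  expect_equal(tr$parsimony, 1L)
  clade <- ape::extract.clade(tr$phylo, tr$variants$node[1])
  expect_setequal(clade$tip.label, c("c1", "c2"))

  # nested sites: B's branch sits below A's
  M2 <- cbind(A = c(1, 1, 1, 0), B = c(1, 1, 0, 0))
  rownames(M2) <- paste0("c", 1:4)
  tr2 <- build_tree(M2)
  nodeA <- tr2$variants$node[tr2$variants$site == "A"]
  nodeB <- tr2$variants$node[tr2$variants$site == "B"]
  anc <- ape::nodepath(tr2$phylo, from = tr2$n_tips + 1, to = nodeB)
  expect_true(nodeA %in% anc)
  # incompatible input is refused
  M3 <- cbind(a = c(1, 1, 0), b = c(0, 1, 1))
  rownames(M3) <- paste0("c", 1:3)
  expect_error(build_tree(M3), "not compatible")
})

test_that("noiseless genotypes reproduce the simulated genealogy exactly", {
  skip_if_not_installed("phangorn")
  set.seed(22)
  for (rep_seed in c(301, 302)) {
    cfg <- sim_config(tracked_lineages = 64, seed = rep_seed)
    pop <- simulate_population(cfg)
    panel <- pop$mutations$mut_id[pop$mutations$gen <= pop$D]
    sc <- simulate_single_cell_readouts(pop, panel = panel, n_cells = 40)
    geno <- sc$genotypes * 1
    tr <- build_tree(geno)
    truth <- oracle_true_tree(pop, sc$cells$cell, sc$cells$leaf)
    rf <- phangorn::RF.dist(ape::unroot(tr$phylo), ape::unroot(truth))
    expect_equal(rf, 0)
  }
})

test_that("generation-to-week conversion interpolates the growth table", {
  expect_equal(generations_to_pmw(0), 0)
  expect_equal(generations_to_pmw(13), 8)    # 1 -> 2^26 over 16 weeks
  expect_equal(generations_to_pmw(26), 16)
  expect_warning(out <- generations_to_pmw(40), "clamped")
  expect_equal(out, 16)
})

test_that("coalescent fit handles the mutation-free star tree", {
  # all cells identical: a star genealogy with zero mutations anywhere
  M <- matrix(0L, 12, 2, dimnames = list(paste0("c", 1:12), c("s1", "s2")))
  M[, 1] <- 1L                          # one shared site on the root
  tr <- build_tree(M)
  expect_equal(length(tr$root_sites), 1L)
  fit <- suppressWarnings(fit_coalescent_too(
    tr, n_chains = 2, n_iter = 400, n_warmup = 300,
    on_nonmixing = "warn", seed = 5))
  # with no branch mutations the TOO posteriors concentrate early
  expect_lt(fit$variant_too$too[1], 2)
})

test_that("TOO ordering respects ancestry in every fit", {
  set.seed(23)
  cfg <- sim_config(tracked_lineages = 256, seed = 400)
  pop <- simulate_population(cfg)
  sc <- simulate_single_cell_readouts(pop, panel = pop$mutations$mut_id,
                                      n_cells = 60)
  tr <- build_tree(impute_perfect_phylogeny(sc$genotypes * 1,
                                            max_exact_sites = 0))
  fit <- suppressWarnings(fit_coalescent_too(
    tr, n_chains = 2, n_iter = 500, n_warmup = 300,
    on_nonmixing = "warn", seed = 6))
  # a variant on a descendant branch never predates its ancestor
  v <- fit$variant_too
  phy <- tr$phylo
  parent <- rep(NA_integer_, tr$n_tips + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  for (i in seq_len(nrow(v))) {
    anc <- parent[v$node[i]]
    while (!is.na(anc)) {
      j <- which(v$node == anc)
      if (length(j))
        expect_lte(v$too[j[1]], v$too[i] + 1e-9)
      anc <- parent[anc]
    }
  }
})

test_that("RRS separates exchangeable from subtree-segregated regions", {
  set.seed(24)
  # balanced tree, regions independent of topology: RRS near 1
  M <- matrix(0L, 24, 12)
  rownames(M) <- paste0("c", 1:24)
  colnames(M) <- paste0("s", 1:12)
  for (k in 1:6) M[((k - 1) * 4 + 1):(k * 4), k] <- 1L
  for (k in 1:6) M[((k - 1) * 4 + 1):((k - 1) * 4 + 2), 6 + k] <- 1L
  tr <- build_tree(M)
  reg_rand <- setNames(sample(c("BA17", "BA18"), 24, replace = TRUE),
                       rownames(M))
  r1 <- compute_rrs(tr, reg_rand, n_boot = 500, seed = 1)
  expect_true(r1$ci_lo <= 1 && r1$ci_hi >= 1)

  # each region a subtree: RRS > 1 and CI excludes 1
  reg_split <- setNames(rep(c("BA17", "BA18"), each = 12), rownames(M))
  r2 <- compute_rrs(tr, reg_split, n_boot = 500, seed = 2)
  expect_gt(r2$rrs, 1)
  expect_gt(r2$ci_lo, 1)

  # permutation of labels returns to the null band
  perm_rrs <- replicate(50, {
    reg_p <- setNames(sample(reg_split), names(reg_split))
    compute_rrs(tr, reg_p, n_boot = 2, seed = NULL)$rrs
  })
  band <- quantile(perm_rrs, c(0.025, 0.975))
  expect_true(r1$rrs >= band[1] - 0.2 && r1$rrs <= band[2] + 0.2)

  # degenerate clade: all cells in one region
  reg_one <- setNames(rep("BA17", 24), rownames(M))
  expect_message(r3 <- compute_rrs(tr, reg_one, n_boot = 10),
                 "undefined")
  expect_true(is.na(r3$rrs))
})

test_that("k-means recovers planted dispersion modes", {
  set.seed(25)
  centers <- diag(5)[rep(1:5, each = 5), ] * 4
  mat <- centers + matrix(rnorm(125, 0, 0.05), 25, 5)
  rownames(mat) <- paste0("v", 1:25)
  km <- kmeans_dispersion(mat, k = 5, seed = 3)
  expect_equal(km$k, 5L)
  expect_equal(adjusted_rand(km$cluster, rep(1:5, each = 5)), 1)

  km1 <- kmeans_dispersion(mat, k = 1, seed = 3)
  expect_true(all(km1$cluster == 1))
  expect_equal(as.numeric(km1$centers), colMeans(mat))

  zero <- matrix(0, 8, 3, dimnames = list(paste0("v", 1:8), NULL))
  expect_message(km0 <- kmeans_dispersion(zero, k = 5, seed = 3),
                 "distinct")
  expect_equal(km0$k, 1L)
  expect_error(kmeans_dispersion(mat[1:3, ], k = 5), "exceeds")
})
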