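# Independent oracles and small constructors used across the suite.

# Exhaustive minimum-cost compatible matrix: enumerates every binary
# matrix of the same dimensions (feasible only for tiny instances) and
# returns the minimum total |posterior - value| flip cost among matrices
# passing the rooted three-gamete test.  Independent of the package's
# branch-and-bound solver.
oracle_min_flip_cost <- function(posterior, threshold = 0.5) {
  M0 <- (posterior >= threshold) * 1L
  n <- length(M0)
  stopifnot(n <= 16)
  compatible <- function(M) {
    ns <- ncol(M)
    if (ns < 2) return(TRUE)
    for (i in 1:(ns - 1)) for (j in (i + 1):ns) {
      p11 <- any(M[, i] == 1 & M[, j] == 1)
      p10 <- any(M[, i] == 1 & M[, j] == 0)
      p01 <- any(M[, i] == 0 & M[, j] == 1)
      if (p11 && p10 && p01) return(FALSE)
    }
    TRUE
  }
  best <- Inf
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[1:n])
    M <- matrix(bits, nrow(M0), ncol(M0))
    if (!compatible(M)) next
    cost <- sum(abs(posterior - M)[M != M0])
    if (cost < best) best <- cost
  }
  best
}

# Detection probability for the amplicon null by exhaustive convolution
# of the two binomials (mutant reads > error reads AND mutant fraction
# above the floor).
oracle_detect_prob <- function(reads, p_mut, p_err, floor_reads) {
  kmax <- min(reads, stats::qbinom(1 - 1e-12, reads, max(p_mut, p_err)) + 50)
  pm <- stats::dbinom(0:kmax, reads, p_mut)
  Fe <- stats::pbinom(0:kmax, reads, p_err)
  tot <- 0
  for (k in 1:kmax) {            # need mutant > error and mutant > floor
    if (k <= floor_reads) next
    tot <- tot + pm[k + 1] * Fe[k]   # P(err <= k - 1) = Fe[k-1+1]
  }
  tot
}

# True genealogy of sampled cells built straight from clone ancestry
# paths (newick text), with branch lengths equal to the number of
# mutations on each binary-tree segment; zero-length internal edges are
# collapsed.  Independent of build_tree's carrier-set construction.
oracle_true_tree <- function(pop, cell_names, leaves) {
  D <- pop$D
  mut <- pop$mutations[pop$mutations$gen <= D, , drop = FALSE]
  seg_len <- function(d, v) sum(mut$gen == d & mut$node == v)
  # returns list(str = newick subtree, carry = mutations accumulated on
  # collapsed single-child segments above the subtree's top node)
  rec <- function(d, v, idx) {
    if (d == D) {
      if (length(idx) == 1) return(list(str = cell_names[idx], carry = 0))
      return(list(str = paste0("(", paste0(cell_names[idx], ":0",
                                           collapse = ","), ")"),
                  carry = 0))
    }
    parts <- character(0)
    for (child in c(2L * v - 1L, 2L * v)) {
      block <- 2L^(D - d - 1L)
      lo <- (child - 1L) * block + 1L
      hi <- child * block
      sub <- idx[leaves[idx] >= lo & leaves[idx] <= hi]
      if (!length(sub)) next
      r <- rec(d + 1L, child, sub)
      parts <- c(parts, paste0(r$str, ":", seg_len(d + 1L, child) + r$carry))
    }
    if (length(parts) == 1) {
      # unary node: pass the single child's edge length upward
      len <- as.numeric(sub("^.*:", "", parts))
      return(list(str = sub(":[0-9.]+$", "", parts), carry = len))
    }
    list(str = paste0("(", paste(parts, collapse = ","), ")"), carry = 0)
  }
  r <- rec(0L, 1L, seq_along(leaves))
  tr <- ape::read.tree(text = paste0(r$str, ";"))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  ape::di2multi(tr, tol = 1e-9)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Random window generator for the artifact filter tests.
random_windows <- function(n, center = "T",
                           probs = c(A = .25, C = .25, G = .25, T = .25)) {
  vapply(seq_len(n), function(i) {
    ch <- sample(names(probs), 41, replace = TRUE, prob = probs)
    ch[21] <- center
    paste(ch, collapse = "")
  }, character(1))
}
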