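# Independent oracles used to freeze expected values; each deliberately
# avoids the package's own implementation path.

# exhaustive enumeration of the net repeat change over t divisions:
# iterates over all 5^t per-division outcomes
enumerate_step_pmf <- function(model, t) {
  kern_k <- -2:2
  d1 <- per_division_pmf(model)
  kern_p <- d1$p
  grids <- rep(list(seq_len(5L)), t)
  combos <- as.matrix(expand.grid(grids))
  net <- rowSums(matrix(kern_k[combos], nrow = nrow(combos)))
  prob <- apply(matrix(kern_p[combos], nrow = nrow(combos)), 1, prod)
  tapply(prob, net, sum)
}

# closed-form pmf via multinomial sums over event counts (independent of
# the convolution code); max_events truncates negligible tails
multinomial_step_pmf <- function(model, t, k, max_events = 14L) {
  r <- model$single_to_double_odds
  p1 <- model$mu * r / (2 * (r + 1)); p2 <- model$mu / (2 * (r + 1))
  p0 <- 1 - model$mu
  total <- 0
  for (n1p in 0:max_events) for (n1m in 0:(max_events - n1p))
    for (n2p in 0:(max_events - n1p - n1m))
      for (n2m in 0:(max_events - n1p - n1m - n2p)) {
        if (n1p - n1m + 2 * (n2p - n2m) != k) next
        m <- n1p + n1m + n2p + n2m
        if (m > t) next
        total <- total +
          exp(lchoose(t, m) + lfactorial(m) -
                lfactorial(n1p) - lfactorial(n1m) -
                lfactorial(n2p) - lfactorial(n2m) +
                n1p * log(p1) + n1m * log(p1) +
                n2p * log(p2) + n2m * log(p2) + (t - m) * log(p0))
      }
  total
}

# naive O(n^3) Saitou-Nei neighbor joining, building newick text directly
naive_nj <- function(D) {
  labels <- rownames(D)
  nodes <- labels
  repeat {
    n <- nrow(D)
    if (n == 3L) break
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    ij <- idx[order(idx[, 1], idx[, 2])[1], ]
    i <- ij[1]; j <- ij[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    newlab <- sprintf("(%s:%.10f,%s:%.10f)", nodes[i], li, nodes[j], lj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newlab)
    dimnames(D2) <- list(nodes, nodes)
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                 nodes[1], la, nodes[2], lb, nodes[3], lc)
  ape::read.tree(text = txt)
}

# exhaustive hypergeometric upper tail by subset enumeration
enumerate_hypergeom_tail <- function(N, B, n, b) {
  pop <- c(rep(1L, B), rep(0L, N - B))
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(pop[s]) >= b)
  mean(hits)
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# small multi-population scenario-C simulation used by several tests
small_sim <- function(seed, age = 340, scenario = "monoclonal_conversion",
                      n_crypts = 2, cells = 6, n_wc = 8, groups = list()) {
  simulate_mouse(sim_config(
    scenario = scenario, mouse_age_days = age, n_crypts = n_crypts,
    cells_per_crypt = cells, n_whole_crypts = n_wc,
    other_groups = groups, seed = seed))
}
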