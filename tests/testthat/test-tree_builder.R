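test_that("three-taxon NJ solves the three-point equations exactly", {
  D <- matrix(c(0, 7, 9, 7, 0, 12, 9, 12, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(pd, D, tolerance = 1e-12)
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  fix <- ape::read.tree(text = "((a:3,b:2):4,(c:5,d:1):2);")
  D <- ape::cophenetic.phylo(fix)
  tr <- nj_tree(D[order(rownames(D)), order(colnames(D))])
  expect_true(same_topology(fix, tr))
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(pd, D, tolerance = 1e-9)
})

test_that("NJ agrees with the naive Saitou-Nei oracle", {
  for (seed in 1:6) {
    ra <- random_additive(sample(5:8, 1), seed = 100 + seed)
    tr <- nj_tree(ra$D)
    oracle <- naive_nj(ra$D)
    expect_true(same_topology(tr, oracle))
    ids <- rownames(ra$D)
    expect_equal(ape::cophenetic.phylo(tr)[ids, ids],
                 ape::cophenetic.phylo(oracle)[ids, ids], tolerance = 1e-8)
  }
})

test_that("invalid distance input is rejected", {
  m <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(m), "symmetric")
  m2 <- matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(m2), "negative")
})

test_that("rooting at the tail leaf preserves leaf-to-leaf path lengths", {
  ra <- random_additive(7, seed = 42)
  tr <- nj_tree(ra$D)
  rooted <- root_tree(tr, rownames(ra$D)[1])
  ids <- rownames(ra$D)
  expect_equal(ape::cophenetic.phylo(rooted)[ids, ids],
               ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-9)
  expect_error(root_tree(tr, "nope"), "not a leaf")
})

test_that("negative branch lengths are clamped with bounded depth effect", {
  # a slightly non-additive matrix that forces a negative NJ branch
  D <- matrix(c(0, 2, 10, 10,
                2, 0, 10, 10,
                10, 10, 0, 1,
                10, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.1  # squeeze
  tr <- nj_tree(D)
  rooted <- root_tree(tr, "a")
  expect_true(all(rooted$edge.length >= 0))
  nd <- node_depths(rooted)
  parent_depth <- nd$depth[match(rooted$edge[, 1], nd$node)]
  child_depth <- nd$depth[match(rooted$edge[, 2], nd$node)]
  expect_true(all(child_depth - parent_depth >= -1e-12))
})

test_that("depths are root-to-node path sums", {
  # rooting at leaf a puts the root at the star's hub, so every other
  # leaf hangs one 100-division branch below it
  star <- ape::read.tree(text = "(a:100,b:100,c:100,d:100):0;")
  star <- root_tree(ape::unroot(star), "a")
  dep <- leaf_depths(star, exclude_root_sample = FALSE)
  expect_equal(unname(dep[c("b", "c", "d")]), c(100, 100, 100))

  cat_tree <- ape::read.tree(text = "(((a:2,b:3):5,c:1):4,d:7);")
  dep2 <- leaf_depths(cat_tree, exclude_root_sample = FALSE)
  expect_equal(unname(dep2[c("a", "b", "c", "d")]), c(11, 12, 5, 7))
})

test_that("computed MRCSC returns the join node of a leaf subset", {
  tr <- ape::read.tree(text = "(((a:2,b:3):5,c:1):4,d:7);")
  expect_equal(computed_mrcsc(tr, c("a", "b"))$depth, 9)   # depth of their join
  expect_equal(computed_mrcsc(tr, "a")$node, 1L)           # singleton: the leaf
  expect_equal(computed_mrcsc(tr, "a")$depth, 11)
  expect_equal(computed_mrcsc(tr, c("a", "b", "c", "d"))$depth, 0)
  expect_error(computed_mrcsc(tr, character(0)), "empty")
})

test_that("median signature takes per-locus medians with ties toward the root", {
  sig <- as_signatures(rbind(c(0L, 1L, -2L), c(0L, 2L, -1L), c(1L, 5L, NA)))
  med <- median_signature(sig)
  expect_equal(unname(med[1, ]), c(0L, 2L, -1L))  # -1.5 resolves toward 0
  two <- as_signatures(rbind(c(1L, -2L), c(2L, -1L)))
  expect_equal(unname(median_signature(two)[1, ]), c(1L, -1L))
  one <- as_signatures(matrix(c(3L, -1L), 1))
  expect_equal(unname(median_signature(one)[1, ]), c(3L, -1L))
})

test_that("newick write/read round-trips topology, lengths and labels", {
  ra <- random_additive(6, seed = 9)
  tr <- ra$tree
  tr$tip.label[2] <- "sample with spaces"
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_setequal(tr2$tip.label, tr$tip.label)
  ids <- tr$tip.label
  expect_equal(ape::cophenetic.phylo(tr2)[ids, ids],
               ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-9)
  expect_error(read_newick(tempfile()), "not found")
})

test_that("whole-crypt depth matches the computed MRCSC of its cells", {
  # append, per crypt, a bulk sample built as the median of the crypt's
  # cells, and compare its reconstructed depth with the computed MRCSC
  rel_diff <- c()
  for (seed in 1:5) {
    out <- small_sim(seed = 700 + seed, age = 200, n_crypts = 4, cells = 5,
                     n_wc = 0)
    sig <- out$true_signatures
    lab <- out$labels
    extra <- lapply(sprintf("crypt%02d", 1:4), function(cid) {
      cells <- lab$sample_id[!is.na(lab$crypt) & lab$crypt == cid]
      median_signature(sig[cells, , drop = FALSE])
    })
    aug <- rbind(unclass(sig), do.call(rbind, lapply(extra, unclass)))
    rownames(aug)[(nrow(sig) + 1):nrow(aug)] <- sprintf("bulk%02d", 1:4)
    aug <- as_signatures(aug, channels = attr(sig, "channels"))
    dm <- distance_matrix(aug, mutation_model(), t_max = 700)
    tree <- root_tree(nj_tree(dm), "tail")
    dep <- leaf_depths(tree)
    for (i in 1:4) {
      cells <- lab$sample_id[!is.na(lab$crypt) & lab$crypt == sprintf("crypt%02d", i)]
      mr <- computed_mrcsc(tree, cells)$depth
      rel_diff <- c(rel_diff, abs(dep[[sprintf("bulk%02d", i)]] - mr) / max(mr, 1))
    }
  }
  expect_lt(mean(rel_diff), 0.15)
})
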