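#' @importFrom stats phyper p.adjust quantile
NULL

#' Hypergeometric tail probability of clade enrichment
#'
#' Probability of observing `b` or more cells of the focal type in a
#' subtree of `n` leaves, when the `n` leaves are a random sample from the
#' `N` cells of which `B` are of the focal type:
#' `p = sum_{i=b}^{min(n,B)} C(B,i) C(N-B,n-i) / C(N,n)`.
#'
#' @param N Total number of cells on the tree.
#' @param B Number of cells of the focal type.
#' @param n Number of leaves in the subtree.
#' @param b Number of subtree leaves of the focal type.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, B, n, b) {
  if (any(c(N, B, n, b) < 0) || B > N || n > N || b > n || b > B)
    stop("inconsistent hypergeometric counts", call. = FALSE)
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

# tip sets of every internal node, by accumulation over the edge list
.subtree_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  tips <- rep(list(integer(0)), n_all)
  for (i in seq_len(n_tip)) tips[[i]] <- i
  # postorder guarantees every child subtree is complete before its parent
  edge <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    tips[[par]] <- c(tips[[par]], tips[[chi]])
  }
  tips
}

#' Clade enrichment test over a lineage tree
#'
#' For every internal node of a rooted lineage tree, tests the null
#' hypothesis of no association between the node's subtree and a
#' dichotomous cell classification, using the hypergeometric upper tail
#' ([hypergeom_tail()]). The tail/root leaf, being a rooting device rather
#' than a sampled cell, is excluded from the population.
#'
#' @param tree A rooted `phylo` (see [root_tree()]).
#' @param labels Named character vector mapping every leaf label to its
#'   group.
#' @param group The focal group `T`.
#' @return An `enrichment_result` data frame with one row per internal
#'   node: `node`, `N`, `B`, `n`, `b`, `p`. Pass it to [fdr_select()] for
#'   significance flags.
#' @export
tree_enrichment <- function(tree, labels, group) {
  stopifnot(inherits(tree, "phylo"))
  rs <- attr(tree, "root_sample_id")
  leaves <- setdiff(tree$tip.label, rs)
  missing <- setdiff(leaves, names(labels))
  if (length(missing))
    stop("unlabeled leaves: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!group %in% labels[leaves])
    stop("group '", group, "' labels no leaf on the tree", call. = FALSE)
  is_focal <- setNames(labels[leaves] == group, leaves)
  N <- length(leaves)
  B <- sum(is_focal)
  tipsets <- .subtree_tips(tree)
  n_tip <- ape::Ntip(tree)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  res <- do.call(rbind, lapply(internal, function(node) {
    labs <- tree$tip.label[tipsets[[node]]]
    labs <- setdiff(labs, rs)
    n <- length(labs)
    if (n == 0L) return(NULL)
    b <- sum(is_focal[labs])
    data.frame(node = node, N = N, B = B, n = n, b = b,
               p = hypergeom_tail(N, B, n, b), stringsAsFactors = FALSE)
  }))
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "group") <- group
  res
}

#' Benjamini-Hochberg selection of significant clades
#'
#' Applies the Benjamini-Hochberg step-up procedure at level `q` across
#' all tested internal nodes of one tree for one focal group, and flags
#' the surviving nodes. The headline clustering p-value of the tree (the
#' "most significant p value" of a bold branch) is attached as the
#' `headline_p` attribute: the minimum raw p among significant nodes, or
#' `NA` when none survive.
#'
#' @param results An `enrichment_result` from [tree_enrichment()].
#' @param q FDR level (default 0.20).
#' @return The results with added columns `p_adj` and `significant`.
#' @export
fdr_select <- function(results, q = 0.20) {
  stopifnot(nrow(results) >= 1L)
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  results$significant <- results$p_adj <= q
  attr(results, "q") <- q
  attr(results, "headline_p") <-
    if (any(results$significant)) min(results$p[results$significant]) else NA_real_
  results
}

#' Concordance of technical replicate pairs on the tree
#'
#' PCR repeats of one biological sample should sit next to each other on
#' the lineage tree and share similar depths. For each replicate pair the
#' leaf-to-leaf path distance and absolute depth difference are computed
#' and compared against randomly resampled pairs of leaves from the same
#' tissue, giving an empirical percentile of the mean replicate path
#' distance under the random-pair null.
#'
#' @param tree A rooted `phylo`.
#' @param replicate_pairs Data frame with columns `a`, `b` (leaf labels).
#' @param tissues Optional named character vector mapping leaf labels to
#'   tissue; random null pairs are drawn within tissue. Default: one pool.
#' @param n_resample Number of random pairs for the null distribution.
#' @return List with `pairs` (per-pair path distance and depth
#'   difference), `null_mean_distances`, and `percentile` (fraction of
#'   null means at or below the observed replicate mean).
#' @export
replicate_concordance <- function(tree, replicate_pairs, tissues = NULL,
                                  n_resample = 1000L) {
  stopifnot(inherits(tree, "phylo"))
  if (nrow(replicate_pairs) == 0L)
    return(list(pairs = data.frame(), null_mean_distances = numeric(0),
                percentile = NA_real_))
  missing <- setdiff(c(replicate_pairs$a, replicate_pairs$b), tree$tip.label)
  if (length(missing))
    stop("replicate sample(s) not on tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pd <- ape::dist.nodes(tree)[seq_len(ape::Ntip(tree)), seq_len(ape::Ntip(tree))]
  dimnames(pd) <- list(tree$tip.label, tree$tip.label)
  dep <- leaf_depths(tree, exclude_root_sample = FALSE)
  pairs <- data.frame(
    a = replicate_pairs$a, b = replicate_pairs$b,
    path_distance = pd[cbind(replicate_pairs$a, replicate_pairs$b)],
    depth_difference = abs(dep[replicate_pairs$a] - dep[replicate_pairs$b]),
    stringsAsFactors = FALSE, row.names = NULL)

  rs <- attr(tree, "root_sample_id")
  pool <- setdiff(tree$tip.label, rs)
  if (is.null(tissues)) tissues <- setNames(rep("all", length(pool)), pool)
  obs_tissue <- tissues[replicate_pairs$a]
  null_means <- vapply(seq_len(n_resample), function(i) {
    mean(vapply(obs_tissue, function(ti) {
      cand <- pool[tissues[pool] == ti]
      if (length(cand) < 2L) cand <- pool
      s <- sample(cand, 2L)
      pd[s[1], s[2]]
    }, 0))
  }, 0)
  list(pairs = pairs,
       null_mean_distances = null_means,
       percentile = mean(null_means <= mean(pairs$path_distance)))
}
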