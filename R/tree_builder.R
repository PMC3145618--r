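#' @importFrom ape nj root getMRCA node.depth.edgelength write.tree read.tree
#'   Ntip dist.nodes
NULL

#' Neighbor-joining lineage tree
#'
#' Builds the unrooted Saitou-Nei neighbor-joining tree from a division
#' distance matrix. Leaves are the samples; branch lengths are in cell
#' divisions.
#'
#' @param dist An `ms_dist` object (see [distance_matrix()]) or a symmetric
#'   non-negative numeric matrix with row/column names.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  m <- if (inherits(dist, "ms_dist")) dist$d else dist
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance input must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(m < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  storage.mode(m) <- "double"
  ape::nj(m)
}

#' Root a lineage tree at the tail (zygote) sample
#'
#' Re-roots the tree at the attachment point of the tail leaf, whose
#' signature is all-zero by construction and therefore stands in for the
#' zygote. Negative branch lengths produced by neighbor joining are
#' clamped to zero; the number of clamped edges and their summed magnitude
#' are recorded in the attributes `clamped_edges` / `clamped_total`.
#'
#' @param tree An unrooted `phylo`.
#' @param root_sample_id Leaf label of the tail/root sample.
#' @return A rooted `phylo` whose root node is the tail attachment point.
#' @export
root_tree <- function(tree, root_sample_id) {
  stopifnot(inherits(tree, "phylo"))
  if (!root_sample_id %in% tree$tip.label)
    stop("root sample '", root_sample_id, "' is not a leaf of the tree",
         call. = FALSE)
  rooted <- ape::root(tree, outgroup = root_sample_id, resolve.root = TRUE)
  neg <- rooted$edge.length < 0
  attr(rooted, "clamped_edges") <- sum(neg)
  attr(rooted, "clamped_total") <- -sum(rooted$edge.length[neg])
  rooted$edge.length[neg] <- 0
  attr(rooted, "root_sample_id") <- root_sample_id
  rooted
}

#' Depths of all tree nodes
#'
#' Depth of a node is the sum of branch lengths on its path from the root,
#' i.e. the estimated number of cell divisions since the zygote.
#'
#' @param tree A rooted `phylo`.
#' @return Data frame with columns `node` (ape node number), `label`
#'   (sample id for leaves, `""` for internal nodes), `is_leaf`, `depth`.
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dep <- ape::node.depth.edgelength(tree)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  data.frame(
    node = seq_len(n_all),
    label = c(tree$tip.label, rep("", tree$Nnode)),
    is_leaf = seq_len(n_all) <= n_tip,
    depth = dep,
    stringsAsFactors = FALSE
  )
}

#' Leaf depths as a named vector
#'
#' @param tree A rooted `phylo`.
#' @param exclude_root_sample Drop the tail/root leaf (if the tree was
#'   rooted with [root_tree()]) from the result.
#' @return Named numeric vector of root-to-leaf path lengths (divisions).
#' @export
leaf_depths <- function(tree, exclude_root_sample = TRUE) {
  nd <- node_depths(tree)
  out <- setNames(nd$depth[nd$is_leaf], nd$label[nd$is_leaf])
  rs <- attr(tree, "root_sample_id")
  if (exclude_root_sample && !is.null(rs)) out <- out[names(out) != rs]
  out
}

#' Computed most recent common stem cell (MRCSC) of a leaf set
#'
#' The most recent common ancestor node of the given leaves; for cells
#' sampled from one crypt this node estimates the crypt's most recent
#' common stem cell, and its depth the number of divisions from the zygote
#' to that stem cell.
#'
#' @param tree A rooted `phylo`.
#' @param leaf_subset Character vector of leaf labels (non-empty).
#' @return List with `node` (ape node number) and `depth`.
#' @export
computed_mrcsc <- function(tree, leaf_subset) {
  stopifnot(inherits(tree, "phylo"))
  if (length(leaf_subset) == 0L) stop("empty leaf subset", call. = FALSE)
  missing <- setdiff(leaf_subset, tree$tip.label)
  if (length(missing))
    stop("leaves not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(unique(leaf_subset)) == 1L) {
    node <- match(leaf_subset[1], tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, unique(leaf_subset))
  }
  nd <- node_depths(tree)
  list(node = node, depth = nd$depth[nd$node == node])
}

# integer median with even-count ties resolved toward zero (the root state)
.median_toward_zero <- function(v) {
  m <- median(v)
  if (m == round(m)) return(as.integer(m))
  cand <- c(floor(m), ceiling(m))
  as.integer(cand[which.min(abs(cand))])
}

#' Median genomic signature of a set of cells
#'
#' Per-channel median deviation across the cells in which the channel was
#' measured; even-count ties are resolved toward zero (the root state),
#' the parsimony-consistent choice. The median signature of a crypt's
#' sampled cells approximates the signature of the crypt's MRCSC, and is
#' how whole-crypt bulk DNA is emulated by the simulator.
#'
#' @param signatures An `ms_signatures` matrix (cells in rows).
#' @return An `ms_signatures` matrix with a single row named `"median"`.
#' @export
median_signature <- function(signatures) {
  stopifnot(is.matrix(signatures), nrow(signatures) >= 1L)
  med <- vapply(seq_len(ncol(signatures)), function(j) {
    v <- signatures[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_integer_ else .median_toward_zero(v)
  }, 0L)
  out <- matrix(med, nrow = 1L,
                dimnames = list("median", colnames(signatures)))
  as_signatures(out, channels = attr(signatures, "channels"))
}

#' Write / read a lineage tree in Newick format
#'
#' Thin wrappers preserving topology, branch lengths and labels; labels
#' containing spaces or Newick metacharacters are single-quoted on write
#' and unquoted on read, per the Newick standard.
#'
#' @param tree A `phylo`.
#' @param path File path.
#' @return `read_newick()` returns the `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  needs_quote <- grepl("[][ \t(),:;']", labs)
  if (any(needs_quote)) {
    ph <- sprintf(".QTIP%d.", seq_along(labs))
    tree$tip.label <- ifelse(needs_quote, ph, labs)
    txt <- ape::write.tree(tree)
    for (i in which(needs_quote))
      txt <- sub(ph[i], paste0("'", gsub("'", "''", labs[i]), "'"),
                 txt, fixed = TRUE)
    writeLines(txt, path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file '", path, "' not found", call. = FALSE)
  txt <- paste(readLines(path), collapse = "")
  if (!nzchar(txt)) stop("empty Newick file '", path, "'", call. = FALSE)
  # extract single-quoted labels, substitute placeholders, restore after parse
  quoted <- regmatches(txt, gregexpr("'(''|[^'])*'", txt))[[1]]
  restored <- character(0)
  if (length(quoted)) {
    restored <- gsub("''", "'", substr(quoted, 2, nchar(quoted) - 1))
    for (i in seq_along(quoted))
      txt <- sub(quoted[i], sprintf(".QTIP%d.", i), txt, fixed = TRUE)
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr)) stop("could not parse Newick file '", path, "'", call. = FALSE)
  for (i in seq_along(restored))
    tr$tip.label[tr$tip.label == sprintf(".QTIP%d.", i)] <- restored[i]
  tr
}
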