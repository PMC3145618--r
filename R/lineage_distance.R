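#' Maximum-likelihood divisions separating two genomic signatures
#'
#' For every locus-allele channel measured in both samples the per-channel
#' deviation difference `d = a - b` is the net repeat change accumulated
#' over the `t` divisions on the cell-lineage path between the two cells.
#' Under the stepwise mutation model the channels are independent, so the
#' log-likelihood of `t` is the sum over shared channels of
#' `log P(d | t)` with `P(. | t)` the t-fold convolution of the
#' per-division net-change distribution. The estimate is the maximiser of
#' this sum over the integer grid `0..t_max`; ties pick the smallest `t`.
#'
#' @param a,b Integer deviation vectors (rows of an `ms_signatures`
#'   matrix), `NA` = unmeasured.
#' @param model A [mutation_model()].
#' @param t_max Largest candidate number of divisions (grid upper end).
#' @param min_shared Minimum number of loci measured in both samples for
#'   the distance to be defined.
#' @param channels Optional channel table used to count shared *loci*
#'   (not channels) against `min_shared`; by default every channel is its
#'   own locus.
#' @param loglik_table Optional precomputed [step_loglik_table()]; pass it
#'   when estimating many pairs under one model.
#' @return The estimated integer number of divisions, or `NA` (with
#'   attribute `reason = "too_few_shared_loci"`) for an undefined pair.
#' @export
pair_ml_divisions <- function(a, b, model, t_max = 3000L, min_shared = 10L,
                              channels = NULL, loglik_table = NULL) {
  shared <- which(!is.na(a) & !is.na(b))
  n_loci <- if (!is.null(channels) && !is.null(names(a)))
    length(unique(channels$locus[match(names(a)[shared], channels$channel)]))
  else length(shared)
  if (n_loci < min_shared) {
    out <- NA_integer_
    attr(out, "reason") <- "too_few_shared_loci"
    return(out)
  }
  d <- abs(a[shared] - b[shared])
  counts <- tabulate(d + 1L, nbins = max(d) + 1L)
  if (is.null(loglik_table))
    loglik_table <- step_loglik_table(model, t_max, max(d))
  if (ncol(loglik_table) < max(d) + 1L)
    stop("loglik_table does not cover the observed deviation differences",
         call. = FALSE)
  ll <- loglik_table[, seq_along(counts), drop = FALSE] %*% counts
  as.integer(which.max(ll) - 1L)  # which.max returns the first (smallest t) tie
}

#' Pairwise division-distance matrix
#'
#' Applies [pair_ml_divisions()] to every pair of signatures. Pairs with
#' fewer than `min_shared` shared loci are imputed as the maximum defined
#' distance in the matrix (and listed in the `flagged_pairs` attribute),
#' keeping the matrix total for neighbor joining.
#'
#' @param signatures An `ms_signatures` matrix (>= 3 rows).
#' @param model A [mutation_model()].
#' @inheritParams pair_ml_divisions
#' @return An `ms_dist` object: list with `d` (symmetric integer matrix of
#'   estimated divisions, zero diagonal), `shared_loci` (symmetric matrix
#'   of shared-locus counts) and `flagged_pairs` (data frame of imputed
#'   pairs).
#' @export
distance_matrix <- function(signatures, model, t_max = 3000L, min_shared = 10L) {
  stopifnot(is.matrix(signatures))
  n <- nrow(signatures)
  if (n < 3L) stop("need at least 3 signatures for a distance matrix", call. = FALSE)
  ids <- rownames(signatures)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  channels <- attr(signatures, "channels")
  locus_of <- if (!is.null(channels))
    channels$locus[match(colnames(signatures), channels$channel)]
  else colnames(signatures)

  meas <- !is.na(signatures)
  k_max <- {
    rng <- range(signatures, na.rm = TRUE)
    as.integer(diff(rng))
  }
  tab <- step_loglik_table(model, t_max, max(k_max, 1L))

  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  flagged <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- meas[i, ] & meas[j, ]
      shared[i, j] <- shared[j, i] <- length(unique(locus_of[ok]))
      if (shared[i, j] < min_shared) {
        d[i, j] <- d[j, i] <- NA_integer_
        flagged[[length(flagged) + 1L]] <-
          data.frame(a = ids[i], b = ids[j], stringsAsFactors = FALSE)
        next
      }
      dd <- abs(signatures[i, ok] - signatures[j, ok])
      counts <- tabulate(dd + 1L, nbins = max(dd) + 1L)
      ll <- tab[, seq_along(counts), drop = FALSE] %*% counts
      d[i, j] <- d[j, i] <- as.integer(which.max(ll) - 1L)
    }
  }
  if (anyNA(d)) {
    imput <- max(d, na.rm = TRUE)
    d[is.na(d)] <- imput
  }
  structure(
    list(sample_ids = ids, d = d, shared_loci = shared,
         flagged_pairs = if (length(flagged)) do.call(rbind, flagged) else
           data.frame(a = character(), b = character(), stringsAsFactors = FALSE)),
    class = "ms_dist")
}

#' @export
print.ms_dist <- function(x, ...) {
  cat(sprintf("Division-distance matrix: %d samples, %d pair(s) imputed\n",
              length(x$sample_ids), nrow(x$flagged_pairs)))
  invisible(x)
}

#' Write / read a distance matrix
#'
#' `write_distance_matrix()` emits a PHYLIP square matrix (or TSV with a
#' header when `format = "tsv"`); `read_distance_matrix()` reads either.
#'
#' @param dist An `ms_dist` object or plain numeric matrix.
#' @param path File path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `read_distance_matrix()` returns the numeric matrix.
#' @export
write_distance_matrix <- function(dist, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  m <- if (inherits(dist, "ms_dist")) dist$d else dist
  if (format == "phylip") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE)),
                       collapse = "\t"), con)
  } else {
    write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    parts <- strsplit(lines[1 + seq_len(n)], "\t")
    ids <- vapply(parts, `[[`, "", 1L)
    m <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
    dimnames(m) <- list(ids, ids)
  } else {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
  }
  m
}
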