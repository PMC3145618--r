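#' @importFrom utils read.delim write.table combn head
#' @importFrom stats median setNames
NULL

# ---- helpers ---------------------------------------------------------------

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.read_table_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             colClasses = "character", na.strings = NULL,
             strip.white = TRUE)
}

# locus name grammar: [Organism letter][Chromosome]_[repeat unit][repeat count]_[serial]
.parse_locus_name <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z])(X|[0-9]+)_([ACGTacgt]+)([0-9]+)_([0-9]+)$", name))[[1]]
  if (length(m) == 0L) return(NULL)
  list(chromosome = m[3], repeat_unit = toupper(m[4]),
       reference_repeat_count = as.integer(m[5]))
}

# ---- locus panel -----------------------------------------------------------

#' Read a microsatellite locus panel table
#'
#' Reads a CSV/TSV export of the panel description table. The first column
#' holds locus names following the grammar
#' `[Organism][Chromosome]_[Repeat unit][repeat count]_[serial]`
#' (e.g. `MX_AC20_3` = mouse X chromosome, AC repeat, 20 units). Loci on the
#' X chromosome are flagged as single-allele (samples are from male mice);
#' autosomal loci carry two alleles.
#'
#' @param path Path to a CSV or TSV file whose columns include the locus
#'   name and, optionally, size and primer sequences.
#' @return An `ms_panel` data frame with columns `name`, `chromosome`,
#'   `repeat_unit`, `unit_length`, `reference_repeat_count`,
#'   `expected_allele_count`, `forward_primer`, `reverse_primer`.
#' @export
read_locus_panel <- function(path) {
  tab <- .read_table_auto(path)
  if (nrow(tab) == 0L) {
    warning("locus panel file '", path, "' contains no rows", call. = FALSE)
    return(.empty_panel())
  }
  hdr <- .norm_header(names(tab))
  name_col <- which(hdr %in% c("name", "locus", "locusname", "lociname"))[1]
  if (is.na(name_col)) name_col <- 1L
  fwd <- which(grepl("forward", hdr))[1]
  rev_ <- which(grepl("reverse", hdr))[1]
  nm <- trimws(tab[[name_col]])
  if (anyDuplicated(nm))
    stop("duplicate locus names in panel: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  parsed <- lapply(nm, .parse_locus_name)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad))
    stop("malformed locus name(s) in panel row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  panel <- data.frame(
    name = nm,
    chromosome = vapply(parsed, `[[`, "", "chromosome"),
    repeat_unit = vapply(parsed, `[[`, "", "repeat_unit"),
    stringsAsFactors = FALSE
  )
  panel$unit_length <- nchar(panel$repeat_unit)
  panel$reference_repeat_count <-
    vapply(parsed, `[[`, 0L, "reference_repeat_count")
  panel$expected_allele_count <- ifelse(panel$chromosome == "X", 1L, 2L)
  panel$forward_primer <- if (!is.na(fwd)) tab[[fwd]] else NA_character_
  panel$reverse_primer <- if (!is.na(rev_)) tab[[rev_]] else NA_character_
  class(panel) <- c("ms_panel", "data.frame")
  panel
}

.empty_panel <- function() {
  panel <- data.frame(name = character(), chromosome = character(),
                      repeat_unit = character(), unit_length = integer(),
                      reference_repeat_count = integer(),
                      expected_allele_count = integer(),
                      forward_primer = character(),
                      reverse_primer = character(),
                      stringsAsFactors = FALSE)
  class(panel) <- c("ms_panel", "data.frame")
  panel
}

#' Allele channels of a panel
#'
#' Expands a panel into one row per allele "channel": X-linked loci
#' contribute a single channel named after the locus, autosomal loci two
#' channels suffixed `_a` and `_b`.
#'
#' @param panel An `ms_panel`.
#' @return Data frame with columns `channel`, `locus`, `allele`.
#' @export
panel_channels <- function(panel) {
  stopifnot(inherits(panel, "ms_panel"))
  out <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    if (panel$expected_allele_count[i] == 1L)
      data.frame(channel = panel$name[i], locus = panel$name[i], allele = 1L,
                 stringsAsFactors = FALSE)
    else
      data.frame(channel = paste0(panel$name[i], c("_a", "_b")),
                 locus = panel$name[i], allele = 1:2, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(channel = character(), locus = character(),
                      allele = integer(), stringsAsFactors = FALSE)
  out
}

# ---- fragment table --------------------------------------------------------

# A cell of the fragment table is one of:
#   "X"     missing (amplification failed)
#   "Null"  locus not measured for this sample
#   a number, or several numbers separated by "/" (multiple capillary peaks)
.cell_sizes <- function(cell) {
  cell <- trimws(cell)
  if (cell == "" || toupper(cell) == "X") return(numeric(0))
  if (tolower(cell) == "null") return(NULL)
  out <- suppressWarnings(as.numeric(strsplit(cell, "/", fixed = TRUE)[[1]]))
  if (anyNA(out)) stop("unparseable fragment-size cell: '", cell, "'", call. = FALSE)
  out
}

.meta_cols <- c(animal_id = "animalid", sample_id = "sampleid",
                tissue = "tissue", isolation_method = "isolationmethod")

#' Read a fragment-size table
#'
#' Reads a CSV/TSV export of the per-sample fragment-size table. Metadata
#' columns (`Animal ID`, `Sample ID`, `Tissue`, `Isolation method`; matched
#' case-insensitively) are followed by one column per X-linked locus and two
#' per autosomal locus (suffixes `_a`/`_b`, or a duplicated header). `X`
#' marks missing data (failed amplification), `Null` marks a locus that was
#' not measured; loci without a column are treated as not measured. A cell
#' containing several sizes separated by `/` records multiple capillary
#' peaks and is resolved by [qc_filter()].
#'
#' @param path Path to the table file.
#' @param panel The `ms_panel` the columns must belong to.
#' @return An `ms_fragments` object: list with `meta` (per-sample metadata),
#'   `cells` (character matrix samples x channels holding the raw cell
#'   text) and `channels` (see [panel_channels()]).
#' @export
read_fragment_table <- function(path, panel) {
  stopifnot(inherits(panel, "ms_panel"))
  tab <- .read_table_auto(path)
  hdr <- .norm_header(names(tab))
  meta_idx <- vapply(.meta_cols, function(key) which(hdr == key)[1], 0)
  if (anyNA(meta_idx))
    stop("fragment table is missing metadata column(s): ",
         paste(names(.meta_cols)[is.na(meta_idx)], collapse = ", "), call. = FALSE)
  meta <- data.frame(
    animal_id = tab[[meta_idx[["animal_id"]]]],
    sample_id = tab[[meta_idx[["sample_id"]]]],
    tissue = tab[[meta_idx[["tissue"]]]],
    isolation_method = tab[[meta_idx[["isolation_method"]]]],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in fragment table", call. = FALSE)

  ch <- panel_channels(panel)
  data_idx <- setdiff(seq_along(tab), meta_idx)
  cols <- names(tab)[data_idx]
  # map each data column to a channel: exact channel name, or the bare locus
  # name (possibly mangled by duplicate-header readers: "L", "L.1", "L_1")
  canon <- function(x) {
    x <- sub("\\.(1)$", "_b", x)
    x <- sub("_(1)$", "_a0", x); x <- sub("_(2)$", "_b", x)
    sub("_a0$", "_a", x)
  }
  resolved <- character(length(cols))
  seen_locus <- character(0)
  for (i in seq_along(cols)) {
    nm <- cols[i]
    if (nm %in% ch$channel) { resolved[i] <- nm; next }
    if (nm %in% ch$locus) {
      k <- sum(seen_locus == nm)
      seen_locus <- c(seen_locus, nm)
      cand <- ch$channel[ch$locus == nm][k + 1L]
      if (is.na(cand)) stop("too many columns for locus '", nm, "'", call. = FALSE)
      resolved[i] <- cand; next
    }
    cn <- canon(nm)
    if (cn %in% ch$channel) { resolved[i] <- cn; next }
    stop("fragment-table column '", nm, "' matches no locus in the panel",
         call. = FALSE)
  }
  if (anyDuplicated(resolved))
    stop("fragment table maps two columns to the same allele channel",
         call. = FALSE)

  cells <- matrix("Null", nrow = nrow(tab), ncol = nrow(ch),
                  dimnames = list(meta$sample_id, ch$channel))
  for (i in seq_along(data_idx)) {
    v <- trimws(tab[[data_idx[i]]])
    v[v == "" | toupper(v) == "X"] <- "X"
    v[tolower(v) == "null"] <- "Null"
    cells[, resolved[i]] <- v
  }
  # validate all cells parse
  for (j in seq_len(ncol(cells))) invisible(lapply(cells[, j], .cell_sizes))
  structure(list(meta = meta, cells = cells, channels = ch),
            class = "ms_fragments")
}

#' @export
print.ms_fragments <- function(x, ...) {
  cat(sprintf("Fragment-size table: %d sample(s) x %d allele channel(s) (%d loci)\n",
              nrow(x$cells), ncol(x$cells), length(unique(x$channels$locus))))
  invisible(x)
}

#' Write a fragment-size table
#'
#' Emits the same CSV/TSV dialect that [read_fragment_table()] reads
#' (`X` = missing, `Null` = not measured), so that a written table
#' round-trips to an identical `ms_fragments` object.
#'
#' @param fragments An `ms_fragments` object.
#' @param path Output path; a `.tsv` extension selects tab separation.
#' @return Invisibly, `path`.
#' @export
write_fragment_table <- function(fragments, path) {
  stopifnot(inherits(fragments, "ms_fragments"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- cbind(
    data.frame(`Animal ID` = fragments$meta$animal_id,
               `Sample ID` = fragments$meta$sample_id,
               Tissue = fragments$meta$tissue,
               `Isolation method` = fragments$meta$isolation_method,
               check.names = FALSE, stringsAsFactors = FALSE),
    as.data.frame(fragments$cells, stringsAsFactors = FALSE)
  )
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# counts of recorded sizes per cell (Null counts as 0)
.n_sizes <- function(cells) {
  ns <- matrix(0L, nrow(cells), ncol(cells), dimnames = dimnames(cells))
  for (j in seq_len(ncol(cells))) {
    v <- cells[, j]
    ns[, j] <- vapply(v, function(cell) {
      s <- .cell_sizes(cell)
      if (is.null(s)) 0L else length(s)
    }, 0L)
  }
  ns
}

# ---- QC --------------------------------------------------------------------

#' Quality-control filtering of fragment records
#'
#' Applies, in order: (1) exclusion of loci that showed signal in a
#' negative control (per plate if a sample-to-plate map is given, globally
#' otherwise); (2) removal, per sample, of any locus displaying more
#' alleles than expected (two peaks at a single-allele X locus, or more
#' than two at an autosomal locus); (3) exclusion of samples in which
#' fewer than `min_alleles` alleles amplified (the default keeps samples
#' with more than 25 amplified alleles).
#'
#' Filtering is total (never errors) and idempotent; the reasons for every
#' drop are attached as the `qc_report` attribute.
#'
#' @param fragments An `ms_fragments` object.
#' @param panel The matching `ms_panel`.
#' @param negative_control_loci Character vector of locus names that showed
#'   signal in a negative control.
#' @param min_alleles Minimum number of amplified alleles for a sample to be
#'   kept (strictly-more-than-25 rule = default 26).
#' @param plate_map Optional named character vector mapping sample id to
#'   plate id; when given together with `negative_control_plates`, the
#'   negative-control exclusions are restricted to samples of the affected
#'   plates. Without a map the exclusion is applied to all samples.
#' @param negative_control_plates Optional character vector of affected
#'   plate ids (parallel use with `plate_map`).
#' @return The filtered `ms_fragments`, with attribute `qc_report`
#'   (data frame `sample_id`, `locus`, `reason`).
#' @export
qc_filter <- function(fragments, panel,
                      negative_control_loci = character(),
                      min_alleles = 26L,
                      plate_map = NULL,
                      negative_control_plates = NULL) {
  stopifnot(inherits(fragments, "ms_fragments"), inherits(panel, "ms_panel"))
  cells <- fragments$cells
  ch <- fragments$channels
  report <- list()

  # 1. negative-control loci
  if (length(negative_control_loci)) {
    affected_samples <- rownames(cells)
    if (!is.null(plate_map) && !is.null(negative_control_plates))
      affected_samples <- names(plate_map)[plate_map %in% negative_control_plates]
    bad_ch <- ch$channel[ch$locus %in% negative_control_loci]
    rows <- intersect(rownames(cells), affected_samples)
    drop <- cells[rows, bad_ch, drop = FALSE] != "Null"
    if (any(drop)) {
      idx <- which(drop, arr.ind = TRUE)
      report[[length(report) + 1L]] <- data.frame(
        sample_id = rows[idx[, 1]],
        locus = ch$locus[match(bad_ch[idx[, 2]], ch$channel)],
        reason = "negative_control", stringsAsFactors = FALSE)
    }
    cells[rows, bad_ch] <- "Null"
  }

  # 2. more alleles than expected at a locus
  ns <- .n_sizes(cells)
  for (locus in unique(ch$locus)) {
    chans <- ch$channel[ch$locus == locus]
    expected <- panel$expected_allele_count[panel$name == locus]
    tot <- rowSums(ns[, chans, drop = FALSE])
    over <- tot > expected
    if (any(over)) {
      report[[length(report) + 1L]] <- data.frame(
        sample_id = rownames(cells)[over], locus = locus,
        reason = "excess_alleles", stringsAsFactors = FALSE)
      cells[over, chans] <- "X"
    }
  }

  # 3. per-sample amplified-allele count
  ns <- .n_sizes(cells)
  n_amp <- rowSums(ns)
  keep <- n_amp >= min_alleles
  if (any(!keep)) {
    report[[length(report) + 1L]] <- data.frame(
      sample_id = rownames(cells)[!keep], locus = NA_character_,
      reason = sprintf("low_allele_count(%d)", n_amp[!keep]),
      stringsAsFactors = FALSE)
  }
  out <- structure(
    list(meta = fragments$meta[keep, , drop = FALSE],
         cells = cells[keep, , drop = FALSE],
         channels = ch),
    class = "ms_fragments")
  attr(out, "qc_report") <- if (length(report)) do.call(rbind, report) else
    data.frame(sample_id = character(), locus = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}

# ---- root signature & genomic signatures -----------------------------------

#' Root (zygote) signature from tail samples
#'
#' The tail contains cells of all three germ layers, so its allele sizes
#' stand in for the zygote. With several tail samples the per-channel
#' median size is used; within each autosomal locus the two allele sizes
#' of every sample are sorted before aggregation so that channel `_a`
#' consistently holds the shorter allele.
#'
#' @param fragments An `ms_fragments` holding the tail sample rows.
#' @param panel The matching `ms_panel`.
#' @return A named numeric vector (class `root_signature`) of fragment
#'   sizes per allele channel; channels measured in no tail sample are
#'   omitted with a warning.
#' @export
root_signature <- function(fragments, panel) {
  stopifnot(inherits(fragments, "ms_fragments"))
  if (nrow(fragments$cells) == 0L)
    stop("no tail samples supplied for the root signature", call. = FALSE)
  ch <- fragments$channels
  out <- setNames(rep(NA_real_, nrow(ch)), ch$channel)
  for (locus in unique(ch$locus)) {
    chans <- ch$channel[ch$locus == locus]
    # per sample: sorted sizes across the locus' channels
    mat <- matrix(NA_real_, nrow(fragments$cells), length(chans))
    for (i in seq_len(nrow(fragments$cells))) {
      s <- unlist(lapply(fragments$cells[i, chans], .cell_sizes))
      s <- sort(s)
      if (length(s) == length(chans)) mat[i, ] <- s
    }
    for (k in seq_along(chans)) {
      v <- mat[, k]
      if (any(!is.na(v))) out[chans[k]] <- median(v, na.rm = TRUE)
    }
  }
  drop <- is.na(out)
  if (any(drop)) {
    warning("channel(s) measured in no tail sample excluded from root: ",
            paste(names(out)[drop], collapse = ", "), call. = FALSE)
    out <- out[!drop]
  }
  class(out) <- "root_signature"
  out
}

#' Genomic signatures relative to the root
#'
#' Converts fragment sizes into integer repeat-unit deviations from the
#' root (zygote) signature: `round((size - root size) / unit length)`.
#' For autosomal loci the sample's two alleles are assigned to the two
#' root alleles by the pairing that minimises the summed absolute
#' deviation (ties keep sorted order); a lone measured allele is assigned
#' to the closer root allele. A size whose deviation is further than
#' `tol` repeat units from an integer marks an unreliable call and the
#' channel is excluded from that sample's signature.
#'
#' @param fragments A QC-filtered `ms_fragments`.
#' @param root A [root_signature()].
#' @param panel The matching `ms_panel`.
#' @param tol Maximum distance from an integer deviation before the call
#'   is discarded (repeat units).
#' @return An `ms_signatures` object: integer matrix samples x channels,
#'   `NA` where a channel is not in the sample's measured mask.
#' @export
compute_signatures <- function(fragments, root, panel, tol = 0.34) {
  stopifnot(inherits(fragments, "ms_fragments"), inherits(root, "root_signature"))
  ch <- fragments$channels
  ch <- ch[ch$channel %in% names(root), , drop = FALSE]
  sig <- matrix(NA_integer_, nrow(fragments$cells), nrow(ch),
                dimnames = list(rownames(fragments$cells), ch$channel))
  unreliable <- 0L
  for (locus in unique(ch$locus)) {
    chans <- ch$channel[ch$locus == locus]
    unit <- panel$unit_length[panel$name == locus]
    rootsz <- unclass(root)[chans]
    for (i in seq_len(nrow(fragments$cells))) {
      s <- sort(unlist(lapply(fragments$cells[i, chans], .cell_sizes)))
      if (length(s) == 0L) next
      if (length(chans) == 1L) {
        assign_to <- 1L
        dev <- (s[1] - rootsz[1]) / unit
        devs <- setNames(dev, chans)
      } else if (length(s) == 2L) {
        d_keep <- (s - rootsz) / unit          # sorted-order pairing
        d_swap <- (rev(s) - rootsz) / unit
        devs <- if (sum(abs(d_swap)) < sum(abs(d_keep))) {
          setNames(d_swap, chans)
        } else setNames(d_keep, chans)
      } else { # one measured allele at a two-allele locus
        dd <- (s[1] - rootsz) / unit
        j <- which.min(abs(dd))
        devs <- setNames(dd[j], chans[j])
      }
      for (nm in names(devs)) {
        d <- devs[[nm]]
        if (abs(d - round(d)) > tol) { unreliable <- unreliable + 1L; next }
        sig[i, nm] <- as.integer(round(d))
      }
    }
  }
  structure(sig, class = c("ms_signatures", class(sig)),
            channels = ch, unreliable_calls = unreliable)
}

#' Build a signature matrix directly from integer deviations
#'
#' Convenience constructor used by the simulator and by tests: wraps an
#' integer deviation matrix (samples x channels, `NA` = unmeasured) as an
#' `ms_signatures` object.
#'
#' @param mat Integer matrix of repeat-unit deviations.
#' @param channels Optional channel table (see [panel_channels()]);
#'   defaults to one single-allele locus per column.
#' @return An `ms_signatures` object.
#' @export
as_signatures <- function(mat, channels = NULL) {
  stopifnot(is.matrix(mat))
  storage.mode(mat) <- "integer"
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("L%03d", seq_len(ncol(mat)))
  if (is.null(channels))
    channels <- data.frame(channel = colnames(mat), locus = colnames(mat),
                           allele = 1L, stringsAsFactors = FALSE)
  structure(mat, class = c("ms_signatures", class(mat)), channels = channels)
}

#' Write genomic signatures as TSV
#'
#' @param signatures An `ms_signatures` matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(sample_id = rownames(signatures),
                   as.data.frame(unclass(signatures)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
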