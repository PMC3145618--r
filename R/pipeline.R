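#' Reconstruct a lineage tree from fragment data
#'
#' The core composition: QC filtering, root signature from the tail
#' sample(s), genomic signatures, maximum-likelihood division distances,
#' neighbor joining, rooting at the tail leaf, and depth extraction.
#'
#' @param fragments An `ms_fragments` table including the tail sample(s).
#' @param panel The matching `ms_panel`.
#' @param tail_ids Sample id(s) of tail samples; the first one becomes the
#'   root leaf of the tree.
#' @param model A [mutation_model()].
#' @param t_max,min_shared See [distance_matrix()].
#' @param qc Apply [qc_filter()] first?
#' @param min_alleles,negative_control_loci Passed to [qc_filter()].
#' @return A `lineage_reconstruction` list: `signatures`, `dist`, `tree`
#'   (rooted `phylo`), `depths` (named leaf depths, tail excluded),
#'   `root`, `qc_report`.
#' @export
reconstruct_lineage <- function(fragments, panel, tail_ids,
                                model = mutation_model(),
                                t_max = 3000L, min_shared = 10L,
                                qc = TRUE, min_alleles = 26L,
                                negative_control_loci = character()) {
  stopifnot(inherits(fragments, "ms_fragments"), inherits(panel, "ms_panel"))
  if (!all(tail_ids %in% fragments$meta$sample_id))
    stop("tail sample(s) missing from the fragment table: ",
         paste(setdiff(tail_ids, fragments$meta$sample_id), collapse = ", "),
         call. = FALSE)
  qc_report <- NULL
  if (qc) {
    fragments <- qc_filter(fragments, panel, negative_control_loci,
                           min_alleles = min_alleles)
    qc_report <- attr(fragments, "qc_report")
    if (!all(tail_ids %in% rownames(fragments$cells)))
      stop("tail sample(s) removed by QC; cannot root the tree", call. = FALSE)
  }
  tails <- structure(list(
    meta = fragments$meta[fragments$meta$sample_id %in% tail_ids, , drop = FALSE],
    cells = fragments$cells[tail_ids, , drop = FALSE],
    channels = fragments$channels), class = "ms_fragments")
  root <- root_signature(tails, panel)
  sig <- compute_signatures(fragments, root, panel)
  dm <- distance_matrix(sig, model, t_max = t_max, min_shared = min_shared)
  tree <- root_tree(nj_tree(dm), tail_ids[1])
  structure(list(signatures = sig, dist = dm, tree = tree,
                 depths = leaf_depths(tree), root = root,
                 qc_report = qc_report),
            class = "lineage_reconstruction")
}

#' @export
print.lineage_reconstruction <- function(x, ...) {
  cat(sprintf("Lineage reconstruction: %d leaves, median depth %.0f divisions\n",
              length(x$depths), median(x$depths)))
  invisible(x)
}

#' Reconstruct directly from a simulation output
#'
#' @param output A `sim_output` from [simulate_mouse()].
#' @param ... Passed to [reconstruct_lineage()] (`t_max`, `min_shared`, ...).
#' @return A `lineage_reconstruction`.
#' @export
reconstruct_sim <- function(output, ...) {
  stopifnot(inherits(output, "sim_output"))
  model <- mutation_model(output$config$mu, output$config$single_to_double_odds)
  reconstruct_lineage(output$fragments, output$panel, output$tail_id,
                      model = model, ...)
}

# ---- config-driven runs ----------------------------------------------------

.as_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

.config_hash <- function(config) rlang::hash(config)

.write_artifact <- function(df, path, hash) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the reconstruction pipeline from a configuration
#'
#' The configuration (list or YAML path) names the input tables and
#' parameters: `panel`, `fragments` (paths), `tail_sample_id`,
#' `mutation_rate` (default 0.01), `step_odds` (default 7), `t_max`,
#' `min_shared_loci`, `min_alleles`, `negative_control_loci`, `out_dir`.
#' Outputs (Newick tree, depth table, QC report) are written under
#' `out_dir` with the configuration hash in each TSV header.
#'
#' @param config List or path to a YAML file.
#' @return The `lineage_reconstruction`, invisibly if `out_dir` is set.
#' @export
run_reconstruct <- function(config) {
  config <- .as_run_config(config)
  panel <- read_locus_panel(config$panel)
  fragments <- read_fragment_table(config$fragments, panel)
  model <- mutation_model(config$mutation_rate %||% 0.01,
                          config$step_odds %||% 7)
  rec <- reconstruct_lineage(
    fragments, panel, config$tail_sample_id,
    model = model,
    t_max = config$t_max %||% 3000L,
    min_shared = config$min_shared_loci %||% 10L,
    min_alleles = config$min_alleles %||% 26L,
    negative_control_loci = config$negative_control_loci %||% character())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- .config_hash(config)
    write_newick(rec$tree, file.path(config$out_dir, "tree.nwk"))
    .write_artifact(data.frame(sample_id = names(rec$depths),
                               depth = rec$depths),
                    file.path(config$out_dir, "depths.tsv"), hash)
    if (!is.null(rec$qc_report))
      .write_artifact(rec$qc_report, file.path(config$out_dir, "qc_report.tsv"),
                      hash)
    return(invisible(rec))
  }
  rec
}

#' Run the clade enrichment analysis
#'
#' @param config List or YAML path; uses `group_labels` (named list/vector
#'   mapping sample id to group), `groups` (focal groups to test; default
#'   all), `fdr_q` (default 0.2) and `out_dir`.
#' @param rec A `lineage_reconstruction`.
#' @return Data frame of enrichment results across focal groups.
#' @export
run_enrich <- function(config, rec) {
  config <- .as_run_config(config)
  labels <- unlist(config$group_labels)
  groups <- config$groups %||% setdiff(unique(labels), NA)
  q <- config$fdr_q %||% 0.2
  out <- do.call(rbind, lapply(groups, function(g) {
    res <- fdr_select(tree_enrichment(rec$tree, labels, g), q = q)
    res$group <- g
    res$headline_p <- attr(res, "headline_p")
    res
  }))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_artifact(out, file.path(config$out_dir, "enrichment.tsv"),
                    .config_hash(config))
  }
  out
}

#' Run the depth statistics report
#'
#' Per-group depth summaries (bootstrap SE of the median) and the pooled
#' mutation-size spectrum.
#'
#' @param config List or YAML path; uses `group_labels`, `seed`, `out_dir`.
#' @param rec A `lineage_reconstruction`.
#' @return List with `summaries` and `spectrum`.
#' @export
run_stats <- function(config, rec) {
  config <- .as_run_config(config)
  labels <- unlist(config$group_labels)
  groups <- setdiff(unique(labels[names(rec$depths)]), NA)
  summaries <- do.call(rbind, lapply(groups, function(g) {
    depth_summary(rec$depths[names(rec$depths)[labels[names(rec$depths)] == g]],
                  seed = config$seed %||% 1L, label = g)
  }))
  spectrum <- mutation_size_spectrum(rec$signatures)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- .config_hash(config)
    .write_artifact(summaries, file.path(config$out_dir, "depth_summaries.tsv"), hash)
    .write_artifact(spectrum, file.path(config$out_dir, "mutation_spectrum.tsv"), hash)
  }
  list(summaries = summaries, spectrum = spectrum)
}

#' Run a simulation from a configuration
#'
#' @param config List or YAML path of [sim_config()] fields plus `out_dir`.
#' @return The `sim_output`, invisibly if written to disk.
#' @export
run_simulate <- function(config) {
  config <- .as_run_config(config)
  out_dir <- config$out_dir
  config$out_dir <- NULL
  cfg <- do.call(sim_config, config)
  out <- simulate_mouse(cfg)
  if (!is.null(out_dir)) {
    write_sim_output(out, out_dir)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
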