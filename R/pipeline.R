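# Pipeline orchestration: prefilter -> scan -> homology -> expression ->
# cluster, each stage independently skippable (the published workflow
# interposes manual curation, so users must be able to intervene between
# stages), with tab-separated reasons tables, a mature-peptide FASTA and
# a JSON run summary written per stage.

#' Pipeline configuration
#'
#' Collects the per-stage configurations, input paths and the global
#' seed. All referenced paths are checked at validation time, before any
#' stage runs.
#'
#' @param fasta Path to the input protein FASTA (required).
#' @param out_dir Output directory (created if needed).
#' @param signal_evidence,tm_evidence,domain_evidence,alignment_hits
#'   Optional paths to annotator tables in the [parse_evidence()]
#'   dialects.
#' @param expression_matrix,cluster_annotation Optional paths to the
#'   expression summary (both or neither).
#' @param seed Global seed, recorded in output headers and used for the
#'   layout.
#' @param stages Named logical list enabling `prefilter`, `homology`,
#'   `expression`, `cluster` (scanning always runs).
#' @param prefilter,scanner,homology,expression,cluster Stage
#'   configuration objects.
#' @param verbose Log one line per stage.
#' @return A list of class `neuropep_pipeline_config`.
#' @export
pipeline_config <- function(fasta, out_dir,
                            signal_evidence = NULL, tm_evidence = NULL,
                            domain_evidence = NULL, alignment_hits = NULL,
                            expression_matrix = NULL,
                            cluster_annotation = NULL,
                            seed = 1L,
                            stages = list(),
                            prefilter = prefilter_config(),
                            scanner = scanner_config(),
                            homology = homology_config(),
                            expression = expression_config(),
                            cluster = cluster_config(),
                            verbose = FALSE) {
  st <- utils::modifyList(list(prefilter = TRUE, homology = TRUE,
                               expression = TRUE, cluster = TRUE), stages)
  paths <- c(fasta = fasta, signal_evidence = signal_evidence,
             tm_evidence = tm_evidence, domain_evidence = domain_evidence,
             alignment_hits = alignment_hits,
             expression_matrix = expression_matrix,
             cluster_annotation = cluster_annotation)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      np_usage_error(sprintf("pipeline input '%s' not found: %s", nm, paths[[nm]]))
    }
  }
  if (xor(is.null(expression_matrix), is.null(cluster_annotation))) {
    np_usage_error("expression_matrix and cluster_annotation must be given together")
  }
  structure(list(fasta = fasta, out_dir = out_dir,
                 signal_evidence = signal_evidence,
                 tm_evidence = tm_evidence,
                 domain_evidence = domain_evidence,
                 alignment_hits = alignment_hits,
                 expression_matrix = expression_matrix,
                 cluster_annotation = cluster_annotation,
                 seed = as.integer(seed), stages = st,
                 prefilter = prefilter, scanner = scanner,
                 homology = homology, expression = expression,
                 cluster = cluster, verbose = isTRUE(verbose)),
            class = "neuropep_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML schema (version 1) mirrors the arguments of
#' [pipeline_config()]: top-level keys `fasta`, `out_dir`, optional
#' evidence/expression paths, `seed`, `stages` (named booleans) and
#' per-stage parameter maps `prefilter`, `scanner`, `homology`,
#' `expression`, `cluster` whose entries are passed to the corresponding
#' `*_config()` constructor.
#'
#' @param path Path to the YAML file.
#' @return A `neuropep_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) np_usage_error(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  # exact [[-indexing throughout: $ would partial-match e.g. "expression"
  # against "expression_matrix"
  cfg <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  pipeline_config(
    fasta = y[["fasta"]], out_dir = y[["out_dir"]],
    signal_evidence = y[["signal_evidence"]],
    tm_evidence = y[["tm_evidence"]],
    domain_evidence = y[["domain_evidence"]],
    alignment_hits = y[["alignment_hits"]],
    expression_matrix = y[["expression_matrix"]],
    cluster_annotation = y[["cluster_annotation"]],
    seed = if (is.null(y[["seed"]])) 1L else y[["seed"]],
    stages = if (is.null(y[["stages"]])) list() else y[["stages"]],
    prefilter = cfg(prefilter_config, y[["prefilter"]]),
    scanner = cfg(scanner_config, y[["scanner"]]),
    homology = cfg(homology_config, y[["homology"]]),
    expression = cfg(expression_config, y[["expression"]]),
    cluster = cfg(cluster_config, y[["cluster"]]),
    verbose = isTRUE(y[["verbose"]]))
}

log_stage <- function(config, stage, n_in, n_out) {
  if (config$verbose) {
    message(sprintf("[neuropep] %-12s in=%d out=%d", stage, n_in, n_out))
  }
}

#' Run the full discovery pipeline
#'
#' Executes the stages in order (prefilter, scan, homology filter,
#' expression filter, similarity clustering), writes each stage's
#' reasons table, the candidate peptide table, a mature-peptide FASTA,
#' the similarity edge list / cluster labels / layout coordinates, a
#' final per-candidate table and a JSON run summary with the counts
#' surviving each stage. Re-running with an identical configuration and
#' seed reproduces all outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`prefilter`,
#'   `peptides`, `scores`, `homology`, `expression`, `graph`, `clusters`,
#'   `layout`, `candidates`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "neuropep_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- config$seed

  records <- read_fasta(config$fasta)
  counts <- list(input = nrow(records))

  evidence <- list()
  if (!is.null(config$signal_evidence)) {
    evidence <- c(evidence, list(parse_evidence(config$signal_evidence, "signal_caller")))
  }
  if (!is.null(config$tm_evidence)) {
    evidence <- c(evidence, list(parse_evidence(config$tm_evidence, "tm_caller")))
  }
  if (!is.null(config$domain_evidence)) {
    evidence <- c(evidence, list(parse_evidence(config$domain_evidence, "domain_scanner")))
  }

  # stage 1: secretome prefilter
  if (config$stages$prefilter) {
    pf <- apply_prefilter(records, evidence, config$prefilter)
  } else {
    kept <- records
    kept$signal_end <- 0L
    pf <- list(kept = kept,
               report = data.frame(id = records$id, kept = 1L,
                                   reason = "skipped", stringsAsFactors = FALSE))
  }
  write_report(pf$report, out("prefilter_report.tsv"), seed)
  counts$prefilter <- nrow(pf$kept)
  log_stage(config, "prefilter", nrow(records), nrow(pf$kept))

  # stage 2: cleavage-site scan (always runs)
  scan <- scan_precursors(pf$kept, config$scanner)
  write_report(scan$peptides, out("peptides.tsv"), seed)
  write_report(scan$scores, out("scores.tsv"), seed)
  passing <- scan$scores$precursor_id[scan$scores$passes]
  pep_pass <- scan$peptides[scan$peptides$counts_toward_pass &
                              scan$peptides$parent_id %in% passing, , drop = FALSE]
  if (nrow(pep_pass)) {
    mat_fa <- data.frame(
      id = sprintf("%s|%d-%d|%s|amid=%d", pep_pass$parent_id,
                   pep_pass$start, pep_pass$end, pep_pass$family,
                   as.integer(pep_pass$amidated)),
      residues = pep_pass$mature, stringsAsFactors = FALSE)
    write_fasta(mat_fa, out("mature_peptides.fasta"))
  }
  counts$scan <- length(passing)
  log_stage(config, "scan", nrow(pf$kept), length(passing))
  survivors <- passing

  # stage 3: homology filter
  if (config$stages$homology && !is.null(config$alignment_hits)) {
    hits <- drop_orphans(parse_evidence(config$alignment_hits, "alignment_hits"),
                         records$id)
    hom <- filter_by_homology(survivors, hits, config$homology)
    write_report(hom$report, out("homology_report.tsv"), seed)
    survivors <- hom$kept
  } else {
    hom <- NULL
  }
  counts$homology <- length(survivors)
  log_stage(config, "homology", counts$scan, length(survivors))

  # stage 4: neuronal-expression filter
  if (config$stages$expression && !is.null(config$expression_matrix)) {
    profiles <- read_expression(config$expression_matrix,
                                config$cluster_annotation)
    expr <- filter_by_expression(survivors, profiles, config$expression)
    write_report(expr$report, out("expression_report.tsv"), seed)
    survivors <- expr$kept
  } else {
    expr <- NULL
  }
  counts$expression <- length(survivors)
  log_stage(config, "expression", counts$homology, length(survivors))

  # stage 5: similarity clustering of survivors
  graph <- clusters <- layout <- NULL
  if (config$stages$cluster && length(survivors) >= 2L) {
    surv_rec <- records[match(survivors, records$id), , drop = FALSE]
    ccfg <- config$cluster
    ccfg$layout$seed <- seed
    graph <- build_graph(surv_rec, ccfg)
    clusters <- connected_clusters(graph)
    layout <- force_layout(graph, ccfg)
    write_report(graph$edges, out("edges.tsv"), seed)
    write_report(clusters, out("clusters.tsv"), seed)
    write_report(layout, out("layout.tsv"), seed)
  }
  log_stage(config, "cluster", counts$expression, counts$expression)

  # final candidate table
  candidates <- data.frame(id = records$id, stringsAsFactors = FALSE)
  candidates$prefilter_pass <- as.integer(candidates$id %in% pf$kept$id)
  m <- match(candidates$id, scan$scores$precursor_id)
  candidates$scan_pass <- as.integer(!is.na(m) & scan$scores$passes[m])
  candidates$n_passing <- ifelse(is.na(m), 0L, scan$scores$n_passing[m])
  candidates$score <- ifelse(is.na(m), 0, scan$scores$score[m])
  candidates$homology_pass <- as.integer(
    if (is.null(hom)) candidates$scan_pass == 1L
    else candidates$id %in% hom$kept)
  candidates$expression_pass <- as.integer(
    if (is.null(expr)) candidates$homology_pass == 1L & candidates$scan_pass == 1L
    else candidates$id %in% expr$kept)
  candidates$final <- as.integer(candidates$id %in% survivors)
  candidates$cluster_label <- if (is.null(clusters)) NA_character_ else
    clusters$cluster_label[match(candidates$id, clusters$id)]
  write_report(candidates, out("candidates.tsv"), seed)

  summary <- list(seed = seed, counts = counts,
                  n_final = length(survivors),
                  stages = config$stages)
  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(prefilter = pf, peptides = scan$peptides,
                 scores = scan$scores, homology = hom, expression = expr,
                 graph = graph, clusters = clusters, layout = layout,
                 candidates = candidates, summary = summary,
                 survivors = survivors))
}
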