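# End-to-end orchestration: configuration, staged execution with a run
# summary and log, and recovery scoring against planted ground truth.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its conventional
#' default: t-score cutoff 3.0 (about p = 0.001 one-sided under
#' normality), gene sets of at most 30 universe members, side-effect
#' frequency at least 20%, side effects backed by at least 2 drugs, 1,000
#' permutations at significance level 0.05.
#'
#' @param t_threshold minimum robust t-score for a drug-process edge.
#' @param max_set_genes maximum gene-set size (members in the universe).
#' @param min_freq minimum side-effect frequency score.
#' @param min_drugs minimum drugs per side effect (TD floor).
#' @param n_perm permutations for the null thresholds.
#' @param alpha significance level of the permutation test.
#' @param seed integer seed for the permutation draws.
#' @param aggregate drug-level aggregation of instance edges, `"union"` or
#'   `"max_t"` (see [filter_edges()]).
#' @param strict_t use `t > t_threshold` (default) rather than `>=`.
#' @param strict_freq use `freq > min_freq` rather than the default `>=`.
#' @param plus_one plus-one correction for empirical p-values
#'   (see [permutation_thresholds()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(t_threshold = 3.0, max_set_genes = 30L,
                            min_freq = 0.2, min_drugs = 2L, n_perm = 1000L,
                            alpha = 0.05, seed = 1L,
                            aggregate = c("union", "max_t"),
                            strict_t = TRUE, strict_freq = FALSE,
                            plus_one = FALSE) {
  aggregate <- match.arg(aggregate)
  .assert_scalar_number(t_threshold, "t_threshold")
  .assert_count(max_set_genes, "max_set_genes")
  .assert_scalar_number(min_freq, "min_freq", 0, 1)
  .assert_count(min_drugs, "min_drugs", 2L)
  .assert_count(n_perm, "n_perm")
  .assert_scalar_number(alpha, "alpha", 0, 1)
  seed <- .assert_count(seed, "seed", lower = 0L)
  structure(list(t_threshold = t_threshold,
                 max_set_genes = as.integer(max_set_genes),
                 min_freq = min_freq, min_drugs = as.integer(min_drugs),
                 n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
                 aggregate = aggregate, strict_t = isTRUE(strict_t),
                 strict_freq = isTRUE(strict_freq),
                 plus_one = isTRUE(plus_one)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys missing from the file keep their [pipeline_config()] defaults;
#' unknown keys are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full process-drug-side-effect pipeline
#'
#' Executes, in order: enrichment scoring of every (gene set, instance,
#' direction), median/MAD t-scores, drug-process edge filtering;
#' side-effect frequency filtering and synonym normalization; the ABC
#' merge over shared drugs; co-occurrence scoring; permutation thresholds;
#' significance flagging.  When `out_dir` is given, all outputs are written
#' there as headered TSV (associations split into the up-regulated
#' `associations_up.tsv` and down-regulated `associations_down.tsv`
#' dialects), together with a machine-readable `summary.json`, a plain-text
#' `run.log`, and optionally a GraphML export of the tripartite network.
#'
#' @param rank_matrix a [rank_matrix()] object (or path to a rank-matrix
#'   TSV when `instances_path` is given).
#' @param sets a [gene_sets()] collection (or GMT path).
#' @param side_effects a [side_effect_records()] data frame (or TSV path).
#' @param synonyms a [synonym_table()] (or TSV path).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param instances_path instance-metadata TSV, required when
#'   `rank_matrix` is a path.
#' @param graphml also write `network.graphml` (default `FALSE`).
#' @return An object of class `pse_run`: list with `dp_edges`, `dse_edges`,
#'   `network`, `associations` (with `significant` flags), `thresholds`,
#'   `tstats`, `summary`, `config`, `log`.
#' @export
run_pipeline <- function(rank_matrix, sets, side_effects, synonyms,
                         config = pipeline_config(), out_dir = NULL,
                         instances_path = NULL, graphml = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(fmt, ...) {
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                           sprintf(fmt, ...)))
  }

  if (is.character(rank_matrix)) {
    if (is.null(instances_path))
      stop("pipeline stage 'read_inputs' failed: rank-matrix path needs `instances_path`",
           call. = FALSE)
    rank_matrix <- .stage("read_inputs", log,
                          read_rank_matrix(rank_matrix, instances_path))
  }
  if (is.character(sets)) sets <- .stage("read_inputs", log, read_gmt(sets))
  if (is.character(side_effects))
    side_effects <- .stage("read_inputs", log, read_side_effects(side_effects))
  if (is.character(synonyms))
    synonyms <- .stage("read_inputs", log, read_synonyms(synonyms))
  note("inputs: %d genes, %d instances, %d sets, %d side-effect records",
       nrow(rank_matrix$ranks), ncol(rank_matrix$ranks), length(sets),
       nrow(side_effects))

  es <- .stage("enrichment", log,
               compute_es_matrix(rank_matrix, sets, direction = "both"))
  tt <- .stage("tscores", log, median_mad_tscores(es))
  note("enrichment: %d scores, %d degenerate (MAD = 0) groups",
       nrow(es), sum(tt$stats$degenerate))
  dp <- .stage("dp_edges", log,
               filter_edges(tt$tscores, t_threshold = config$t_threshold,
                            max_set_genes = config$max_set_genes,
                            aggregate = config$aggregate,
                            strict = config$strict_t))
  note("drug-process edges: %d (t %s %.3g, set size <= %d)", nrow(dp),
       if (config$strict_t) ">" else ">=", config$t_threshold,
       config$max_set_genes)

  filt <- .stage("sider_filter", log,
                 filter_by_frequency(side_effects, min_freq = config$min_freq,
                                     strict = config$strict_freq))
  dse <- .stage("sider_normalize", log,
                normalize_drug_names(filt, synonyms))
  note("side-effect edges: %d of %d records pass frequency %s %.2g; %d unmatched names",
       nrow(dse), nrow(side_effects), if (config$strict_freq) ">" else ">=",
       config$min_freq, attr(dse, "unmatched"))

  network <- .stage("merge", log, merge_networks(dp, dse))
  note("bridge: %d drugs, %d effects, %d process units",
       network$counts["drugs"], network$counts["effects"],
       network$counts["processes"])
  assoc <- .stage("co_occurrence", log,
                  co_occurrence(network, min_drugs = config$min_drugs))
  thresholds <- .stage("permutation", log,
                       permutation_thresholds(network, n_perm = config$n_perm,
                                              alpha = config$alpha,
                                              seed = config$seed,
                                              plus_one = config$plus_one))
  assoc <- .stage("thresholds", log, apply_thresholds(assoc, thresholds))
  note("associations: %d candidate pairs, %d significant at alpha %.3g",
       nrow(assoc), sum(assoc$significant), config$alpha)

  summary <- list(
    n_genes = nrow(rank_matrix$ranks),
    n_instances = ncol(rank_matrix$ranks),
    n_sets = length(sets),
    n_se_records = nrow(side_effects),
    n_dp_edges = nrow(dp),
    n_dse_edges = nrow(dse),
    unmatched_names = attr(dse, "unmatched"),
    n_bridge_drugs = unname(network$counts["drugs"]),
    n_effects = unname(network$counts["effects"]),
    n_processes = unname(network$counts["processes"]),
    n_associations = nrow(assoc),
    n_significant = sum(assoc$significant),
    thresholds = stats::setNames(as.list(thresholds$min_cd),
                                 as.character(thresholds$td)),
    seed = config$seed)

  run <- structure(list(dp_edges = dp, dse_edges = dse, network = network,
                        associations = assoc, thresholds = thresholds,
                        tstats = tt$stats, summary = summary,
                        config = config, log = log),
                   class = "pse_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_dp_edges(dp, p("drug_process_edges.tsv"))
    write_dse_edges(dse, synonyms, p("drug_side_effect_edges.tsv"))
    write_association_file(assoc[assoc$direction == "up", , drop = FALSE],
                           p("associations_up.tsv"), "additional2")
    write_association_file(assoc[assoc$direction == "down", , drop = FALSE],
                           p("associations_down.tsv"), "additional3")
    .write_tsv(as.data.frame(thresholds), p("thresholds.tsv"))
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    writeLines(log, p("run.log"))
    if (graphml) export_graphml(network, p("network.graphml"))
  }
  run
}

#' @export
print.pse_run <- function(x, ...) {
  s <- x$summary
  cat("<pse_run>\n")
  cat(sprintf("  inputs: %d genes x %d instances, %d gene sets, %d side-effect records\n",
              s$n_genes, s$n_instances, s$n_sets, s$n_se_records))
  cat(sprintf("  drug-process edges: %d | drug-side-effect edges: %d\n",
              s$n_dp_edges, s$n_dse_edges))
  cat(sprintf("  bridge: %d drugs, %d effects, %d process units\n",
              s$n_bridge_drugs, s$n_effects, s$n_processes))
  cat(sprintf("  associations: %d (%d significant at alpha %.3g)\n",
              s$n_associations, s$n_significant, x$config$alpha))
  invisible(x)
}

#' @export
summary.pse_run <- function(object, ...) object$summary

#' Score planted-association recovery of a pipeline run
#'
#' Compares the run's significant process/side-effect associations against
#' a scenario's planted ground truth.
#'
#' @param run a [run_pipeline()] result.
#' @param ground_truth the `ground_truth` element of a
#'   [generate_scenario()] result (or a compatible list with a
#'   `process_effect` data frame).
#' @return A list: `planted` (the ground-truth pairs with `detected` and
#'   `significant` flags), `recovery` (fraction of planted pairs flagged
#'   significant), `n_false` (significant associations that were not
#'   planted).
#' @export
evaluate_recovery <- function(run, ground_truth) {
  stopifnot(inherits(run, "pse_run"))
  gt <- ground_truth$process_effect
  key <- function(df) paste(df$go_id, df$umls_cui, df$direction)
  assoc <- run$associations
  gt$detected <- key(gt) %in% key(assoc)
  sig <- assoc[assoc$significant, , drop = FALSE]
  gt$significant <- key(gt) %in% key(sig)
  list(planted = gt,
       recovery = mean(gt$significant),
       n_false = sum(!(key(sig) %in% key(gt))))
}
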