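# Readers and writers for every flat-file dialect the pipeline touches.
# All intermediates are headered TSV so runs can be inspected and diffed.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a rank matrix and its instance metadata
#'
#' Expects a TSV whose first column holds gene/probe ids and whose remaining
#' columns (one per instance) hold integer ranks, plus a sidecar TSV with
#' columns `instance_id` and `drug`.  Every rank column must be a
#' permutation of `1..N`; a duplicated rank aborts with the offending
#' column and rank named.
#'
#' @param path rank-matrix TSV.
#' @param meta_path instance-metadata TSV.
#' @return A [rank_matrix()] object.
#' @export
read_rank_matrix <- function(path, meta_path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("rank matrix needs a gene column plus instances",
                          call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  meta <- .read_tsv(meta_path)
  rank_matrix(m, meta)
}

#' Write a rank matrix and its instance metadata
#' @param x a [rank_matrix()] object.
#' @param path rank-matrix TSV to write.
#' @param meta_path instance-metadata TSV to write.
#' @export
write_rank_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "pse_rank_matrix"))
  df <- data.frame(gene = rownames(x$ranks), x$ranks, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(x$instances, meta_path)
  invisible(c(path, meta_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.  Duplicate members within a line are dropped with a
#' warning; a line with fewer than 3 fields is a format error reported with
#' its line number.
#'
#' @param path GMT file.
#' @return A [gene_sets()] collection (`go_id` = field 1, `term_name` =
#'   field 2).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
         call. = FALSE)
  ndup <- 0L
  genes <- lapply(parts, function(p) {
    g <- p[-(1:2)]
    d <- duplicated(g)
    ndup <<- ndup + sum(d)
    g[!d]
  })
  if (ndup > 0L)
    warning(sprintf("dropped %d duplicated gene id(s) within GMT lines", ndup),
            call. = FALSE)
  gene_sets(vapply(parts, `[[`, character(1), 1L),
            vapply(parts, `[[`, character(1), 2L),
            genes)
}

#' Write gene sets to a GMT file
#' @param sets a [gene_sets()] collection.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "pse_gene_sets"))
  lines <- vapply(sets, function(s)
    paste(c(s$go_id, s$term_name, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read side-effect records (Table-1-style 5-column TSV)
#'
#' Columns: `compound_id`, `umls_cui`, `effect_name`, `freq_description`,
#' `freq_score`.  A missing/blank `freq_score` is re-derived from the
#' description via [parse_frequency()].
#'
#' @param path TSV file.
#' @return A [side_effect_records()] data frame.
#' @export
read_side_effects <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  req <- c("compound_id", "umls_cui", "effect_name", "freq_description",
           "freq_score")
  if (!all(req %in% names(df)))
    stop("side-effect TSV needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  fs <- suppressWarnings(as.numeric(df$freq_score))
  missing <- is.na(fs)
  if (any(missing))
    fs[missing] <- parse_frequency(df$freq_description[missing])
  side_effect_records(df$compound_id, df$umls_cui, df$effect_name,
                      df$freq_description, fs)
}

#' Write side-effect records
#' @param records a [side_effect_records()] data frame.
#' @param path output TSV.
#' @export
write_side_effects <- function(records, path) {
  .write_tsv(as.data.frame(records), path)
}

#' Read a synonym table (canonical_id, name, name_type TSV)
#' @param path TSV file.
#' @return A [synonym_table()].
#' @export
read_synonyms <- function(path) {
  df <- .read_tsv(path, colClasses = "character")
  req <- c("canonical_id", "name", "name_type")
  if (!all(req %in% names(df)))
    stop("synonym TSV needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  synonym_table(df$canonical_id, df$name, df$name_type)
}

#' Write a synonym table
#' @param synonyms a [synonym_table()].
#' @param path output TSV.
#' @export
write_synonyms <- function(synonyms, path) {
  .write_tsv(as.data.frame(synonyms), path)
}

#' Write / read drug-process edges
#'
#' Columns: `drug`, `go_id`, `direction`, `t`, `instance_id`.
#' @param edges data frame from [filter_edges()].
#' @param path TSV path.
#' @export
write_dp_edges <- function(edges, path) .write_tsv(edges, path)

#' @rdname write_dp_edges
#' @export
read_dp_edges <- function(path) .read_tsv(path)

#' Write drug-side-effect edges (Additional-file-1 dialect)
#'
#' Columns: DrugBank-style id, canonical drug name, UMLS concept id, effect
#' name, plus the frequency score.
#'
#' @param dse data frame from [normalize_drug_names()].
#' @param synonyms the [synonym_table()] used for normalization (supplies
#'   the canonical ids).
#' @param path output TSV.
#' @export
write_dse_edges <- function(dse, synonyms, path) {
  prim <- synonyms[synonyms$name_type == "primary", , drop = FALSE]
  out <- data.frame(drugbank_id = prim$canonical_id[match(dse$drug, prim$name)],
                    drug = dse$drug, umls_cui = dse$umls_cui,
                    effect_name = dse$effect_name,
                    freq_score = dse$freq_score,
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' Write process/side-effect associations (Additional-file-2/3 dialect)
#'
#' Four mandatory columns — UMLS concept id, GO id, CD, TD — plus the score
#' and, when present, the significance flag.  Dialect `additional2` holds
#' up-regulated associations, `additional3` down-regulated ones; a
#' direction mismatch is an error.  Rows are ordered by (effect, GO id).
#'
#' @param assocs data frame from [co_occurrence()] /
#'   [apply_thresholds()].
#' @param path output TSV.
#' @param dialect `"additional2"` (up) or `"additional3"` (down).
#' @export
write_association_file <- function(assocs, path,
                                   dialect = c("additional2", "additional3")) {
  dialect <- match.arg(dialect)
  want <- if (dialect == "additional2") "up" else "down"
  if (nrow(assocs) && any(assocs$direction != want))
    stop(sprintf("dialect %s holds %s-regulated associations only",
                 dialect, want), call. = FALSE)
  cols <- c("umls_cui", "go_id", "cd", "td", "score",
            intersect("significant", names(assocs)))
  out <- assocs[order(assocs$umls_cui, assocs$go_id), cols, drop = FALSE]
  .write_tsv(out, path)
}

#' Read an association file written by [write_association_file()]
#' @param path TSV path.
#' @param direction direction to stamp on the rows (`"up"` for
#'   additional2 files, `"down"` for additional3).
#' @return Data frame in [co_occurrence()] layout.
#' @export
read_association_file <- function(path, direction = c("up", "down")) {
  direction <- match.arg(direction)
  df <- .read_tsv(path)
  df$direction <- if (nrow(df)) direction else character(0)
  df[, c("umls_cui", "go_id", "direction", "cd", "td", "score",
         intersect("significant", names(df))), drop = FALSE]
}

#' Export the tripartite network as GraphML
#'
#' Builds an igraph graph with node attribute `layer` (`process`, `drug`,
#' `side_effect`) and writes it in GraphML; process nodes are keyed
#' `go_id (direction)`.
#'
#' @param network an [merge_networks()] result.
#' @param path output `.graphml` path.
#' @return The igraph object, invisibly.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "abc_network"))
  pnode <- sprintf("%s (%s)", network$dp$go_id, network$dp$direction)
  nodes <- rbind(
    data.frame(name = unique(pnode), layer = "process",
               stringsAsFactors = FALSE),
    data.frame(name = network$drugs, layer = "drug", stringsAsFactors = FALSE),
    data.frame(name = unique(network$dse$umls_cui), layer = "side_effect",
               stringsAsFactors = FALSE))
  edges <- rbind(data.frame(from = network$dp$drug, to = pnode,
                            stringsAsFactors = FALSE),
                 data.frame(from = network$dse$drug, to = network$dse$umls_cui,
                            stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Write a generated scenario to a directory
#'
#' Writes the four pipeline inputs in their on-disk dialects plus
#' `groundtruth.tsv` with columns (layer, source_id, target_id,
#' direction).
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "pse_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_rank_matrix(scenario$rank_matrix, p("rank_matrix.tsv"),
                    p("instances.tsv"))
  write_gmt(scenario$gene_sets, p("gene_sets.gmt"))
  write_side_effects(scenario$side_effects, p("side_effects.tsv"))
  write_synonyms(scenario$synonyms, p("synonyms.tsv"))
  gt <- scenario$ground_truth
  gt_df <- rbind(
    data.frame(layer = "drug_process", source_id = gt$drug_process$drug,
               target_id = gt$drug_process$go_id,
               direction = gt$drug_process$direction, stringsAsFactors = FALSE),
    data.frame(layer = "process_effect", source_id = gt$process_effect$go_id,
               target_id = gt$process_effect$umls_cui,
               direction = gt$process_effect$direction,
               stringsAsFactors = FALSE),
    data.frame(layer = "drug_effect", source_id = gt$drug_effect$drug,
               target_id = gt$drug_effect$umls_cui, direction = "",
               stringsAsFactors = FALSE))
  .write_tsv(gt_df, p("groundtruth.tsv"))
  invisible(dir)
}
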