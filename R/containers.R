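# Core containers: the per-instance rank matrix and GO-style gene sets.

#' Construct a rank matrix of drug-treatment instances
#'
#' A rank matrix holds, for every treatment instance (one drug exposure vs
#' control), a total ordering of a shared gene/probe universe: rank 1 is the
#' most up-regulated gene relative to control, rank N the most down-regulated.
#'
#' @param ranks integer matrix, genes x instances; rownames are gene ids,
#'   colnames are instance ids.  Every column must be a permutation of
#'   `1..nrow(ranks)` (no ties, no gaps).
#' @param instances data frame with columns `instance_id` and `drug` mapping
#'   each column of `ranks` to the treated drug.
#' @return An object of class `pse_rank_matrix`: a list with elements
#'   `ranks` (the validated matrix) and `instances` (the metadata).
#' @examples
#' rm <- rank_matrix(matrix(c(1:3, 3:1), 3, 2,
#'                          dimnames = list(paste0("g", 1:3), c("i1", "i2"))),
#'                   data.frame(instance_id = c("i1", "i2"),
#'                              drug = c("drugA", "drugB")))
#' ordered_genes(rm, "i2")
#' @export
rank_matrix <- function(ranks, instances) {
  if (!is.matrix(ranks) || !is.numeric(ranks))
    stop("`ranks` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("`ranks` must have gene rownames and instance colnames", call. = FALSE)
  if (anyDuplicated(rownames(ranks)))
    stop("duplicate gene ids in rank matrix", call. = FALSE)
  n <- nrow(ranks)
  if (n < 2L) stop("rank matrix needs at least 2 genes", call. = FALSE)
  storage.mode(ranks) <- "integer"
  for (j in seq_len(ncol(ranks))) {
    cj <- unname(ranks[, j])
    if (anyNA(cj) || !identical(sort(cj), seq_len(n))) {
      bad <- cj[duplicated(cj)]
      stop(sprintf(
        "column '%s' is not a permutation of 1..%d%s",
        colnames(ranks)[j], n,
        if (length(bad)) sprintf(" (rank %d occurs more than once)", bad[1L]) else ""
      ), call. = FALSE)
    }
  }
  if (!is.data.frame(instances) ||
      !all(c("instance_id", "drug") %in% names(instances)))
    stop("`instances` must be a data frame with columns instance_id, drug",
         call. = FALSE)
  instances <- instances[match(colnames(ranks), instances$instance_id), , drop = FALSE]
  if (anyNA(instances$instance_id))
    stop("every rank-matrix column needs a row in `instances`", call. = FALSE)
  rownames(instances) <- NULL
  structure(list(ranks = ranks, instances = instances),
            class = "pse_rank_matrix")
}

#' @export
print.pse_rank_matrix <- function(x, ...) {
  cat(sprintf("<pse_rank_matrix> %d genes x %d instances (%d drugs)\n",
              nrow(x$ranks), ncol(x$ranks),
              length(unique(x$instances$drug))))
  invisible(x)
}

#' @export
dim.pse_rank_matrix <- function(x) dim(x$ranks)

#' Gene universe of a rank matrix
#' @param x a [rank_matrix()] object.
#' @return Character vector of gene ids.
#' @export
universe <- function(x) {
  stopifnot(inherits(x, "pse_rank_matrix"))
  rownames(x$ranks)
}

#' Ranked gene list of one instance
#'
#' @param x a [rank_matrix()] object.
#' @param instance_id column (instance) identifier.
#' @return Character vector of gene ids, position j = the gene at rank j
#'   (rank 1 = most up-regulated versus control).
#' @export
ordered_genes <- function(x, instance_id) {
  stopifnot(inherits(x, "pse_rank_matrix"))
  j <- match(instance_id, colnames(x$ranks))
  if (is.na(j)) stop(sprintf("unknown instance '%s'", instance_id), call. = FALSE)
  rownames(x$ranks)[order(x$ranks[, j])]
}

#' Construct a collection of gene sets
#'
#' @param go_id character vector of GO-style accessions.
#' @param term_name character vector of term names (same length).
#' @param genes list of character vectors of member gene ids; duplicates
#'   within a set are removed.
#' @return An object of class `pse_gene_sets`: a list of records, each with
#'   `go_id`, `term_name`, `genes`.
#' @export
gene_sets <- function(go_id, term_name, genes) {
  stopifnot(length(go_id) == length(term_name),
            length(go_id) == length(genes), is.list(genes))
  if (anyDuplicated(go_id))
    stop("duplicate go_id in gene set collection", call. = FALSE)
  out <- lapply(seq_along(go_id), function(i) {
    g <- unique(as.character(genes[[i]]))
    if (length(g) < 1L)
      stop(sprintf("gene set '%s' is empty", go_id[i]), call. = FALSE)
    list(go_id = go_id[i], term_name = term_name[i], genes = g)
  })
  names(out) <- go_id
  structure(out, class = "pse_gene_sets")
}

#' @export
print.pse_gene_sets <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1))
  cat(sprintf("<pse_gene_sets> %d sets, sizes %d-%d (median %g)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' @export
`[.pse_gene_sets` <- function(x, i) {
  structure(NextMethod(), class = "pse_gene_sets")
}

#' Gene-set sizes counted against a universe
#'
#' @param sets a [gene_sets()] collection.
#' @param universe optional character vector; when given, sizes count only
#'   members present in the universe.
#' @return Named integer vector of sizes.
#' @export
set_sizes <- function(sets, universe = NULL) {
  stopifnot(inherits(sets, "pse_gene_sets"))
  vapply(sets, function(s) {
    g <- s$genes
    if (!is.null(universe)) g <- g[g %in% universe]
    length(g)
  }, integer(1))
}
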