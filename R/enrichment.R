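# Running-sum enrichment of gene sets in ranked instances, robust
# median/MAD standardization across instances, and thresholded drug-process
# edges.

# Walk the ranked list once.  Increments are the classic unweighted
# zero-sum pair: +sqrt((N-Ns)/Ns) on a member, -sqrt(Ns/(N-Ns)) on a
# non-member, so the sum returns to 0 exactly at position N.  The walk is
# carried out in exact integer arithmetic — hit +(N-Ns), miss -Ns, the
# same pair up to the positive factor sqrt(Ns*(N-Ns)) — and rescaled once
# at the end, so the zero-sum identity and all tie comparisons are exact.
# Under convention "signed" the score is the signed running-sum value at
# its maximum |deviation| from zero; under "positive" it is the maximum of
# the running sum itself (the largest deviation above zero along the
# traversed list).  Ties go to the earliest position (which.max returns
# the first maximum).
.running_es <- function(hit, convention = "signed") {
  n <- length(hit)
  ns <- sum(hit)
  cs <- cumsum(ifelse(hit, n - ns, -ns)) # exact while |cs| <= Ns*(N-Ns)
  at <- if (convention == "signed") which.max(abs(cs)) else which.max(cs)
  scale <- sqrt(ns * (n - ns))
  list(es = cs[at] / scale, at = at, final = cs[n] / scale, n_hits = ns)
}

#' Running-sum enrichment score of a gene set in one ranked instance
#'
#' Walks the instance's ranked gene list, adding `sqrt((N-Ns)/Ns)` whenever a
#' set member is met and subtracting `sqrt(Ns/(N-Ns))` otherwise (N = list
#' length, Ns = members present in the list).  The enrichment score (ES) is
#' the signed value of the running sum at its maximum absolute deviation from
#' zero; the increments are zero-sum, so the running sum ends at 0 exactly.
#' A set concentrated near the top of the list scores a large positive ES.
#' Down-regulation is scored by traversing the reversed list
#' (`direction = "down"`).
#'
#' Two score conventions are offered.  `"signed"` (the default here) is the
#' classic two-sided statistic: the signed running-sum value at its maximum
#' absolute deviation from zero.  Because the reversed-list walk mirrors
#' and negates the forward walk, the signed down score is exactly the
#' negated up score, and across independent instances the signed null is
#' bimodal.  `"positive"` is the one-sided statistic — the maximum of the
#' running sum along the traversed list — which makes the two traversal
#' directions genuinely distinct one-sided tests with a unimodal null; the
#' pipeline standardizes that statistic (see [compute_es_matrix()]).
#'
#' @param ordered_genes character vector; the instance's genes in rank order
#'   (rank 1 = most up-regulated), see [ordered_genes()].
#' @param genes character vector of gene-set members (a [gene_sets()] record's
#'   `$genes`, or any id vector).
#' @param direction `"up"` scores enrichment at the top of the list, `"down"`
#'   at the bottom (equivalently, the top of the reversed list).
#' @param convention `"signed"` (maximum absolute deviation, signed) or
#'   `"positive"` (maximum deviation above zero); ties at the extreme go to
#'   the earliest position in either case.  The walk itself runs in exact
#'   integer arithmetic (hit `+(N-Ns)`, miss `-Ns`, the same increments up
#'   to a positive per-set factor) and is rescaled once at the end, so the
#'   zero-sum identity holds exactly.
#' @return A list with `es` (the score), `at` (1-based position of the
#'   extreme deviation along the traversed list), `n_hits` (Ns), `n` (N)
#'   and `final` (the running sum after position N — zero up to rounding,
#'   by construction).
#' @examples
#' lst <- paste0("g", 1:10)
#' compute_es(lst, c("g1", "g2"))$es # 2*sqrt(8/2) = 4
#' @export
compute_es <- function(ordered_genes, genes, direction = c("up", "down"),
                       convention = c("signed", "positive")) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  n <- length(ordered_genes)
  if (n < 2L) stop("ranked list needs at least 2 genes", call. = FALSE)
  hit <- ordered_genes %in% genes
  ns <- sum(hit)
  if (ns == 0L)
    stop("gene set has no overlap with the ranked list's universe",
         call. = FALSE)
  if (ns == n)
    stop("degenerate gene set: covers the whole universe (miss increment undefined)",
         call. = FALSE)
  if (direction == "down") hit <- rev(hit)
  r <- .running_es(hit, convention)
  list(es = r$es, at = r$at, n_hits = ns, n = n, direction = direction,
       final = r$final)
}

#' Enrichment scores for all (gene set, instance) pairs
#'
#' Applies [compute_es()] to every combination of gene set and instance.
#' Sets that would fail its preconditions in a given instance universe (no
#' overlap, or covering the whole universe) are skipped with one warning
#' summarizing the skips rather than aborting the run.
#'
#' The default convention here is `"positive"`: each direction is a
#' one-sided enrichment test of its own traversal (up on the ranked list,
#' down on the reversed list), which is what the downstream median/MAD
#' standardization assumes.  See [compute_es()] for the distinction.
#'
#' @param x a [rank_matrix()] object.
#' @param sets a [gene_sets()] collection.
#' @param direction `"up"`, `"down"`, or `"both"` (default) to score both
#'   traversal directions.
#' @param convention passed to the running-sum walk; `"positive"`
#'   (default) or `"signed"`, see [compute_es()].
#' @return A data frame with one row per scored (set, instance, direction):
#'   columns `go_id`, `instance_id`, `drug`, `direction`, `es`, `set_size`
#'   (members present in the universe).
#' @export
compute_es_matrix <- function(x, sets, direction = c("both", "up", "down"),
                              convention = c("positive", "signed")) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  stopifnot(inherits(x, "pse_rank_matrix"))
  if (!inherits(sets, "pse_gene_sets") || length(sets) == 0L)
    stop("`sets` must be a nonempty pse_gene_sets collection", call. = FALSE)
  if (ncol(x$ranks) == 0L)
    stop("rank matrix has no instances", call. = FALSE)
  dirs <- if (direction == "both") c("up", "down") else direction

  uni <- rownames(x$ranks)
  n <- length(uni)
  # membership of each set against the shared universe, computed once
  memb <- lapply(sets, function(s) uni %in% s$genes)
  ns <- vapply(memb, sum, integer(1))
  ok <- ns >= 1L & ns < n
  if (any(!ok)) {
    warning(sprintf("skipping %d set(s) with no usable overlap: %s",
                    sum(!ok),
                    paste(head(names(sets)[!ok], 5L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(ok)
  inst_ids <- colnames(x$ranks)
  drugs <- x$instances$drug

  rows <- vector("list", length(inst_ids) * length(keep) * length(dirs))
  k <- 0L
  for (j in seq_along(inst_ids)) {
    ord <- order(x$ranks[, j])
    for (i in keep) {
      hit_up <- memb[[i]][ord]
      for (d in dirs) {
        hit <- if (d == "down") rev(hit_up) else hit_up
        r <- .running_es(hit, convention)
        k <- k + 1L
        rows[[k]] <- list(go_id = names(sets)[i], instance_id = inst_ids[j],
                          drug = drugs[j], direction = d, es = r$es,
                          set_size = ns[[i]])
      }
    }
  }
  out <- do.call(rbind.data.frame, c(rows[seq_len(k)],
                                     list(stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Robust median/MAD t-scores of enrichment scores
#'
#' For each (gene set, direction) the ES values across all instances are
#' standardized against their median and median absolute deviation:
#' `t = (ES - MED) / (1.4826 * MAD)`.  The factor 1.4826 makes the MAD a
#' consistent estimator of the standard deviation under normality, so `t`
#' reads like a z-score that is robust to the few drug-responsive outlier
#' instances that the method is hunting for.  Groups whose MAD is zero
#' (constant ES) are flagged degenerate and produce no t-scores.
#'
#' @param es data frame from [compute_es_matrix()] (columns `go_id`,
#'   `instance_id`, `drug`, `direction`, `es`, `set_size`).
#' @return A list with `tscores` (the input rows of non-degenerate groups
#'   plus a `t` column) and `stats` (per-group `go_id`, `direction`,
#'   `median`, `mad`, `n`, `degenerate`).  The `mad` column is the raw
#'   median absolute deviation; the 1.4826 scale enters only in `t`.
#' @export
median_mad_tscores <- function(es) {
  req <- c("go_id", "direction", "es")
  if (!is.data.frame(es) || !all(req %in% names(es)))
    stop("`es` must be a data frame with columns go_id, direction, es",
         call. = FALSE)
  key <- paste(es$go_id, es$direction, sep = "\r")
  grp <- split(seq_len(nrow(es)), key)
  sizes <- lengths(grp)
  if (any(sizes < 2L))
    stop(sprintf("%d (go_id, direction) group(s) have fewer than 2 instances",
                 sum(sizes < 2L)), call. = FALSE)
  stats_rows <- vector("list", length(grp))
  t_all <- rep(NA_real_, nrow(es))
  degenerate_idx <- logical(nrow(es))
  for (g in seq_along(grp)) {
    idx <- grp[[g]]
    v <- es$es[idx]
    med <- stats::median(v)
    mad_raw <- stats::median(abs(v - med))
    degen <- mad_raw == 0
    if (!degen) t_all[idx] <- (v - med) / (1.4826 * mad_raw)
    degenerate_idx[idx] <- degen
    stats_rows[[g]] <- list(go_id = es$go_id[idx[1L]],
                            direction = es$direction[idx[1L]],
                            median = med, mad = mad_raw,
                            n = length(idx), degenerate = degen)
  }
  stats_df <- do.call(rbind.data.frame,
                      c(stats_rows, list(stringsAsFactors = FALSE)))
  rownames(stats_df) <- NULL
  tsc <- es[!degenerate_idx, , drop = FALSE]
  tsc$t <- t_all[!degenerate_idx]
  rownames(tsc) <- NULL
  list(tscores = tsc, stats = stats_df)
}

#' Threshold t-scores into drug-process edges
#'
#' Keeps (gene set, instance) pairs whose t-score exceeds `t_threshold`
#' (strictly, by default) and whose set has at most `max_set_genes` members
#' in the supplied universe, then attaches the instance's drug.  With
#' `aggregate = "union"` every passing instance yields an edge (an edge
#' exists if any instance of the drug passes); with `aggregate = "max_t"`
#' only the best-scoring instance per (drug, set, direction) is kept.
#'
#' @param tscores the `tscores` data frame from [median_mad_tscores()].
#' @param t_threshold minimum t-score (default 3.0, approximately p = 0.001
#'   one-sided under normality).
#' @param max_set_genes maximum gene-set size counted against the universe
#'   (default 30, i.e. sets with fewer than 31 genes).
#' @param aggregate `"union"` (default) or `"max_t"`; see above.
#' @param strict keep `t > t_threshold` when `TRUE` (default), `>=` otherwise.
#' @return Data frame of edges: `drug`, `go_id`, `direction`, `t`,
#'   `instance_id`.
#' @export
filter_edges <- function(tscores, t_threshold = 3.0, max_set_genes = 30L,
                         aggregate = c("union", "max_t"), strict = TRUE) {
  aggregate <- match.arg(aggregate)
  .assert_scalar_number(t_threshold, "t_threshold")
  if (t_threshold <= 0) stop("`t_threshold` must be > 0", call. = FALSE)
  req <- c("go_id", "instance_id", "drug", "direction", "t", "set_size")
  if (!is.data.frame(tscores) || !all(req %in% names(tscores)))
    stop("`tscores` must carry columns ", paste(req, collapse = ", "),
         call. = FALSE)
  pass_t <- if (strict) tscores$t > t_threshold else tscores$t >= t_threshold
  keep <- pass_t & tscores$set_size <= max_set_genes
  out <- tscores[keep, c("drug", "go_id", "direction", "t", "instance_id"),
                 drop = FALSE]
  if (aggregate == "max_t" && nrow(out) > 1L) {
    key <- paste(out$drug, out$go_id, out$direction, sep = "\r")
    best <- unlist(lapply(split(seq_len(nrow(out)), key),
                          function(i) i[which.max(out$t[i])]),
                   use.names = FALSE)
    out <- out[sort(best), , drop = FALSE]
  }
  out <- out[order(out$drug, out$go_id, out$direction, out$instance_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
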