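# Merging the drug-process and drug-side-effect layers over shared drugs,
# CD/TD co-occurrence scoring, and permutation significance thresholds.

#' Merge the drug-process and drug-side-effect layers
#'
#' The two layers are bridged by their shared drugs (the ABC pattern:
#' A = processes, B = drugs, C = side effects).  Both layers are restricted
#' to drugs appearing in both; the result records layer sizes before and
#' after the restriction.
#'
#' @param dp_edges drug-process edges from [filter_edges()] (columns `drug`,
#'   `go_id`, `direction`).
#' @param dse_edges drug-side-effect edges from [normalize_drug_names()]
#'   (columns `drug`, `umls_cui`).
#' @return An object of class `abc_network`: list with `drugs` (the bridge),
#'   `dp` (unique drug/process/direction rows), `dse` (unique
#'   drug/side-effect rows) and `counts`.
#' @export
merge_networks <- function(dp_edges, dse_edges) {
  stopifnot(all(c("drug", "go_id", "direction") %in% names(dp_edges)),
            all(c("drug", "umls_cui") %in% names(dse_edges)))
  bridge <- sort(intersect(unique(dp_edges$drug), unique(dse_edges$drug)))
  if (length(bridge) == 0L)
    stop("empty bridge: no drug occurs in both the process and side-effect layers",
         call. = FALSE)
  dp <- unique(dp_edges[dp_edges$drug %in% bridge,
                        c("drug", "go_id", "direction"), drop = FALSE])
  keep_dse <- c("drug", "umls_cui",
                intersect("effect_name", names(dse_edges)))
  dse <- unique(dse_edges[dse_edges$drug %in% bridge, keep_dse, drop = FALSE])
  dp <- dp[order(dp$drug, dp$go_id, dp$direction), , drop = FALSE]
  dse <- dse[order(dse$drug, dse$umls_cui), , drop = FALSE]
  rownames(dp) <- rownames(dse) <- NULL
  structure(list(
    drugs = bridge, dp = dp, dse = dse,
    counts = c(drugs = length(bridge),
               effects = length(unique(dse$umls_cui)),
               processes = nrow(unique(dp[, c("go_id", "direction")])),
               dp_edges = nrow(dp), dse_edges = nrow(dse))
  ), class = "abc_network")
}

#' @export
print.abc_network <- function(x, ...) {
  cat(sprintf(paste0("<abc_network> %d bridge drugs, %d side effects, ",
                     "%d (process, direction) units\n  %d drug-process edges, ",
                     "%d drug-side-effect edges\n"),
              x$counts["drugs"], x$counts["effects"], x$counts["processes"],
              x$counts["dp_edges"], x$counts["dse_edges"]))
  invisible(x)
}

# drugs x (go_id, direction) logical incidence of the process layer
.dp_incidence <- function(network) {
  units <- unique(network$dp[, c("go_id", "direction")])
  units <- units[order(units$go_id, units$direction), , drop = FALSE]
  ukey <- paste(units$go_id, units$direction, sep = "\r")
  m <- matrix(FALSE, length(network$drugs), nrow(units),
              dimnames = list(network$drugs, ukey))
  m[cbind(match(network$dp$drug, network$drugs),
          match(paste(network$dp$go_id, network$dp$direction, sep = "\r"),
                ukey))] <- TRUE
  attr(m, "units") <- units
  m
}

#' Co-occurrence scores of (process, side effect) pairs
#'
#' For every side effect caused by at least `min_drugs` bridge drugs
#' (TD = its drug degree) and every (process, direction) perturbed by at
#' least one of those drugs, counts the drugs doing both (CD) and scores the
#' pair `CD / TD`.  A score near 1 means nearly all drugs causing the effect
#' share the process response.  Scores are kept exact here; round only for
#' display.
#'
#' @param network an [merge_networks()] result.
#' @param min_drugs minimum TD, default 2 (an effect seen with a single drug
#'   carries no co-occurrence signal).
#' @return Data frame: `umls_cui`, `go_id`, `direction`, `cd`, `td`,
#'   `score`.
#' @export
co_occurrence <- function(network, min_drugs = 2L) {
  stopifnot(inherits(network, "abc_network"))
  min_drugs <- .assert_count(min_drugs, "min_drugs", lower = 2L)
  m <- .dp_incidence(network)
  units <- attr(m, "units")
  eff_drugs <- split(network$dse$drug, network$dse$umls_cui)
  eff_drugs <- eff_drugs[lengths(lapply(eff_drugs, unique)) >= min_drugs]
  out <- vector("list", length(eff_drugs))
  for (i in seq_along(eff_drugs)) {
    drugs <- unique(eff_drugs[[i]])
    cd <- colSums(m[drugs, , drop = FALSE])
    hit <- cd > 0L
    if (!any(hit)) next
    out[[i]] <- data.frame(umls_cui = names(eff_drugs)[i],
                           go_id = units$go_id[hit],
                           direction = units$direction[hit],
                           cd = as.integer(cd[hit]),
                           td = length(drugs),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(umls_cui = character(), go_id = character(),
                      direction = character(), cd = integer(),
                      td = integer(), stringsAsFactors = FALSE)
  out$score <- out$cd / out$td
  out <- out[order(out$umls_cui, out$go_id, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation null thresholds for co-occurrence counts
#'
#' For each observed side-effect drug degree TD, draws TD drugs uniformly
#' without replacement from the bridge drug pool `n_perm` times, recomputes
#' the per-(process, direction) co-occurrence counts against the real
#' drug-process layer, and pools the counts over processes and draws into an
#' empirical null.  The threshold for that TD is the smallest count
#' `cd >= 2` whose null tail probability `P(null >= cd)` is below `alpha`;
#' when even the largest attainable count is not rare enough the TD is
#' marked unattainable (`min_cd = NA`).
#'
#' @param network an [merge_networks()] result.
#' @param tds integer vector of TD values to calibrate; defaults to all
#'   degrees observed in the side-effect layer (capped at `min_drugs = 2`
#'   and the pool size).
#' @param n_perm number of permutations per TD, default 1000.
#' @param alpha significance level, default 0.05; comparison is strict
#'   (`p < alpha`).
#' @param seed optional integer; same seed, same table.
#' @param plus_one add the plus-one small-sample correction to the
#'   empirical tail probability (default `FALSE`, matching a literal
#'   "p < alpha" reading of the pooled empirical tail).
#' @return An object of class `co_threshold_table`: data frame with columns
#'   `td`, `min_cd` (NA when unattainable); attributes `alpha`, `n_perm`
#'   and `null` (named list of tabulated null counts per TD, used for
#'   diagnostics).
#' @export
permutation_thresholds <- function(network, tds = NULL, n_perm = 1000L,
                                   alpha = 0.05, seed = NULL,
                                   plus_one = FALSE) {
  stopifnot(inherits(network, "abc_network"))
  n_perm <- .assert_count(n_perm, "n_perm")
  .assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  if (is.null(tds)) {
    deg <- tapply(network$dse$drug, network$dse$umls_cui,
                  function(v) length(unique(v)))
    tds <- sort(unique(as.integer(deg[deg >= 2L])))
  }
  tds <- sort(unique(as.integer(tds)))
  pool <- network$drugs
  if (any(tds > length(pool)))
    stop(sprintf("TD %d exceeds the bridge drug pool (%d drugs)",
                 max(tds), length(pool)), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- .dp_incidence(network)
  nulls <- vector("list", length(tds))
  min_cd <- rep(NA_integer_, length(tds))
  for (k in seq_along(tds)) {
    td <- tds[k]
    counts <- integer(0)
    acc <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      draw <- sample(length(pool), td)
      acc[[b]] <- colSums(m[draw, , drop = FALSE])
    }
    counts <- unlist(acc, use.names = FALSE)
    nulls[[k]] <- table(factor(counts, levels = 0:td))
    n_tot <- length(counts)
    for (cd in 2:td) {
      tail_n <- sum(counts >= cd)
      p <- if (plus_one) (tail_n + 1) / (n_tot + 1) else tail_n / n_tot
      if (p < alpha) { min_cd[k] <- cd; break }
    }
  }
  out <- data.frame(td = tds, min_cd = min_cd)
  names(nulls) <- as.character(tds)
  structure(out, alpha = alpha, n_perm = n_perm, null = nulls,
            class = c("co_threshold_table", "data.frame"))
}

#' Build a co-occurrence threshold table by hand
#'
#' Wraps a TD -> minimal-significant-CD mapping (e.g. one published from a
#' larger calibration) so it can be fed to [apply_thresholds()].
#'
#' @param td integer vector of side-effect drug degrees.
#' @param min_cd integer vector of minimal significant co-occurrence counts
#'   (`NA` = unattainable); thresholds below 2 are rejected.
#' @param alpha,n_perm metadata describing how the table was derived.
#' @return A `co_threshold_table`.
#' @examples
#' # a published calibration: TD 2-5 -> 2, 6-17 -> 3, 19-26 -> 4
#' co_threshold_table(c(2:17, 19, 24:26),
#'                    c(rep(2, 4), rep(3, 12), rep(4, 4)))
#' @export
co_threshold_table <- function(td, min_cd, alpha = 0.05, n_perm = NA_integer_) {
  td <- as.integer(td)
  min_cd <- as.integer(min_cd)
  stopifnot(length(td) == length(min_cd), !anyDuplicated(td))
  if (any(min_cd < 2L, na.rm = TRUE))
    stop("thresholds below the TD floor of 2 are not meaningful", call. = FALSE)
  ord <- order(td)
  structure(data.frame(td = td[ord], min_cd = min_cd[ord]),
            alpha = alpha, n_perm = n_perm,
            class = c("co_threshold_table", "data.frame"))
}

#' @export
print.co_threshold_table <- function(x, ...) {
  cat(sprintf("<co_threshold_table> alpha = %g, n_perm = %d\n",
              attr(x, "alpha"), attr(x, "n_perm")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Flag significant process/side-effect associations
#'
#' Marks an association significant when its co-occurrence count reaches the
#' permutation threshold for its side effect's drug degree
#' (`cd >= min_cd[td]`).  TDs calibrated as unattainable flag nothing.
#'
#' @param assocs data frame from [co_occurrence()].
#' @param table a [permutation_thresholds()] result.
#' @return `assocs` with a logical `significant` column.
#' @export
apply_thresholds <- function(assocs, table) {
  stopifnot(inherits(table, "co_threshold_table"),
            all(c("cd", "td") %in% names(assocs)))
  idx <- match(assocs$td, table$td)
  if (anyNA(idx) && nrow(assocs))
    stop(sprintf("no threshold entry for TD value(s): %s",
                 paste(sort(unique(assocs$td[is.na(idx)])), collapse = ", ")),
         call. = FALSE)
  thr <- table$min_cd[idx]
  assocs$significant <- !is.na(thr) & assocs$cd >= thr
  assocs
}
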