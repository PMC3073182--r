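# Simplified literature-evaluation harness: normalized-edit-distance
# matching of extracted noun phrases against GO term names, per-term
# co-occurrence counts, and top-n% overlap with a predicted term list.

#' Normalized string similarity
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))` after case-folding and
#' trimming; 1 exactly when the normalized strings are equal (two empty
#' strings count as identical), 0 when every character differs.  Symmetric
#' by construction.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' string_similarity("Antioxidant activity", "antioxidant activity") # 1
#' string_similarity("abc", "xyz")                                   # 0
#' @export
string_similarity <- function(a, b) {
  a <- tolower(trimws(as.character(a)))
  b <- tolower(trimws(as.character(b)))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  d <- as.numeric(diag(utils::adist(a, b, partial = FALSE)))
  len <- pmax(nchar(a), nchar(b))
  out <- ifelse(len == 0, 1, 1 - d / len)
  pmin(pmax(out, 0), 1)
}

#' Count phrase matches per gene-set term
#'
#' A phrase matches a term when their normalized edit-distance similarity
#' reaches `threshold`; each match increments the term's co-occurrence
#' count.  Every term appears in the output even with a zero count, so the
#' result ranks the full candidate vocabulary.
#'
#' @param phrases character vector of extracted noun phrases (one per
#'   literature occurrence; repeats count repeatedly).
#' @param terms a [gene_sets()] collection (term names are matched) or a
#'   named character vector `go_id -> term_name`.
#' @param threshold similarity cutoff in `[0, 1]`, default 0.55; matching is
#'   inclusive (`similarity >= threshold`).
#' @param effect_name optional label carried into the output.
#' @return Data frame: `go_id`, `term_name`, `effect_name`, `co_count`,
#'   `score` (count normalized by the total phrase count; 0 when there are
#'   no phrases).
#' @export
match_terms <- function(phrases, terms, threshold = 0.55,
                        effect_name = NA_character_) {
  .assert_scalar_number(threshold, "threshold", 0, 1)
  if (inherits(terms, "pse_gene_sets")) {
    ids <- names(terms)
    nm <- vapply(terms, `[[`, character(1), "term_name")
  } else {
    ids <- names(terms)
    nm <- as.character(terms)
    if (is.null(ids)) stop("`terms` needs go_id names", call. = FALSE)
  }
  phrases <- as.character(phrases)
  counts <- integer(length(ids))
  if (length(phrases)) {
    pn <- tolower(trimws(phrases))
    tn <- tolower(trimws(nm))
    d <- utils::adist(pn, tn)
    len <- outer(nchar(pn), nchar(tn), pmax)
    sim <- ifelse(len == 0, 1, 1 - d / len)
    counts <- as.integer(colSums(sim >= threshold))
  }
  data.frame(go_id = ids, term_name = nm, effect_name = effect_name,
             co_count = counts,
             score = if (length(phrases)) counts / length(phrases) else 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of predicted terms with the top-n% of a literature ranking
#'
#' Ranks the full candidate vocabulary by literature co-occurrence count
#' (descending, ties broken lexically by GO id for determinism) and, for
#' each fraction f, counts how many predicted terms fall inside the top
#' `ceiling(f * n_candidates)` of that ranking.  The top-n sets are nested,
#' so counts are non-decreasing in f.
#'
#' @param predicted character vector of predicted GO ids.
#' @param lit data frame from [match_terms()] (columns `go_id`,
#'   `co_count`).
#' @param fractions fractions of the ranking to inspect, default
#'   `0.1 .. 0.5`.
#' @return Data frame: `fraction`, `cutoff_rank`, `n_candidates`,
#'   `n_overlap`.
#' @export
topn_overlap <- function(predicted, lit, fractions = seq(0.1, 0.5, by = 0.1)) {
  stopifnot(all(c("go_id", "co_count") %in% names(lit)), nrow(lit) > 0L)
  ord <- order(-lit$co_count, lit$go_id)
  ranked <- lit$go_id[ord]
  n <- length(ranked)
  predicted <- unique(as.character(predicted))
  res <- lapply(fractions, function(f) {
    k <- ceiling(f * n)
    data.frame(fraction = f, cutoff_rank = k, n_candidates = n,
               n_overlap = sum(predicted %in% ranked[seq_len(min(k, n))]))
  })
  do.call(rbind, res)
}
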