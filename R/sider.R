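# SIDER-style drug/side-effect records: frequency parsing, frequency
# filtering and drug-name normalization against a synonym table.

#' Default map from qualitative frequency terms to scores
#'
#' Matches the frequency dialect of SIDER-style dumps: a percentage, a
#' percent range, or one of a small set of qualitative descriptors.
#' Unknown descriptors are never guessed.
#'
#' @return Named numeric vector (names are lower-case descriptors).
#' @export
default_frequency_terms <- function() {
  c(postmarketing = 0.001, rare = 0.001, infrequent = 0.01)
}

#' Parse side-effect frequency descriptions into scores
#'
#' `"26%"` parses to 0.26; a range `"10-20%"` (hyphen or en-dash) parses to
#' its midpoint 0.15; qualitative descriptors are looked up
#' (case-insensitively) in `term_map`.  Anything unrecognized yields `NA`
#' with a summary warning, never an error.
#'
#' @param x character vector of frequency descriptions.
#' @param term_map named numeric vector for qualitative terms; defaults to
#'   [default_frequency_terms()].
#' @return Numeric vector of scores in `[0, 1]`, `NA` where unparseable.
#' @examples
#' parse_frequency(c("26%", "Postmarketing", "10-20%", "sometimes"))
#' @export
parse_frequency <- function(x, term_map = default_frequency_terms()) {
  x <- as.character(x)
  s <- tolower(trimws(x))
  out <- rep(NA_real_, length(x))

  pct <- "([0-9]+(?:\\.[0-9]+)?)"
  re_single <- paste0("^", pct, "\\s*%$")
  re_range <- paste0("^", pct, "\\s*[-–]\\s*", pct, "\\s*%$")

  is_range <- grepl(re_range, s)
  if (any(is_range)) {
    lo <- as.numeric(sub(re_range, "\\1", s[is_range]))
    hi <- as.numeric(sub(re_range, "\\2", s[is_range]))
    out[is_range] <- (lo + hi) / 2 / 100
  }
  is_single <- !is_range & grepl(re_single, s)
  if (any(is_single))
    out[is_single] <- as.numeric(sub(re_single, "\\1", s[is_single])) / 100

  rest <- !is_range & !is_single
  hit <- match(s[rest], names(term_map))
  out[rest] <- unname(term_map[hit])

  bad <- is.na(out) & !is.na(x) & nzchar(s)
  if (any(bad))
    warning(sprintf("%d unrecognized frequency description(s), e.g. '%s'",
                    sum(bad), x[which(bad)[1L]]), call. = FALSE)
  out
}

#' Build side-effect records
#'
#' @param compound_id drug name/alias string used as the record's drug key in
#'   the side-effect layer (normalized via [normalize_drug_names()]).
#' @param umls_cui UMLS concept id, `C` followed by digits.
#' @param effect_name human-readable side-effect name.
#' @param freq_description raw frequency string (see [parse_frequency()]).
#' @param freq_score optional pre-resolved score in `[0, 1]`; when `NULL`
#'   it is parsed from `freq_description`.
#' @return Data frame of class `pse_side_effects` with those five columns.
#' @export
side_effect_records <- function(compound_id, umls_cui, effect_name,
                                freq_description,
                                freq_score = NULL) {
  if (!all(grepl("^C[0-9]+$", umls_cui)))
    stop("umls_cui must match 'C' followed by digits", call. = FALSE)
  if (is.null(freq_score)) freq_score <- parse_frequency(freq_description)
  if (any(!is.na(freq_score) & (freq_score < 0 | freq_score > 1)))
    stop("freq_score must lie in [0, 1]", call. = FALSE)
  out <- data.frame(compound_id = as.character(compound_id),
                    umls_cui = as.character(umls_cui),
                    effect_name = as.character(effect_name),
                    freq_description = as.character(freq_description),
                    freq_score = as.numeric(freq_score),
                    stringsAsFactors = FALSE)
  class(out) <- c("pse_side_effects", class(out))
  out
}

#' Filter side-effect records by frequency
#'
#' Keeps records whose frequency score reaches `min_freq` (inclusive by
#' default); records with missing frequency are always dropped — a relation
#' without frequency evidence cannot clear a frequency threshold.
#'
#' @param records data frame from [side_effect_records()] (or any data frame
#'   with a `freq_score` column).
#' @param min_freq threshold in `[0, 1]`, default 0.2.
#' @param strict drop ties at the threshold when `TRUE` (default `FALSE`:
#'   `freq_score >= min_freq` is kept).
#' @return The filtered data frame.
#' @export
filter_by_frequency <- function(records, min_freq = 0.2, strict = FALSE) {
  .assert_scalar_number(min_freq, "min_freq", 0, 1)
  stopifnot("freq_score" %in% names(records))
  fs <- records$freq_score
  keep <- !is.na(fs) & (if (strict) fs > min_freq else fs >= min_freq)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a drug synonym table
#'
#' @param canonical_id DrugBank-style accession of the drug.
#' @param name a name string for the drug.
#' @param name_type one of `"primary"`, `"synonym"`, `"brand"`; each
#'   canonical id must have exactly one primary name.
#' @return Data frame of class `pse_synonyms`.
#' @export
synonym_table <- function(canonical_id, name, name_type) {
  if (!all(name_type %in% c("primary", "synonym", "brand")))
    stop("name_type must be primary, synonym or brand", call. = FALSE)
  out <- data.frame(canonical_id = as.character(canonical_id),
                    name = as.character(name),
                    name_type = as.character(name_type),
                    stringsAsFactors = FALSE)
  n_primary <- tapply(out$name_type == "primary", out$canonical_id, sum)
  if (any(n_primary != 1L))
    stop("every canonical_id needs exactly one primary name", call. = FALSE)
  class(out) <- c("pse_synonyms", class(out))
  out
}

.norm_name <- function(x) tolower(trimws(x))

#' Normalize side-effect-layer drug names to canonical drug names
#'
#' Resolves each record's drug name through the synonym table (primary
#' names, synonyms and brand names) by exact match after trimming and
#' case-folding — no fuzzy matching, which silently merges distinct drugs.
#' Matched records are rewritten to carry the canonical primary name;
#' unmatched records are dropped and counted in the `unmatched` attribute.
#'
#' @param records data frame from [side_effect_records()]; the `compound_id`
#'   column holds the name to resolve.
#' @param synonyms a [synonym_table()].
#' @return Data frame of drug/side-effect edges: `drug` (canonical primary
#'   name), `umls_cui`, `effect_name`, `freq_score`; attribute `unmatched`
#'   gives the number of dropped records.
#' @export
normalize_drug_names <- function(records, synonyms) {
  stopifnot(inherits(synonyms, "pse_synonyms"),
            all(c("compound_id", "umls_cui", "effect_name", "freq_score")
                %in% names(records)))
  key <- .norm_name(synonyms$name)
  # a single name string mapping to two canonical drugs is unresolvable
  amb <- tapply(synonyms$canonical_id, key, function(v) length(unique(v)))
  if (any(amb > 1L)) {
    bad <- names(amb)[amb > 1L]
    stop(sprintf("ambiguous synonym table: name(s) %s map to multiple drugs",
                 paste(sprintf("'%s'", head(bad, 5L)), collapse = ", ")),
         call. = FALSE)
  }
  primary <- synonyms$name[synonyms$name_type == "primary"]
  names(primary) <- synonyms$canonical_id[synonyms$name_type == "primary"]

  idx <- match(.norm_name(records$compound_id), key)
  matched <- !is.na(idx)
  canon <- unname(primary[synonyms$canonical_id[idx[matched]]])
  out <- data.frame(drug = canon,
                    umls_cui = records$umls_cui[matched],
                    effect_name = records$effect_name[matched],
                    freq_score = records$freq_score[matched],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$drug, out$umls_cui), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- sum(!matched)
  out
}
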