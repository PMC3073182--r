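# Independent oracles and small fixture builders shared across test files.

# Naive running-sum oracle: explicit scalar loop, tracking the extreme with
# a strict improvement rule so the earliest index wins ties.  Kept
# deliberately separate from the package's vectorized path.
oracle_es <- function(ordered, members, direction = "up",
                      convention = "signed") {
  if (direction == "down") ordered <- rev(ordered)
  hits <- ordered %in% members
  n <- length(ordered)
  ns <- sum(hits)
  # integer walk (hit +(n-ns), miss -ns) rescaled at the end: the increment
  # pair equals sqrt((n-ns)/ns) / -sqrt(ns/(n-ns)) times sqrt(ns*(n-ns))
  s <- 0L
  best_key <- -Inf
  best_val <- NA_integer_
  best_at <- NA_integer_
  for (j in seq_len(n)) {
    s <- s + (if (hits[j]) n - ns else -ns)
    key <- if (convention == "signed") abs(s) else s
    if (key > best_key) {
      best_key <- key
      best_val <- s
      best_at <- j
    }
  }
  scale <- sqrt(ns * (n - ns))
  list(es = best_val / scale, at = best_at, final = s / scale)
}

# Median/MAD by explicit sorting, independent of stats::median.
oracle_med_mad <- function(v) {
  srt <- sort(v)
  n <- length(srt)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else mean(srt[n / 2 + 0:1])
  dev <- sort(abs(v - med))
  mad <- if (n %% 2 == 1) dev[(n + 1) / 2] else mean(dev[n / 2 + 0:1])
  c(med = med, mad = mad)
}

# A ranked-instance fixture: universe g1..gN with a given member placement.
ranked_universe <- function(n) paste0("g", seq_len(n))

# Small scenario the full pipeline can chew through in well under a second.
mini_scenario <- function(seed = 7, planted_strength = 0.8, n_drugs = 15L,
                          n_effects = 6L, drugs_per_effect = 3L) {
  generate_scenario(scenario_config(
    n_genes = 500L, n_sets = 40L, set_size_range = c(5L, 15L),
    n_drugs = n_drugs, n_effects = n_effects,
    drugs_per_effect = drugs_per_effect,
    planted_strength = planted_strength, seed = seed))
}

# Hand-built ABC network: explicit drug-process and drug-side-effect edges.
toy_network <- function(dp, dse) {
  merge_networks(
    data.frame(drug = dp$drug, go_id = dp$go_id,
               direction = if (is.null(dp$direction)) "up" else dp$direction,
               stringsAsFactors = FALSE),
    data.frame(drug = dse$drug, umls_cui = dse$umls_cui,
               stringsAsFactors = FALSE))
}

# Exhaustive permutation null: enumerate every td-subset of the drug pool
# and tabulate per-process co-occurrence counts.
oracle_null_counts <- function(network, td) {
  pool <- network$drugs
  dp <- network$dp
  combos <- utils::combn(pool, td, simplify = FALSE)
  units <- unique(dp[, c("go_id", "direction")])
  counts <- integer(0)
  for (drugs in combos) {
    for (u in seq_len(nrow(units))) {
      hit <- dp$drug[dp$go_id == units$go_id[u] &
                       dp$direction == units$direction[u]]
      counts <- c(counts, sum(drugs %in% hit))
    }
  }
  counts
}
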