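test_that("network merge bridges exactly the drugs present in both layers", {
  dp <- data.frame(drug = c("a", "b", "c"), go_id = "GO:1", direction = "up")
  dse <- data.frame(drug = c("b", "c", "d"), umls_cui = "C1")
  net <- merge_networks(dp, dse)
  expect_identical(net$drugs, c("b", "c"))
  expect_true(all(net$dp$drug %in% net$drugs))
  expect_true(all(net$dse$drug %in% net$drugs))

  expect_error(merge_networks(dp, data.frame(drug = "z", umls_cui = "C1")),
               "empty bridge")
})

test_that("seeded scenario drugs survive the merge per ground truth", {
  sc <- mini_scenario(seed = 31)
  dp <- data.frame(drug = unique(sc$ground_truth$drug_process$drug),
                   go_id = "GO:1", direction = "up")
  dse <- normalize_drug_names(filter_by_frequency(sc$side_effects),
                              sc$synonyms)
  net <- merge_networks(dp, dse)
  expect_setequal(net$drugs, unique(sc$ground_truth$drug_effect$drug))
})

test_that("co-occurrence counts and scores follow the CD/TD definition", {
  # effect C1: drugs d1..d4 (TD 4); process GO:1 hit by d1,d2,d3 (CD 3)
  net <- toy_network(
    dp = data.frame(drug = c("d1", "d2", "d3", "d4"),
                    go_id = c("GO:1", "GO:1", "GO:1", "GO:2")),
    dse = data.frame(drug = c("d1", "d2", "d3", "d4", "d5hasnoedge"),
                     umls_cui = "C1"))
  assoc <- co_occurrence(net)
  # d5 never bridges, so TD = 4
  expect_identical(unique(assoc$td), 4L)
  expect_identical(assoc$cd[assoc$go_id == "GO:1"], 3L)
  expect_equal(assoc$score[assoc$go_id == "GO:1"], 3 / 4)
  expect_equal(assoc$score[assoc$go_id == "GO:2"], 1 / 4)
  # cd = td reaches the score ceiling of 1
  net2 <- toy_network(dp = data.frame(drug = c("d1", "d2"), go_id = "GO:1"),
                      dse = data.frame(drug = c("d1", "d2"), umls_cui = "C1"))
  expect_equal(co_occurrence(net2)$score, 1)
})

test_that("effects below the minimum drug count are excluded entirely", {
  net <- toy_network(
    dp = data.frame(drug = c("d1", "d2"), go_id = "GO:1"),
    dse = data.frame(drug = c("d1", "d2", "d1"),
                     umls_cui = c("C1", "C1", "C2")))
  assoc <- co_occurrence(net)
  expect_false("C2" %in% assoc$umls_cui) # TD = 1
  expect_true("C1" %in% assoc$umls_cui)
  expect_error(co_occurrence(net, min_drugs = 1), "min_drugs")
})

test_that("per-effect CD totals conserve the drug-process hit count", {
  sc <- mini_scenario(seed = 41)
  run <- run_pipeline(sc$rank_matrix, sc$gene_sets, sc$side_effects,
                      sc$synonyms, pipeline_config(n_perm = 50, seed = 1))
  net <- run$network
  assoc <- run$associations
  for (cui in unique(assoc$umls_cui)) {
    drugs <- unique(net$dse$drug[net$dse$umls_cui == cui])
    hits <- nrow(net$dp[net$dp$drug %in% drugs, ])
    expect_identical(sum(assoc$cd[assoc$umls_cui == cui]), hits)
  }
})

test_that("permutation thresholds hit the floor at alpha = 1", {
  net <- toy_network(
    dp = data.frame(drug = paste0("d", 1:4), go_id = rep(c("GO:1", "GO:2"), 2)),
    dse = data.frame(drug = paste0("d", 1:4), umls_cui = "C1"))
  tab <- permutation_thresholds(net, tds = c(2, 3), n_perm = 50, alpha = 1,
                                seed = 1)
  expect_identical(tab$min_cd, c(2L, 2L))
})

test_that("a universally-hit process makes the threshold unattainable", {
  # all 4 drugs hit the same single process: every draw of 2 has cd = 2,
  # so P(null >= 2) = 1 and nothing can be significant
  net <- toy_network(dp = data.frame(drug = paste0("d", 1:4), go_id = "GO:1"),
                     dse = data.frame(drug = paste0("d", c(1, 2, 1, 3)),
                                      umls_cui = c("C1", "C1", "C2", "C2")))
  exhaustive <- oracle_null_counts(net, 2)
  expect_true(all(exhaustive == 2L))
  tab <- permutation_thresholds(net, tds = 2, n_perm = 200, alpha = 0.05,
                                seed = 3)
  expect_true(is.na(tab$min_cd))
  assoc <- co_occurrence(net)
  flagged <- apply_thresholds(assoc, tab)
  expect_false(any(flagged$significant))
})

test_that("thresholds are reproducible under a fixed seed", {
  sc <- mini_scenario(seed = 51)
  run <- run_pipeline(sc$rank_matrix, sc$gene_sets, sc$side_effects,
                      sc$synonyms, pipeline_config(n_perm = 100, seed = 9))
  t1 <- permutation_thresholds(run$network, n_perm = 100, seed = 12)
  t2 <- permutation_thresholds(run$network, n_perm = 100, seed = 12)
  expect_identical(t1, t2)
  expect_error(permutation_thresholds(run$network, tds = 10000),
               "exceeds the bridge")
})

test_that("thresholds relax as alpha grows", {
  sc <- mini_scenario(seed = 61)
  run <- run_pipeline(sc$rank_matrix, sc$gene_sets, sc$side_effects,
                      sc$synonyms, pipeline_config(n_perm = 100, seed = 2))
  strictv <- permutation_thresholds(run$network, n_perm = 400, alpha = 0.01,
                                    seed = 5)
  loose <- permutation_thresholds(run$network, n_perm = 400, alpha = 0.2,
                                  seed = 5)
  both <- merge(as.data.frame(strictv), as.data.frame(loose), by = "td",
                suffixes = c("_strict", "_loose"))
  ok <- !is.na(both$min_cd_strict) & !is.na(both$min_cd_loose)
  expect_true(all(both$min_cd_loose[ok] <= both$min_cd_strict[ok]))
  # unattainable at strict alpha can only become attainable, never vice versa
  expect_true(all(!is.na(both$min_cd_loose[!is.na(both$min_cd_strict)])))
})

test_that("hand-built threshold tables apply published TD semantics", {
  tab <- co_threshold_table(c(2:17, 19, 24:26),
                            c(rep(2, 4), rep(3, 12), rep(4, 4)))
  assoc <- data.frame(umls_cui = "C1", go_id = paste0("GO:", 1:3),
                      direction = "up",
                      cd = c(2L, 2L, 4L), td = c(4L, 10L, 26L),
                      score = c(0.5, 0.2, 4 / 26))
  out <- apply_thresholds(assoc, tab)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE))
  expect_error(apply_thresholds(transform(assoc, td = 99L), tab),
               "no threshold entry")
  expect_error(co_threshold_table(2, 1), "floor")
})
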