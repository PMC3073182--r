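test_that("scenario configuration validates its invariants", {
  expect_s3_class(scenario_config(), "scenario_config")
  expect_error(scenario_config(n_genes = 50, set_size_range = c(5, 50)),
               "smaller than the gene universe")
  expect_error(scenario_config(set_size_range = c(10, 5)), "increasing pair")
  expect_error(scenario_config(planted_strength = 1.2), "planted_strength")
  expect_error(scenario_config(n_drugs = 0), "n_drugs")
  expect_error(scenario_config(n_sets = 3, n_effects = 5), "distinct gene set")
  expect_error(scenario_config(n_drugs = 2, drugs_per_effect = 3),
               "cannot exceed")
})

test_that("every rank-matrix column is a permutation of the universe", {
  sc <- generate_scenario(scenario_config(
    n_genes = 100, n_sets = 10, set_size_range = c(3, 6), n_drugs = 5,
    n_effects = 2, drugs_per_effect = 2, seed = 1))
  m <- sc$rank_matrix$ranks
  expect_identical(ncol(m), 5L)
  for (j in seq_len(ncol(m)))
    expect_identical(sort(unname(m[, j])), 1:100)
})

test_that("identical seeds reproduce the scenario bit for bit", {
  cfg <- scenario_config(n_genes = 120, n_sets = 8, set_size_range = c(3, 6),
                         n_drugs = 6, n_effects = 3, drugs_per_effect = 2,
                         seed = 99)
  expect_identical(generate_scenario(cfg), generate_scenario(cfg))
  cfg2 <- scenario_config(n_genes = 120, n_sets = 8, set_size_range = c(3, 6),
                          n_drugs = 6, n_effects = 3, drugs_per_effect = 2,
                          seed = 100)
  expect_false(identical(generate_scenario(cfg), generate_scenario(cfg2)))
})

test_that("full-strength planting puts every set gene in the extreme decile", {
  sc <- generate_scenario(scenario_config(
    n_genes = 200, n_sets = 6, set_size_range = c(5, 10), n_drugs = 4,
    n_effects = 1, drugs_per_effect = 1, planted_strength = 1.0, seed = 3))
  plant <- sc$ground_truth$drug_process[1, ]
  inst <- sc$rank_matrix$instances$instance_id[
    sc$rank_matrix$instances$drug == plant$drug][1]
  genes <- sc$gene_sets[[plant$go_id]]$genes
  ranks <- sc$rank_matrix$ranks[genes, inst]
  decile <- floor(0.1 * 200)
  if (plant$direction == "up") {
    expect_true(all(ranks <= decile))
  } else {
    expect_true(all(ranks > 200 - decile))
  }
})

test_that("planted links pass the frequency filter and decoys fail it", {
  sc <- mini_scenario(seed = 2)
  se <- sc$side_effects
  key <- paste(se$compound_id, se$umls_cui)
  gt_key <- paste(sc$ground_truth$drug_effect$drug,
                  sc$ground_truth$drug_effect$umls_cui)
  expect_true(all(se$freq_score[key %in% gt_key] >= 0.25))
  expect_true(all(se$freq_score[!key %in% gt_key] <= 0.1))
  # frequency descriptions round-trip through the parser
  expect_equal(parse_frequency(se$freq_description), se$freq_score)
})

test_that("drugs sharing a planted effect share a planted process", {
  sc <- mini_scenario(seed = 13)
  gt <- sc$ground_truth
  for (i in seq_len(nrow(gt$process_effect))) {
    cui <- gt$process_effect$umls_cui[i]
    drugs <- gt$drug_effect$drug[gt$drug_effect$umls_cui == cui]
    proc <- gt$process_effect$go_id[i]
    planted_drugs <- gt$drug_process$drug[gt$drug_process$go_id == proc]
    expect_true(all(drugs %in% planted_drugs))
  }
})

test_that("synonym collisions rename the side-effect layer but not the bridge", {
  sc <- mini_scenario(seed = 21)
  expect_identical(make_synonym_collisions(sc, 0), sc)

  aliased <- make_synonym_collisions(sc, 1)
  primaries <- aliased$synonyms$name[aliased$synonyms$name_type == "primary"]
  expect_false(any(aliased$side_effects$compound_id %in% primaries))

  cfg <- pipeline_config(n_perm = 50, seed = 4)
  run_plain <- run_pipeline(sc$rank_matrix, sc$gene_sets, sc$side_effects,
                            sc$synonyms, cfg)
  run_alias <- run_pipeline(aliased$rank_matrix, aliased$gene_sets,
                            aliased$side_effects, aliased$synonyms, cfg)
  expect_identical(run_alias$summary$n_bridge_drugs,
                   run_plain$summary$n_bridge_drugs)
  expect_identical(run_alias$dse_edges, run_plain$dse_edges)
})
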