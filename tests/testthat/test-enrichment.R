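test_that("running-sum score matches hand-derived worked examples", {
  lst <- ranked_universe(10)
  # both members at the very top: 2 * sqrt((10-2)/2) = 4
  r <- compute_es(lst, c("g1", "g2"))
  expect_identical(r$es, 2 * sqrt(8 / 2))
  expect_identical(r$at, 2L)

  # members at ranks 2 and 4 of 4: partial sums (-1, 0, -1, 0); the signed
  # extreme is -1, reached first at position 1
  lst4 <- ranked_universe(4)
  r4 <- compute_es(lst4, c("g2", "g4"))
  expect_identical(r4$es, -1)
  expect_identical(r4$at, 1L)
  # one-sided convention: the running sum never rises above 0, first hit at
  # position 2
  r4p <- compute_es(lst4, c("g2", "g4"), convention = "positive")
  expect_identical(r4p$es, 0)
  expect_identical(r4p$at, 2L)
})

test_that("invalid gene sets are rejected with informative errors", {
  lst <- ranked_universe(10)
  expect_error(compute_es(lst, c("x1", "x2")), "no overlap")
  expect_error(compute_es(lst, lst), "degenerate")
  expect_error(compute_es("g1", "g1"), "at least 2")
})

test_that("vectorized scorer equals the exhaustive partial-sum oracle", {
  set.seed(42)
  for (case in 1:150) {
    n <- sample(5:50, 1)
    ns <- sample(seq_len(n - 1), 1)
    lst <- sample(ranked_universe(n))
    members <- sample(lst, ns)
    dir <- sample(c("up", "down"), 1)
    conv <- sample(c("signed", "positive"), 1)
    got <- compute_es(lst, members, dir, conv)
    want <- oracle_es(lst, members, dir, conv)
    expect_identical(got$es, want$es)
    expect_identical(got$at, want$at)
  }
})

test_that("zero-sum increments return the running sum to zero", {
  set.seed(11)
  for (case in 1:50) {
    n <- sample(10:80, 1)
    lst <- sample(ranked_universe(n))
    members <- sample(lst, sample(seq_len(n - 1), 1))
    expect_lt(abs(oracle_es(lst, members)$final), 1e-9)
  }
})

test_that("down-direction scoring equals up-scoring of the reversed list", {
  set.seed(5)
  for (case in 1:25) {
    n <- sample(10:60, 1)
    lst <- sample(ranked_universe(n))
    members <- sample(lst, sample(seq_len(n - 1), 1))
    for (conv in c("signed", "positive"))
      expect_identical(compute_es(lst, members, "down", conv)$es,
                       compute_es(rev(lst), members, "up", conv)$es)
  }
})

make_small_rm <- function(n_genes = 30, n_inst = 5, seed = 3) {
  set.seed(seed)
  g <- ranked_universe(n_genes)
  m <- vapply(seq_len(n_inst), function(j) sample.int(n_genes), integer(n_genes))
  dimnames(m) <- list(g, paste0("i", seq_len(n_inst)))
  rank_matrix(m, data.frame(instance_id = colnames(m),
                            drug = paste0("d", seq_len(n_inst))))
}

test_that("matrix scoring covers every pair and matches per-pair calls", {
  rm <- make_small_rm()
  set.seed(8)
  sets <- gene_sets(sprintf("GO:%07d", 1:10), paste("term", 1:10),
                    lapply(1:10, function(i) sample(universe(rm), 5)))
  es <- compute_es_matrix(rm, sets, direction = "up")
  expect_identical(nrow(es), 50L)
  es_both <- compute_es_matrix(rm, sets)
  expect_identical(nrow(es_both), 100L)
  for (k in sample(nrow(es_both), 20)) {
    row <- es_both[k, ]
    single <- compute_es(ordered_genes(rm, row$instance_id),
                         sets[[row$go_id]]$genes, row$direction,
                         convention = "positive")
    expect_identical(row$es, single$es)
  }
})

test_that("sets without usable overlap are skipped with a warning", {
  rm <- make_small_rm()
  sets <- gene_sets(c("GO:0000001", "GO:0000002"), c("ok", "alien"),
                    list(universe(rm)[1:4], c("zz1", "zz2")))
  expect_warning(es <- compute_es_matrix(rm, sets, direction = "up"),
                 "skipping 1 set")
  expect_identical(nrow(es), 5L)
  expect_setequal(unique(es$go_id), "GO:0000001")
})

test_that("median/MAD t-scores match independent sorting-based computation", {
  mk <- function(v) data.frame(go_id = "GO:1", instance_id = seq_along(v),
                               drug = "d", direction = "up", es = v,
                               set_size = 5L)
  out <- median_mad_tscores(mk(c(1, 2, 3, 4, 100)))
  om <- oracle_med_mad(c(1, 2, 3, 4, 100))
  expect_equal(om[["med"]], 3)
  expect_equal(om[["mad"]], 1)
  expect_equal(out$tscores$t[out$tscores$es == 100], 97 / 1.4826)
  expect_equal(out$stats$median, 3)
  expect_equal(out$stats$mad, 1)

  out2 <- median_mad_tscores(mk(c(-1, 0, 1)))
  expect_equal(out2$tscores$t[out2$tscores$es == 1], 1 / 1.4826)
  expect_equal(out2$tscores$t[out2$tscores$es == 1], 0.6745, tolerance = 1e-4)

  # constant rows are flagged degenerate, not given infinite t
  out3 <- median_mad_tscores(mk(c(2, 2, 2)))
  expect_identical(nrow(out3$tscores), 0L)
  expect_true(out3$stats$degenerate)

  expect_error(median_mad_tscores(mk(1)), "fewer than 2")
})

test_that("t-scores are invariant under positive per-set rescaling of ES", {
  set.seed(21)
  es <- data.frame(go_id = rep(c("GO:1", "GO:2"), each = 8),
                   instance_id = rep(1:8, 2), drug = rep(letters[1:8], 2),
                   direction = "up", es = rnorm(16), set_size = 10L)
  base <- median_mad_tscores(es)
  scaled <- es
  scaled$es[scaled$go_id == "GO:1"] <- scaled$es[scaled$go_id == "GO:1"] * 37.5
  out <- median_mad_tscores(scaled)
  expect_equal(out$tscores$t, base$tscores$t)
})

test_that("edge filtering applies strict t cutoff and set-size cap", {
  tsc <- data.frame(
    go_id = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5"),
    instance_id = paste0("i", 1:5), drug = paste0("d", 1:5),
    direction = "up",
    es = 1, set_size = c(30L, 30L, 31L, 30L, 12L),
    t = c(3.01, 3.0, 3.5, 4.14835, 2.99))
  kept <- filter_edges(tsc)
  expect_setequal(kept$go_id, c("GO:1", "GO:4"))
  # boundary: t = 3.0 exactly passes only the inclusive variant
  expect_true("GO:2" %in% filter_edges(tsc, strict = FALSE)$go_id)
  # size 31 fails "at most 30" even with a towering t
  expect_false("GO:3" %in% filter_edges(tsc)$go_id)
})

test_that("drug-level aggregation keeps all passing instances or the best one", {
  tsc <- data.frame(go_id = "GO:1", instance_id = c("i1", "i2", "i3"),
                    drug = "d1", direction = "up", es = 1, set_size = 10L,
                    t = c(3.5, 4.5, 2.0))
  expect_identical(nrow(filter_edges(tsc, aggregate = "union")), 2L)
  best <- filter_edges(tsc, aggregate = "max_t")
  expect_identical(best$instance_id, "i2")
})
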