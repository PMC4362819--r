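test_that("contingency tables are built from propagated pair counts", {
  onto <- chain_ontology()
  whole <- build_network(
    make_records(paste0("D", 1:4), paste0("G", 1:4), paste0("H", 1:4),
                 c("MI_0571", "MI_0902", "GO_0018377", "INO_0000140")),
    onto)
  sub <- subset_network(
    make_records(paste0("D", 1:4), paste0("G", 1:4), paste0("H", 1:4),
                 c("MI_0571", "MI_0902", "GO_0018377", "INO_0000140")),
    c("D1", "D3"), onto)
  tab <- build_table("MI_0902", sub, whole)
  expect_equal(unclass(tab)[c("a", "b", "A", "B")],
               list(a = 1, b = 1, A = 2, B = 2))
  # term absent from sub but present in whole
  tab2 <- build_table("INO_0000140", sub, whole)
  expect_equal(tab2$a, 0)
  expect_equal(tab2$b, 2)
  # identical networks give a = A, b = B
  tab3 <- build_table("MI_0571", whole, whole)
  expect_equal(tab3$a, tab3$A)
  expect_equal(tab3$b, tab3$B)
})

test_that("an empty sub-network is an error", {
  onto <- chain_ontology()
  net <- build_network(make_records("D1", "G1", "G2", "MI_0571"), onto)
  empty <- build_network(make_records(character(0), character(0),
                                      character(0), character(0)), onto)
  expect_error(build_table("MI_0571", empty, net), "empty sub-network")
  expect_error(run_enrichment(empty, net, onto), "empty sub-network")
})

test_that("table invariants are enforced", {
  expect_error(contingency_table(5, 0, 4, 100), "exceed")
  expect_error(contingency_table(-1, 0, 4, 100), "non-negative")
  expect_error(contingency_table(0.5, 0, 4, 100), "non-negative")
})

test_that("the worked 30-of-180 vs 1500-of-31500 table behaves as expected", {
  tab <- contingency_table(30, 150, 1500, 30000)
  expect_equal(enrichment_fold(tab), 3.5)
  p_mod <- modified_fisher(tab, "over")
  p_raw <- modified_fisher(tab, "over", modify = FALSE)
  # the one-pair modification is conservative
  expect_gt(p_mod, p_raw)
  # unmodified p equals the standard hypergeometric survival function
  expect_equal(p_raw, phyper(29, 1530, 30150, 180, lower.tail = FALSE))
  # and the modified p equals the tail of the shifted table
  expect_equal(p_mod, phyper(28, 1529, 30150, 179, lower.tail = FALSE))
})

test_that("zero hits cannot be over-represented", {
  expect_equal(modified_fisher(contingency_table(0, 20, 50, 500), "over"), 1)
  expect_equal(enrichment_fold(contingency_table(0, 20, 50, 500)), 0)
})

test_that("exact tails match the enumeration oracle on small tables", {
  # frozen from the brute-force lchoose enumeration (oracle_tail)
  expect_equal(modified_fisher(contingency_table(3, 7, 10, 80), "over",
                               modify = FALSE),
               oracle_tail(3, 7, 10, 80), tolerance = 1e-12)
  expect_equal(modified_fisher(contingency_table(3, 7, 10, 80), "over"),
               oracle_tail(2, 7, 10, 80), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(20:120, 1), c(1, 3, 4, 12)))
    a <- min(cells[1], cells[3])  # keep sub contained in whole
    tab <- contingency_table(a, cells[2], cells[3], cells[4])
    expect_equal(modified_fisher(tab, "over", modify = FALSE),
                 oracle_tail(a, cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_equal(modified_fisher(tab, "under", modify = FALSE),
                 oracle_tail(a, cells[2], cells[3], cells[4], upper = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("unmodified one-sided p agrees with fisher.test", {
  set.seed(9)
  for (i in 1:25) {
    a <- sample(0:15, 1); b <- sample(0:30, 1)
    A <- a + sample(0:40, 1); B <- b + sample(0:60, 1)
    m <- matrix(c(a, b, A, B), 2)
    expect_equal(modified_fisher(contingency_table(a, b, A, B), "over",
                                 modify = FALSE),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(modified_fisher(contingency_table(a, b, A, B), "under",
                                 modify = FALSE),
                 fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-10)
    expect_equal(modified_fisher(contingency_table(a, b, A, B), "over",
                                 modify = FALSE, sided = "two"),
                 fisher.test(m)$p.value, tolerance = 1e-10)
  }
})

test_that("more hits give smaller over-representation p-values", {
  n_sub <- 40L; A <- 200L; B <- 1800L
  p <- vapply(1:30, function(a) {
    modified_fisher(contingency_table(a, n_sub - a, A, B), "over")
  }, 0)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("enrichment folds come from raw counts", {
  expect_equal(enrichment_fold(contingency_table(5, 45, 100, 900)), 1)
  expect_true(is.na(enrichment_fold(contingency_table(0, 10, 0, 90))))
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.5, 0.5)), c(0.5, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("BH is permutation-equivariant, monotone and matches the oracle", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # rank-monotone
  }
})

test_that("run_enrichment applies the minimum-pair filter to the tested set", {
  onto <- chain_ontology()
  # 6 pairs on MI_0571 (passes), 4 pairs on GO_0018377 (excluded)
  rec <- rbind(
    make_records(paste0("D", 1:6), paste0("G", 1:6), paste0("H", 1:6),
                 "MI_0571"),
    make_records(paste0("E", 1:4), paste0("G", 11:14), paste0("H", 11:14),
                 "GO_0018377"),
    make_records(paste0("F", 1:30), paste0("G", 21:50), paste0("H", 21:50),
                 "INO_0000140"))
  whole <- build_network(rec, onto)
  sub <- subset_network(rec, c(paste0("D", 1:6), paste0("E", 1:4)), onto)
  res <- run_enrichment(sub, whole, onto, min_pairs = 5)
  expect_false("GO_0018377" %in% res$term_id)
  expect_true("MI_0571" %in% res$term_id)
  # BH m equals the size of the tested set
  expect_equal(res$p_bh, bh_adjust(res$p_raw))
})

test_that("direction calls respect fold thresholds and exclusivity", {
  cfg <- sim_config(seed = 55, n_terms = 15, n_genes = 60,
                    n_pairs_whole = 800, n_docs_whole = 900,
                    concept_fraction = 0.25)
  sim <- simulate_records(cfg)
  onto <- simulate_ontology(cfg)
  whole <- build_network(sim$records, onto)
  sub <- subset_network(sim$records, sim$concept_docs, onto)
  res <- run_enrichment(sub, whole, onto)
  expect_true(all(res$direction %in% c("over", "under", "none")))
  expect_true(all(res$fold[res$direction == "over"] >= 2))
  expect_true(all(res$fold[res$direction == "under"] <= 0.5))
  expect_true(all(res$p_bh[res$direction != "none"] < 0.05))
  expect_true(all(res$p_bh >= res$p_raw - 1e-15))
  # a term with fold exactly 1 is never called
  expect_true(all(res$direction[abs(res$fold - 1) < 1e-12] == "none"))
  expect_false(any(duplicated(res$term_id)))
})

test_that("the most frequent gene pair is reported with its document count", {
  onto <- chain_ontology()
  rec <- rbind(
    make_records(paste0("D", 1:5), "IFNG", "IL12A", "INO_0000140"),
    make_records(paste0("D", 6:7), "CD4", "S100B", "INO_0000140"),
    make_records("D8", "AAA", "BBB", "INO_0000140"),
    make_records(paste0("D", 1:5), paste0("X", 1:5), paste0("Y", 1:5),
                 "MI_0571"))
  net <- build_network(rec, onto)
  res <- run_enrichment(net, net, onto, min_pairs = 3)
  row <- res[res$term_id == "INO_0000140", ]
  expect_equal(row$top_pair, "IFNG_IL12A")
  expect_equal(row$top_pair_docs, 5L)
})

test_that("top-pair ties break lexicographically", {
  onto <- chain_ontology()
  rec <- rbind(
    make_records(c("D1", "D2"), "ZZA", "ZZB", "MI_0571"),
    make_records(c("D3", "D4"), "AAA", "AAB", "MI_0571"),
    make_records(paste0("D", 5:9), paste0("P", 1:5), paste0("Q", 1:5),
                 "MI_0571"))
  net <- build_network(rec, onto)
  res <- run_enrichment(net, net, onto, min_pairs = 1)
  expect_equal(res$top_pair[res$term_id == "MI_0571"], "AAA_AAB")
})

test_that("results serialize to TSV with full-precision p-values", {
  onto <- chain_ontology()
  rec <- make_records(paste0("D", 1:8), paste0("G", 1:8), paste0("H", 1:8),
                      "MI_0571")
  net <- build_network(rec, onto)
  res <- run_enrichment(net, net, onto)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- utils::read.delim(path)
  expect_equal(names(back),
               c("term_id", "label", "direction", "a", "sub_total", "A",
                 "whole_total", "fold", "p_raw", "p_bh", "top_pair",
                 "top_pair_docs"))
  expect_equal(back$p_raw, res$p_raw, tolerance = 1e-6)
})
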