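mkMetas <- function(ids, site, readCount = 2e6) {
  data.frame(metagenome_id = ids, site = site,
             sample_date = as.Date("2008-06-01"), read_count = readCount,
             stringsAsFactors = FALSE)
}

test_that("hit filtering applies the inclusive identity cutoff and best-hit rule", {
  hits <- data.frame(
    metagenome_id = "mg",
    query_id = c("o1", "o2", "o3", "o3", "o4", "o4"),
    subject_id = c("A", "B", "C", "D", "E", "F"),
    percent_identity = c(30.0, 29.9, 50, 50, 60, 60),
    bitscore = c(100, 100, 90, 80, 70, 70))
  out <- filterHits(hits)
  expect_true("o1" %in% out$query_id)    # 30.0 retained, inclusive
  expect_false("o2" %in% out$query_id)   # 29.9 dropped
  expect_identical(out$subject_id[out$query_id == "o3"], "C")  # best bitscore
  expect_identical(out$subject_id[out$query_id == "o4"], "E")  # tie -> lexicographic
  expect_equal(nrow(filterHits(hits, bestHitOnly = FALSE)), 5L)
})

test_that("filtering a decoy-laden simulated table keeps exactly the planted hits", {
  cfg <- simConfig(seed = 23, decoyFraction = 0.3)
  metas <- mkMetas(sprintf("m%02d", 1:6),
                   rep(c("mendota_epi", "troutbog_epi"), each = 3))
  hits <- simulateMarkerHits(cfg, demoMarkerCatalog(), metas)
  truth <- attr(hits, "truth")
  kept <- filterHits(hits)
  perMg <- table(factor(kept$metagenome_id, levels = metas$metagenome_id))
  planted <- tapply(truth$true_hits, factor(truth$metagenome_id,
                                            levels = metas$metagenome_id), sum)
  expect_equal(as.vector(perMg), as.vector(planted))
})

test_that("abundance table normalizes to hits per million with zero-fill and conservation", {
  catalog <- data.frame(marker_id = c("A", "B"),
                        function_category = c("nitrogen fixation", "urease"))
  metas <- mkMetas("mg1", "mendota_epi", readCount = 2e6)
  hits <- data.frame(metagenome_id = "mg1",
                     query_id = sprintf("o%02d", 1:10),
                     subject_id = "A", percent_identity = 50, bitscore = 100)
  ab <- abundanceTable(hits, catalog, metas)
  expect_equal(ab$hits_per_million[ab$function_category == "nitrogen fixation"], 5.0)
  # zero-fill for the category with no hits
  expect_equal(ab$raw_hits[ab$function_category == "urease"], 0L)
  # conservation: category counts sum to retained hits
  expect_equal(sum(ab$raw_hits), nrow(hits))
  # joint xk scaling leaves hits_per_million unchanged
  k <- 3
  hitsK <- do.call(rbind, replicate(k, hits, simplify = FALSE))
  hitsK$query_id <- sprintf("o%02d", seq_len(nrow(hitsK)))
  metasK <- mkMetas("mg1", "mendota_epi", readCount = 2e6 * k)
  abK <- abundanceTable(hitsK, catalog, metasK)
  expect_equal(abK$hits_per_million, ab$hits_per_million)
  # unresolvable subjects error, or drop under the lenient flag
  bad <- rbind(hits, data.frame(metagenome_id = "mg1", query_id = "oX",
                                subject_id = "ZZZ", percent_identity = 50,
                                bitscore = 10))
  expect_error(abundanceTable(bad, catalog, metas), "ZZZ")
  expect_warning(ab2 <- abundanceTable(bad, catalog, metas, lenient = TRUE),
                 "ZZZ")
  expect_equal(sum(ab2$raw_hits), nrow(hits))
})

test_that("rank-sum test matches hand-computed exact p-values and the null", {
  rs <- rankSumTest(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(rs$p_raw, 2 / 70, tolerance = 1e-12)
  expect_equal(rs$statistic, 0)
  same <- rankSumTest(c(1, 2, 3), c(3, 2, 1))
  expect_gte(same$p_raw, 0.99)
  expect_error(rankSumTest(numeric(), 1), "non-empty")
})

test_that("exact rank-sum branch agrees with enumeration for all small tie-free inputs", {
  for (n in 2:6) for (m in n:6) {
    N <- n + m
    splits <- combn(N, n)   # exactness depends only on ranks
    wAll <- colSums(matrix(splits, nrow = n)) - n * (n + 1) / 2
    pImpl <- pOracle <- numeric(ncol(splits))
    for (j in seq_len(ncol(splits))) {
      x <- splits[, j]
      y <- setdiff(seq_len(N), x)
      pImpl[j] <- rankSumTest(x, y)$p_raw
      pOracle[j] <- min(1, 2 * min(mean(wAll <= wAll[j]),
                                   mean(wAll >= wAll[j])))
    }
    expect_equal(pImpl, pOracle, tolerance = 1e-12)
  }
})

test_that("site comparisons apply Bonferroni over categories x pairs with median direction", {
  set.seed(61)
  catalog <- data.frame(marker_id = sprintf("M%d", 1:5),
                        function_category = sprintf("cat%d", 1:5))
  metas <- mkMetas(sprintf("m%02d", 1:30),
                   rep(c("mendota_epi", "troutbog_epi", "troutbog_hypo"),
                       each = 10))
  hits <- simulateMarkerHits(simConfig(seed = 61), catalog, metas)
  ab <- abundanceTable(filterHits(hits), catalog, metas)
  cmp <- compareSites(ab, metas)
  expect_equal(nrow(cmp), 5L * 2L)
  nTests <- 10
  ok <- !is.na(cmp$p_raw)
  expect_equal(cmp$p_adjusted[ok], pmin(1, cmp$p_raw[ok] * nTests))
  expect_true(all(cmp$higher_site[ok & cmp$p_adjusted >= 0.05] == "ns"))
  # rows are invariant to abundance row order
  cmp2 <- compareSites(ab[sample(nrow(ab)), ], metas)
  expect_equal(cmp, cmp2)
})

test_that("null site effects keep the familywise significant rate controlled", {
  catalog <- data.frame(marker_id = sprintf("M%d", 1:4),
                        function_category = sprintf("cat%d", 1:4))
  metas <- mkMetas(sprintf("m%02d", 1:30),
                   rep(c("mendota_epi", "troutbog_epi", "troutbog_hypo"),
                       each = 10), readCount = 1e6)
  anySig <- vapply(1:60, function(r) {
    hits <- simulateMarkerHits(simConfig(seed = 7000 + r), catalog, metas)
    ab <- abundanceTable(filterHits(hits), catalog, metas)
    cmp <- compareSites(ab, metas)
    any(cmp$higher_site != "ns", na.rm = TRUE)
  }, TRUE)
  expect_lte(mean(anySig), 0.1)  # Bonferroni keeps familywise error near 0.05
})
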