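test_that("GH profiles count genes once, families distinctly, and ignore non-GH classes", {
  mags <- data.frame(mag_id = c("m1", "m2"), gene_count = c(100, 50))
  ann <- data.frame(
    mag_id = c("m1", "m1", "m1", "m1", "m1", "m2"),
    gene_id = c("g1", "g2", "g3", "g3", "g4", "gA"),
    cazyme_family = c("GH13", "GH13_10", "GH5", "GH13", "GT2", "CE1"))
  prof <- ghProfile(ann, mags)
  m1 <- prof[prof$mag_id == "m1", ]
  expect_equal(m1$gh_gene_count, 3L)      # g4 is GT, g3 counted once
  expect_equal(m1$gh_family_count, 2L)    # GH13 (subfamily collapsed) + GH5
  expect_equal(m1$coding_density, 3.0)
  m2 <- prof[prof$mag_id == "m2", ]
  expect_equal(unlist(m2[, 2:4], use.names = FALSE), c(0, 0, 0))
  # subfamilies kept on request
  profK <- ghProfile(ann, mags, collapseSubfamilies = FALSE)
  expect_equal(profK$gh_family_count[profK$mag_id == "m1"], 3L)
  expect_error(ghProfile(data.frame(mag_id = "zz", gene_id = "g",
                                    cazyme_family = "GH1"), mags), "zz")
})

test_that("fuzzed GH profiles match a per-gene brute-force tally", {
  set.seed(71)
  mags <- data.frame(mag_id = sprintf("m%02d", 1:10),
                     gene_count = sample(500:5000, 10))
  fams <- c(sprintf("GH%d", 1:20), "GT2", "PL1", "CE4", "CBM6", "AA3")
  ann <- data.frame(
    mag_id = sample(mags$mag_id, 800, TRUE),
    gene_id = sprintf("g%03d", sample(1:100, 800, TRUE)),
    cazyme_family = sample(fams, 800, TRUE))
  prof <- ghProfile(ann, mags)
  for (m in mags$mag_id) {
    rows <- ann[ann$mag_id == m & grepl("^GH", ann$cazyme_family), ]
    genes <- unique(rows$gene_id)
    famsSeen <- unique(sub("_.*$", "", rows$cazyme_family))
    p <- prof[prof$mag_id == m, ]
    expect_equal(p$gh_gene_count, length(genes))
    expect_equal(p$gh_family_count, length(famsSeen))
    expect_equal(p$coding_density,
                 100 * length(genes) / mags$gene_count[mags$mag_id == m])
  }
})

test_that("density-diversity correlation matches the closed form and handles degeneracy", {
  # exact line: r^2 = 1
  lin <- data.frame(mag_id = letters[1:5], coding_density = 1:5,
                    gh_family_count = 2 * (1:5) + 3)
  expect_equal(densityDiversityCorrelation(lin)$r_squared, 1.0)
  # zero centered cross-product: r^2 = 0
  orth <- data.frame(mag_id = letters[1:4],
                     coding_density = c(1, 1, -1, -1),
                     gh_family_count = c(1, -1, 1, -1))
  expect_equal(densityDiversityCorrelation(orth)$r_squared, 0.0)
  # closed-form oracle on random profiles
  set.seed(81)
  x <- runif(50); y <- 3 * x + rnorm(50, sd = 0.3)
  prof <- data.frame(mag_id = sprintf("m%02d", 1:50), coding_density = x,
                     gh_family_count = y)
  res <- densityDiversityCorrelation(prof)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(48 / (1 - r^2))
  expect_equal(res$r_squared, r^2, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 48), tolerance = 1e-12)
  expect_equal(res$n, 50L)
  # symmetry in (x, y) and invariance under positive affine transforms
  swapped <- data.frame(mag_id = prof$mag_id, coding_density = y,
                        gh_family_count = x)
  expect_equal(densityDiversityCorrelation(swapped)$r_squared, res$r_squared)
  scaled <- transform(prof, coding_density = 10 * coding_density + 2)
  expect_equal(densityDiversityCorrelation(scaled)$r_squared, res$r_squared)
  # degenerate input
  const <- transform(prof, coding_density = 1)
  expect_error(densityDiversityCorrelation(const), "degenerate")
  expect_error(densityDiversityCorrelation(prof[1:2, ]), "at least 3")
})

test_that("order x site aggregation averages correctly and matches a partition oracle", {
  mags <- tinyMags()
  prof <- data.frame(mag_id = mags$mag_id,
                     gh_gene_count = c(4, 8, 2, 10),
                     gh_family_count = c(3, 6, 2, 7),
                     coding_density = c(2, 4, 1, 5))
  # two MAGs forced into one (site, order) group
  mags$site[2] <- "mendota_epi"; mags$order[2] <- "Burkholderiales"
  agg <- aggregateByOrder(prof, mags)
  g <- agg[agg$site == "mendota_epi" & agg$order == "Burkholderiales", ]
  expect_equal(g$mean_density, 3)       # mean of 2 and 4
  expect_equal(g$n_mags, 2L)
  # singleton group mean equals its value
  s <- agg[agg$order == "Bacteroidales", ]
  expect_equal(s$mean_density, 5)
  # NA order falls back to Unclassified-<effective phylum>
  mags2 <- tinyMags()
  agg2 <- aggregateByOrder(prof, mags2)
  expect_true("Unclassified-Verrucomicrobia" %in% agg2$order)
  # brute-force partition oracle
  key <- paste(mags$site, mags$order)
  for (kk in unique(key)) {
    rows <- prof[key == kk, ]
    got <- agg[paste(agg$site, agg$order) == paste(
      mags$site[key == kk][1],
      mags$order[key == kk][1]), ]
    expect_equal(got$mean_density, mean(rows$coding_density))
    expect_equal(got$mean_family_count, mean(rows$gh_family_count))
  }
})

test_that("synthetic CAZyme tables couple coding density and family diversity", {
  cfg <- simConfig(seed = 9)
  sim <- simulateMags(cfg)
  caz <- simulateCazymeAnnotations(cfg, sim$mags)
  prof <- ghProfile(caz, sim$mags)
  expect_equal(nrow(prof), nrow(sim$mags))
  expect_true(all(prof$gh_family_count <= pmax(prof$gh_gene_count, 0)))
  res <- densityDiversityCorrelation(prof)
  expect_gt(res$r_squared, 0.5)     # strong positive coupling by design
  expect_lt(res$p_value, 1e-6)
  # determinism
  caz2 <- simulateCazymeAnnotations(cfg, sim$mags)
  expect_identical(caz, caz2)
})
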