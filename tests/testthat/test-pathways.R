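test_that("step coverage is set intersection over annotation synonyms", {
  step <- list(step_id = "nifH",
               annotation_ids = c("KO:K02586", "TIGR:TIGR1287"),
               unique = TRUE)
  expect_true(stepCovered(step, c("TIGR:TIGR1287", "COG:COG0001")))
  expect_false(stepCovered(step, c("KO:K99999")))

  set.seed(31)
  universe <- c(sprintf("KO:K%05d", 1:6), sprintf("PFAM:PF%05d", 1:6))
  for (i in 1:1000) {
    syn <- sample(universe, sample(1:4, 1))
    ann <- sample(universe, sample(0:6, 1))
    expect_identical(stepCovered(list(annotation_ids = syn), ann),
                     length(intersect(syn, ann)) > 0L)
  }
})

test_that("pathway scoring applies the half-completeness rule and unique-step veto", {
  pw <- PathwayDefinition("p", list(
    list(step_id = "s1", annotation_ids = "KO:K1", unique = FALSE),
    list(step_id = "s2", annotation_ids = "KO:K2", unique = FALSE),
    list(step_id = "s3", annotation_ids = "KO:K3", unique = FALSE),
    list(step_id = "s4", annotation_ids = "KO:K4", unique = FALSE)))
  sc <- scorePathway(pw, c("KO:K1", "KO:K2"))
  expect_equal(sc$completeness_fraction, 0.5)
  expect_true(sc$present)  # half coverage is enough without unique steps

  pwu <- PathwayDefinition("p", list(
    list(step_id = "s1", annotation_ids = "KO:K1", unique = TRUE),
    list(step_id = "s2", annotation_ids = "KO:K2", unique = FALSE),
    list(step_id = "s3", annotation_ids = "KO:K3", unique = FALSE),
    list(step_id = "s4", annotation_ids = "KO:K4", unique = FALSE)))
  sc <- scorePathway(pwu, c("KO:K2", "KO:K3", "KO:K4"))
  expect_equal(sc$completeness_fraction, 0.75)
  expect_false(sc$present)  # uncovered unique step vetoes the call

  sc <- scorePathway(pw, character())
  expect_equal(sc$completeness_fraction, 0)
  expect_false(sc$present)
})

test_that("presence calls on dropout-free synthetic data equal the planted truth", {
  cfg <- simConfig(seed = 7, completenessRange = c(1, 1),
                   contaminationRate = 0,
                   nMagsPerSite = c(mendota_epi = 20L, troutbog_epi = 10L,
                                    troutbog_hypo = 10L))
  sim <- simulateMags(cfg)
  pm <- callAll(sim$annotations, demoPathwayCatalog(),
                magIds = sim$mags$mag_id)
  calls <- pathwayPresence(pm)[cbind(sim$truth$mag_id,
                                     sim$truth$pathway_id)]
  expect_identical(unname(calls), sim$truth$planted)
})

test_that("enlarging an annotation set never lowers completeness or revokes presence", {
  set.seed(41)
  universe <- c(sprintf("KO:K%d", 1:8), sprintf("COG:COG%d", 1:4))
  catalog <- randomSmallCatalog(universe)
  for (i in 1:50) {
    ann <- sample(universe, sample(0:8, 1))
    extra <- c(ann, sample(universe, 1))
    for (p in catalog) {
      a <- scorePathway(p, ann)
      b <- scorePathway(p, extra)
      expect_gte(b$completeness_fraction, a$completeness_fraction)
      if (a$present) expect_true(b$present)
    }
  }
})

test_that("callAll handles empty catalogs and unannotated MAGs", {
  ann <- data.frame(mag_id = "m1", gene_id = "g1",
                    annotation_id = "KO:K02588")
  pm <- callAll(ann, list())
  expect_equal(dim(pathwayPresence(pm)), c(1L, 0L))

  pm2 <- callAll(ann, demoPathwayCatalog(), magIds = c("m1", "m2"))
  expect_true(all(pathwayCompleteness(pm2)["m2", ] == 0))
  expect_false(any(pathwayPresence(pm2)["m2", ]))
})

test_that("aggregation by site and effective phylum reports all groups with fractions", {
  mags <- tinyMags()
  cf <- matrix(c(1, 1, 0, 0.25,
                 0.6, 0, 0.75, 0), 4, 2,
               dimnames = list(mags$mag_id, c("pwA", "pwB")))
  uok <- matrix(TRUE, 4, 2, dimnames = dimnames(cf))
  pm <- new("PresenceMatrix", completeness = cf, uniqueOk = uok,
            presence = (cf >= 0.5) & uok)
  agg <- aggregatePresence(pm, mags)
  # m1 (Betaproteobacteria) and m2 (Verrucomicrobia) are separate groups
  beta <- agg[agg$effective_phylum == "Betaproteobacteria" &
                agg$pathway_id == "pwA", ]
  expect_equal(beta$n_mags, 1L)
  expect_equal(beta$fraction, 1)
  # zero-presence groups are still reported
  verruB <- agg[agg$effective_phylum == "Verrucomicrobia" &
                  agg$pathway_id == "pwB", ]
  expect_equal(verruB$n_present, 0L)
  expect_equal(verruB$fraction, 0)
  # unknown MAG errors by name
  expect_error(aggregatePresence(pm, mags[-1, ]), "m1")

  grp <- data.frame(mag_id = c("x", "y", "z"), site = "mendota_epi",
                    phylum = "Chlorobi", class = NA)
  cf3 <- matrix(c(1, 1, 0), 3, 1, dimnames = list(grp$mag_id, "pw"))
  u3 <- matrix(TRUE, 3, 1, dimnames = dimnames(cf3))
  pm3 <- new("PresenceMatrix", completeness = cf3, uniqueOk = u3,
             presence = (cf3 >= 0.5) & u3)
  expect_equal(aggregatePresence(pm3, grp)$fraction, 2 / 3)
})

test_that("aggregated presence fractions recover the planted per-phylum probability", {
  ## one pathway planted at probability 0.8 in every phylum, no dropout
  taxa <- data.frame(phylum = c("Chlorobi", "Bacteroidetes"),
                     class = NA_character_, weight = c(1, 1))
  pp <- data.frame(phylum = rep(taxa$phylum, each = 1),
                   pathway_id = "xylose_degradation", prob = 0.8)
  cfg <- simConfig(seed = 17, taxa = taxa, pathwayPresenceProb = pp,
                   completenessRange = c(1, 1), contaminationRate = 0,
                   nMagsPerSite = c(mendota_epi = 100L, troutbog_epi = 50L,
                                    troutbog_hypo = 50L))
  sim <- simulateMags(cfg)
  pm <- callAll(sim$annotations, demoPathwayCatalog(),
                magIds = sim$mags$mag_id)
  agg <- aggregatePresence(pm, sim$mags)
  xa <- agg[agg$pathway_id == "xylose_degradation", ]
  fracAll <- sum(xa$n_present) / sum(xa$n_mags)
  ci <- qbinom(c(0.005, 0.995), 200, 0.8) / 200
  expect_gte(fracAll, ci[1])
  expect_lte(fracAll, ci[2])
})
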