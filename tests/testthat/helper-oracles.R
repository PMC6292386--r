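## Independent oracles used across tests. These deliberately re-derive
## results by brute force (enumeration, per-character tallies, explicit
## loops) and never call the package functions they check.

## Exact two-sided rank-sum p-value by enumeration of all C(n+m, n)
## assignments of the pooled ranks to the first group. Assumes no ties.
enumRankSumP <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # Mann-Whitney U for x
  splits <- utils::combn(n + m, n)
  wAll <- apply(splits, 2L, function(ix) sum(seq_len(n + m)[ix]) -
                  n * (n + 1) / 2)
  pl <- mean(wAll <= wObs)
  pg <- mean(wAll >= wObs)
  min(1, 2 * min(pl, pg))
}

## Brute-force pathway scorer: explicit loops over steps and synonyms.
bruteScorePathway <- function(steps, annotations) {
  covered <- 0L
  uniqueOk <- TRUE
  for (s in steps) {
    hit <- FALSE
    for (a in s$annotation_ids) {
      for (b in annotations) if (identical(a, b)) hit <- TRUE
    }
    if (hit) covered <- covered + 1L
    if (isTRUE(s$unique) && !hit) uniqueOk <- FALSE
  }
  frac <- covered / length(steps)
  list(completeness_fraction = frac, unique_steps_satisfied = uniqueOk,
       present = frac >= 0.5 && uniqueOk)
}

## Analytic probability that a planted pathway is still called present when
## each gene survives independently with probability `c` (one gene per step):
## all unique steps must survive, and total surviving steps must reach half.
analyticRecall <- function(steps, c) {
  k <- length(steps)
  u <- sum(vapply(steps, function(s) isTRUE(s$unique), TRUE))
  need <- ceiling(k / 2) - u  # further non-unique steps required
  pB <- if (need <= 0) 1 else
    stats::pbinom(need - 1L, size = k - u, prob = c, lower.tail = FALSE)
  c^u * pB
}

## Random small pathway catalog over a compact annotation-id universe, so
## that all 2^|universe| annotation subsets can be enumerated.
randomSmallCatalog <- function(universe, nPathways = 5L, maxSteps = 6L) {
  defs <- lapply(seq_len(nPathways), function(i) {
    k <- sample(1:maxSteps, 1L)
    steps <- lapply(seq_len(k), function(j) {
      list(step_id = sprintf("s%d", j),
           annotation_ids = sample(universe, sample(1:2, 1L)),
           unique = stats::runif(1) < 0.3)
    })
    PathwayDefinition(sprintf("pw%d", i), steps)
  })
  names(defs) <- vapply(defs, function(p) p@pathwayId, "")
  defs
}

## A small hand-made MAG metadata table.
tinyMags <- function() {
  data.frame(
    mag_id = c("m1", "m2", "m3", "m4"),
    site = c("mendota_epi", "mendota_epi", "troutbog_epi", "troutbog_hypo"),
    phylum = c("Proteobacteria", "Verrucomicrobia", "Proteobacteria",
               "Bacteroidetes"),
    class = c("Betaproteobacteria", NA, NA, "Bacteroidia"),
    order = c("Burkholderiales", NA, "Rhodospirillales", "Bacteroidales"),
    family = NA_character_, genus = NA_character_, species = NA_character_,
    completeness = c(90, 75, 60, 55), contamination = c(2, 5, 9, 1),
    genome_length = c(3e6, 4e6, 2.5e6, 5e6),
    gene_count = c(3000, 4000, 2500, 5000),
    stringsAsFactors = FALSE)
}
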