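## Synthetic-data generators with planted ground truth. The defaults emulate
## the study design the package targets: 193 MAGs split 99/31/63 across the
## three lake sites with completeness 50-99%; 94 + 47 + 47 metagenomes;
## negative-binomial marker hit counts with multiplicative site effects;
## Gaussian seasonal blooms for MAG coverage with nitrogenase counts coupled
## to diazotroph coverage. Every generator is deterministic given the
## config seed.

#' SimConfig: parameters of the synthetic lake-metagenome generator
#'
#' See [simConfig()] for slot semantics and defaults.
#'
#' @slot seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @slot nMagsPerSite named integer vector, MAGs per site.
#' @slot taxa data.frame (`phylum`, `class`, `weight`) of taxon draw weights.
#' @slot pathwayPresenceProb data.frame (`phylum`, `pathway_id`, `prob`) of
#'   planted presence probabilities; unlisted pairs have probability 0.
#' @slot completenessRange numeric length-2 interval within \[0.5, 1\].
#' @slot contaminationRate probability a slot of 100 candidate foreign genes
#'   enters a MAG as contamination.
#' @slot markerSiteEffect data.frame (`function_category`, `site`, `effect`)
#'   of multiplicative site effects; unlisted pairs have effect 1.
#' @slot baseRate expected marker hits per read per category at effect 1.
#' @slot nbDispersion negative-binomial size parameter of hit counts.
#' @slot decoyFraction fraction of sub-threshold decoy hits added.
#' @slot nSamplesPerYear samples per year in the time series.
#' @slot bloomWidthDays Gaussian bloom standard deviation, days.
#' @slot years integer vector of simulated years.
#' @slot readCount merged reads per time-series metagenome.
#' @slot copyFactor expected nitrogenase hits per million reads per unit of
#'   diazotroph coverage.
#' @slot diazotrophYears years whose dominant bloom MAG is a diazotroph.
#' @export
setClass("SimConfig",
  representation(seed = "integer", nMagsPerSite = "integer",
                 taxa = "data.frame", pathwayPresenceProb = "data.frame",
                 completenessRange = "numeric", contaminationRate = "numeric",
                 markerSiteEffect = "data.frame", baseRate = "numeric",
                 nbDispersion = "numeric", decoyFraction = "numeric",
                 nSamplesPerYear = "integer", bloomWidthDays = "numeric",
                 years = "integer", readCount = "numeric",
                 copyFactor = "numeric", diazotrophYears = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (is.null(names(object@nMagsPerSite)) ||
      !all(names(object@nMagsPerSite) %in% .SITES))
    msgs <- c(msgs, "nMagsPerSite must be named by site")
  if (nrow(object@taxa) == 0L)
    msgs <- c(msgs, "taxa list must be non-empty")
  else if (any(object@taxa$weight <= 0))
    msgs <- c(msgs, "taxon weights must be positive")
  pp <- object@pathwayPresenceProb
  if (nrow(pp) && (any(pp$prob < 0) || any(pp$prob > 1)))
    msgs <- c(msgs, "presence probabilities must lie in [0, 1]")
  cr <- object@completenessRange
  if (length(cr) != 2L || cr[1L] > cr[2L] || cr[1L] < 0.5 || cr[2L] > 1)
    msgs <- c(msgs, "completenessRange must be an interval within [0.5, 1]")
  if (object@contaminationRate < 0 || object@contaminationRate > 1)
    msgs <- c(msgs, "contaminationRate must be a probability")
  se <- object@markerSiteEffect
  if (nrow(se) && any(se$effect <= 0))
    msgs <- c(msgs, "site effects must be positive")
  if (object@baseRate <= 0) msgs <- c(msgs, "baseRate must be positive")
  if (object@nbDispersion <= 0)
    msgs <- c(msgs, "nbDispersion must be positive")
  if (object@decoyFraction < 0 || object@decoyFraction > 1)
    msgs <- c(msgs, "decoyFraction must be a probability")
  if (object@nSamplesPerYear < 2L)
    msgs <- c(msgs, "need at least 2 samples per year")
  if (object@bloomWidthDays <= 0)
    msgs <- c(msgs, "bloomWidthDays must be positive")
  if (object@readCount <= 0) msgs <- c(msgs, "readCount must be positive")
  if (object@copyFactor <= 0) msgs <- c(msgs, "copyFactor must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: seed %d; %s MAG(s); %d taxa; completeness ",
                     "[%.2f, %.2f]; contamination %.3f\n"),
              object@seed, paste(object@nMagsPerSite, collapse = "+"),
              nrow(object@taxa), object@completenessRange[1L],
              object@completenessRange[2L], object@contaminationRate))
})

## Freshwater-typical taxon mix; Proteobacteria carried at class rank.
.defaultTaxa <- function() {
  data.frame(
    phylum = c("Actinobacteria", "Bacteroidetes", "Verrucomicrobia",
               "Cyanobacteria", "Chlorobi", "Acidobacteria",
               "Planctomycetes", rep("Proteobacteria", 5L)),
    class = c(rep(NA_character_, 7L), "Alphaproteobacteria",
              "Betaproteobacteria", "Gammaproteobacteria",
              "Deltaproteobacteria", "Epsilonproteobacteria"),
    weight = c(0.20, 0.15, 0.10, 0.08, 0.05, 0.05, 0.05,
               0.08, 0.12, 0.06, 0.04, 0.02),
    stringsAsFactors = FALSE)
}

## Planted presence probabilities for the shipped demonstration catalog,
## motivated by the qualitative pattern of the target system: nitrogen
## fixation in Cyanobacteria, Chlorobi and some Proteobacteria; polyamine
## pathways nearly universal; assimilatory sulfate reduction common,
## dissimilatory rare; CBB carbon fixation in Cyanobacteria.
.defaultPresenceProbs <- function(taxa = .defaultTaxa()) {
  phyla <- unique(taxa$phylum)
  all <- function(p) data.frame(phylum = phyla, pathway_id = p,
                                prob = NA_real_, stringsAsFactors = FALSE)
  rbind(
    data.frame(phylum = c("Cyanobacteria", "Chlorobi", "Proteobacteria",
                          "Acidobacteria", "Verrucomicrobia"),
               pathway_id = "nitrogen_fixation",
               prob = c(0.65, 0.5, 0.2, 0.2, 0.15)),
    transform(all("polyamine_synthesis"), prob = 0.94),
    transform(all("polyamine_degradation"), prob = 0.87),
    transform(all("assimilatory_sulfate_reduction"), prob = 0.7),
    data.frame(phylum = c("Chlorobi", "Proteobacteria"),
               pathway_id = "dissimilatory_sulfate_reduction",
               prob = c(0.6, 0.1)),
    data.frame(phylum = c("Cyanobacteria", "Proteobacteria"),
               pathway_id = "cbb_carbon_fixation", prob = c(0.9, 0.15)),
    data.frame(phylum = c("Chlorobi", "Proteobacteria",
                          "Epsilonproteobacteria"),
               pathway_id = "sox_thiosulfate_oxidation",
               prob = c(0.5, 0.25, 0.4)),
    data.frame(phylum = c("Bacteroidetes", "Verrucomicrobia",
                          "Planctomycetes", "Actinobacteria"),
               pathway_id = "xylose_degradation",
               prob = c(0.5, 0.5, 0.4, 0.35)))
}

#' Build a synthetic-data configuration
#'
#' Defaults reproduce the study conditions the generators emulate: 99/31/63
#' MAGs across the three sites with completeness drawn uniformly on
#' 50-99%, a low contamination rate, a freshwater-typical taxon mix,
#' presence probabilities for the demonstration pathway catalog,
#' negative-binomial marker counts, and five years of 19 samples each
#' (94 metagenomes) for the bloom time series with the dominant MAG
#' diazotrophic in 2008, 2011 and 2012.
#'
#' @param seed integer RNG seed.
#' @param nMagsPerSite named integer vector of MAG counts per site.
#' @param taxa data.frame (`phylum`, `class`, `weight`).
#' @param pathwayPresenceProb data.frame (`phylum`, `pathway_id`, `prob`).
#' @param completenessRange length-2 numeric within \[0.5, 1\].
#' @param contaminationRate probability of foreign-gene contamination.
#' @param markerSiteEffect data.frame (`function_category`, `site`,
#'   `effect`); omitted pairs have effect 1.
#' @param baseRate expected hits per read per category at effect 1.
#' @param nbDispersion negative-binomial size of hit counts.
#' @param decoyFraction fraction of sub-threshold (10-30% identity) decoys.
#' @param nSamplesPerYear time-series samples per year.
#' @param bloomWidthDays bloom standard deviation in days.
#' @param years years simulated in the time series.
#' @param readCount merged reads per time-series metagenome.
#' @param copyFactor nitrogenase hits per million reads per unit coverage.
#' @param diazotrophYears years whose dominant MAG fixes nitrogen.
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
simConfig <- function(seed = 1L,
                      nMagsPerSite = c(mendota_epi = 99L, troutbog_epi = 31L,
                                       troutbog_hypo = 63L),
                      taxa = .defaultTaxa(),
                      pathwayPresenceProb = .defaultPresenceProbs(taxa),
                      completenessRange = c(0.5, 0.99),
                      contaminationRate = 0.02,
                      markerSiteEffect = data.frame(
                        function_category = character(), site = character(),
                        effect = numeric(), stringsAsFactors = FALSE),
                      baseRate = 5e-6,
                      nbDispersion = 5,
                      decoyFraction = 0.1,
                      nSamplesPerYear = 19L,
                      bloomWidthDays = 30,
                      years = 2008:2012,
                      readCount = 1e7,
                      copyFactor = 5,
                      diazotrophYears = c(2008L, 2011L, 2012L)) {
  new("SimConfig", seed = as.integer(seed),
      nMagsPerSite = stats::setNames(as.integer(nMagsPerSite),
                                     names(nMagsPerSite)),
      taxa = taxa, pathwayPresenceProb = pathwayPresenceProb,
      completenessRange = as.numeric(completenessRange),
      contaminationRate = as.numeric(contaminationRate),
      markerSiteEffect = markerSiteEffect, baseRate = as.numeric(baseRate),
      nbDispersion = as.numeric(nbDispersion),
      decoyFraction = as.numeric(decoyFraction),
      nSamplesPerYear = as.integer(nSamplesPerYear),
      bloomWidthDays = as.numeric(bloomWidthDays),
      years = as.integer(years), readCount = as.numeric(readCount),
      copyFactor = as.numeric(copyFactor),
      diazotrophYears = as.integer(diazotrophYears))
}

.siteEffect <- function(config, category, site) {
  se <- config@markerSiteEffect
  hit <- se$effect[se$function_category == category & se$site == site]
  if (length(hit)) hit[1L] else 1
}

.presenceProb <- function(config, phylum, pathwayId) {
  pp <- config@pathwayPresenceProb
  hit <- pp$prob[pp$phylum == phylum & pp$pathway_id == pathwayId]
  if (length(hit)) hit[1L] else 0
}

#' Simulate MAG metadata and annotation tables with planted pathways
#'
#' Each MAG draws a taxon by weight, a completeness from the configured
#' range, and for every catalog pathway a planted presence Bernoulli draw
#' keyed by (phylum, pathway). Planted pathways contribute one gene per step
#' (annotation id sampled among the step's synonyms); every gene is then
#' independently dropped with probability 1 - completeness, the mechanism by
#' which genome incompleteness erodes pathway calls. Contamination adds
#' foreign annotations drawn from catalog ids outside the MAG's planted set,
#' `Binomial(100, contaminationRate)` genes per MAG.
#'
#' @param config a [SimConfig-class].
#' @param catalog named list of [PathwayDefinition-class]s (defaults to the
#'   shipped demonstration catalog).
#' @return A list with `mags` (MAG metadata data.frame), `annotations`
#'   (annotation table) and `truth` (data.frame `mag_id`, `pathway_id`,
#'   `planted`).
#' @export
#' @examples
#' sim <- simulateMags(simConfig(seed = 7,
#'   nMagsPerSite = c(mendota_epi = 5L, troutbog_epi = 3L,
#'                    troutbog_hypo = 2L)))
#' head(sim$truth)
simulateMags <- function(config, catalog = demoPathwayCatalog()) {
  stopifnot(is(config, "SimConfig"))
  if (nrow(config@taxa) == 0L) stop("empty taxa list", call. = FALSE)
  set.seed(config@seed)
  allIds <- unique(unlist(lapply(catalog, function(p)
    lapply(p@steps, function(s) s$annotation_ids))))
  magRows <- list(); annRows <- list(); truthRows <- list()
  for (site in names(config@nMagsPerSite)) {
    .assertSites(site, "simulateMags")
    for (i in seq_len(config@nMagsPerSite[[site]])) {
      magId <- sprintf("%s_MAG_%03d", site, i)
      taxon <- config@taxa[sample.int(nrow(config@taxa), 1L,
                                      prob = config@taxa$weight), ]
      compl <- stats::runif(1L, config@completenessRange[1L],
                            config@completenessRange[2L])
      genomeLength <- round(stats::runif(1L, 2e6, 6e6))
      geneCount <- round(genomeLength / 1000)
      genes <- character(); anns <- character()
      planted <- logical(length(catalog))
      names(planted) <- names(catalog)
      for (p in names(catalog)) {
        prob <- .presenceProb(config, taxon$phylum, p)
        planted[[p]] <- stats::runif(1L) < prob
        if (planted[[p]]) {
          for (s in catalog[[p]]@steps) {
            genes <- c(genes, sprintf("g%05d", length(genes) + 1L))
            anns <- c(anns, if (length(s$annotation_ids) == 1L)
              s$annotation_ids else sample(s$annotation_ids, 1L))
          }
        }
      }
      keep <- stats::runif(length(genes)) < compl
      genes <- genes[keep]; anns <- anns[keep]
      nContam <- stats::rbinom(1L, 100L, config@contaminationRate)
      if (nContam > 0L) {
        foreign <- setdiff(allIds, anns)
        nContam <- min(nContam, length(foreign))
        if (nContam > 0L) {
          cg <- sprintf("c%05d", seq_len(nContam))
          genes <- c(genes, cg)
          anns <- c(anns, sample(foreign, nContam))
        }
      }
      magRows[[magId]] <- data.frame(
        mag_id = magId, site = site, phylum = taxon$phylum,
        class = taxon$class, order = NA_character_, family = NA_character_,
        genus = NA_character_, species = NA_character_,
        completeness = 100 * compl,
        contamination = 100 * config@contaminationRate,
        genome_length = genomeLength, gene_count = geneCount,
        stringsAsFactors = FALSE)
      if (length(genes))
        annRows[[magId]] <- data.frame(
          mag_id = magId, gene_id = paste0(magId, "_", genes),
          annotation_id = anns, stringsAsFactors = FALSE)
      truthRows[[magId]] <- data.frame(
        mag_id = magId, pathway_id = names(planted),
        planted = unname(planted), stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(annRows)) do.call(rbind, annRows) else
    data.frame(mag_id = character(), gene_id = character(),
               annotation_id = character(), stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  mags <- do.call(rbind, magRows); rownames(mags) <- NULL
  truth <- do.call(rbind, truthRows); rownames(truth) <- NULL
  list(mags = mags, annotations = ann, truth = truth)
}

#' Simulate marker gene hit tables for a set of metagenomes
#'
#' Per (metagenome, function category), a hit count is drawn
#' negative-binomially with mean `baseRate * read_count * effect(category,
#' site)` and size `nbDispersion`. Each hit is assigned a random marker of
#' the category, a percent identity uniform on \[30, 100\] and a unique
#' query ORF; a `decoyFraction` of additional sub-threshold hits (identity
#' on \[10, 30)) exercises the identity cutoff downstream.
#'
#' @param config a [SimConfig-class].
#' @param catalog marker catalog data.frame (`marker_id`,
#'   `function_category`).
#' @param metagenomes data.frame with columns `metagenome_id`, `site`,
#'   `read_count`.
#' @return data.frame of hit records (`metagenome_id`, `query_id`,
#'   `subject_id`, `percent_identity`, `bitscore`) with attribute `truth`, a
#'   data.frame of planted above-threshold counts per (metagenome,
#'   category).
#' @export
simulateMarkerHits <- function(config, catalog, metagenomes) {
  stopifnot(is(config, "SimConfig"))
  .assertCols(catalog, c("marker_id", "function_category"), "marker catalog")
  .assertCols(metagenomes, c("metagenome_id", "site", "read_count"),
              "metagenome list")
  .assertSites(metagenomes$site, "simulateMarkerHits")
  if (any(metagenomes$read_count <= 0))
    stop("read_count must be positive", call. = FALSE)
  set.seed(config@seed)
  cats <- sort(unique(catalog$function_category))
  markersByCat <- split(catalog$marker_id, catalog$function_category)
  ## One grid row per (metagenome, category); counts drawn vectorized.
  grid <- expand.grid(ci = seq_along(cats),
                      mi = seq_len(nrow(metagenomes)),
                      KEEP.OUT.ATTRS = FALSE)
  rc <- metagenomes$read_count[grid$mi]
  eff <- mapply(function(ci, mi) .siteEffect(config, cats[ci],
                                             metagenomes$site[mi]),
                grid$ci, grid$mi)
  mu <- config@baseRate * rc * eff
  n <- stats::rnbinom(nrow(grid), size = config@nbDispersion, mu = mu)
  nDecoy <- round(config@decoyFraction * n)
  nTot <- n + nDecoy
  idx <- rep.int(seq_len(nrow(grid)), nTot)
  mg <- metagenomes$metagenome_id[grid$mi][idx]
  subj <- unlist(lapply(seq_len(nrow(grid)), function(k) {
    if (nTot[k] == 0L) return(character())
    sample(markersByCat[[cats[grid$ci[k]]]], nTot[k], replace = TRUE)
  }), use.names = FALSE)
  pid <- unlist(lapply(seq_len(nrow(grid)), function(k) {
    c(stats::runif(n[k], 30, 100), stats::runif(nDecoy[k], 10, 30))
  }), use.names = FALSE)
  orf <- stats::ave(seq_along(idx), mg, FUN = seq_along)
  hits <- data.frame(
    metagenome_id = as.character(mg %||% character()),
    query_id = if (length(idx)) sprintf("%s_orf%06d", mg, orf) else character(),
    subject_id = as.character(subj %||% character()),
    percent_identity = as.numeric(pid %||% numeric()),
    bitscore = round(stats::runif(length(idx), 40, 300), 1),
    stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  attr(hits, "truth") <- data.frame(
    metagenome_id = metagenomes$metagenome_id[grid$mi],
    function_category = cats[grid$ci], true_hits = n,
    stringsAsFactors = FALSE)
  hits
}

#' Simulate a seasonal MAG coverage and nitrogenase time series
#'
#' One Cyanobacteria MAG per configured year follows a Gaussian bloom
#' (random peak date, width `bloomWidthDays`, amplitude 10) in its year and
#' a flat low baseline (0.05) elsewhere. Nitrogenase hit counts per sample
#' are coupled only to diazotroph coverage: mean `copyFactor * total
#' diazotroph coverage * read_count / 1e6` with negative-binomial noise
#' (`noise = FALSE` rounds the mean instead), split across the three Mo-Fe
#' nitrogenase subunit markers. The dominant MAGs of `diazotrophYears` are
#' the diazotrophs.
#'
#' @param config a [SimConfig-class].
#' @param noise draw negative-binomial counts (`TRUE`) or use the rounded
#'   expectation (`FALSE`).
#' @return A list with `mags`, `coverage` (raw `mapped_bases` table),
#'   `metas`, `hits`, and `truth` (list: `dominant` data.frame per year with
#'   the planted dominant MAG and its diazotroph flag, `diazotrophs`,
#'   `expected` data.frame of exact expected hits-per-million per sample).
#' @export
simulateTimeseries <- function(config, noise = TRUE) {
  stopifnot(is(config, "SimConfig"))
  if (config@nSamplesPerYear < 2L)
    stop("need at least 2 samples per year", call. = FALSE)
  set.seed(config@seed)
  years <- config@years
  nifMarkers <- c("TIGR1282", "TIGR1286", "TIGR1287")
  magIds <- sprintf("CYANO_%d", years)
  diaz <- years %in% config@diazotrophYears
  names(diaz) <- magIds
  mags <- data.frame(
    mag_id = magIds, site = "mendota_epi", phylum = "Cyanobacteria",
    class = NA_character_, order = "Nostocales", family = NA_character_,
    genus = NA_character_, species = NA_character_,
    completeness = round(stats::runif(length(magIds), 70, 99), 1),
    contamination = round(stats::runif(length(magIds), 0, 5), 1),
    genome_length = round(stats::runif(length(magIds), 2.5e6, 5e6)),
    gene_count = NA_real_, stringsAsFactors = FALSE)
  mags$gene_count <- round(mags$genome_length / 1000)
  peak <- round(stats::runif(length(years), 170, 260))  # day of year
  days <- round(seq(135, 290, length.out = config@nSamplesPerYear))
  metas <- do.call(rbind, lapply(seq_along(years), function(yi) {
    data.frame(
      metagenome_id = sprintf("ME_%d_%02d", years[yi],
                              seq_len(config@nSamplesPerYear)),
      site = "mendota_epi",
      sample_date = as.Date(sprintf("%d-01-01", years[yi])) + days - 1L,
      read_count = config@readCount, stringsAsFactors = FALSE)
  }))
  baseline <- 0.05; amplitude <- 10
  covRows <- list(); hitRows <- list(); expRows <- list()
  for (si in seq_len(nrow(metas))) {
    d <- metas$sample_date[si]
    yi <- match(.yearOf(d), years)
    doy <- as.integer(format(d, "%j"))
    cov <- vapply(seq_along(magIds), function(mi) {
      if (mi == yi)
        baseline + amplitude *
          exp(-(doy - peak[yi])^2 / (2 * config@bloomWidthDays^2))
      else baseline
    }, 0)
    gbases <- metas$read_count[si] * 150 / 1e9
    covRows[[si]] <- data.frame(
      mag_id = magIds, metagenome_id = metas$metagenome_id[si],
      mapped_bases = cov * mags$genome_length * gbases,
      stringsAsFactors = FALSE)
    diazCov <- sum(cov[diaz])
    mu <- config@copyFactor * diazCov * metas$read_count[si] / 1e6
    n <- if (noise)
      stats::rnbinom(1L, size = config@nbDispersion, mu = mu)
    else round(mu)
    if (n > 0L)
      hitRows[[length(hitRows) + 1L]] <- data.frame(
        metagenome_id = metas$metagenome_id[si],
        query_id = sprintf("%s_orf%06d", metas$metagenome_id[si],
                           seq_len(n)),
        subject_id = sample(nifMarkers, n, replace = TRUE),
        percent_identity = stats::runif(n, 30, 100),
        bitscore = round(stats::runif(n, 40, 300), 1),
        stringsAsFactors = FALSE)
    expRows[[si]] <- data.frame(
      metagenome_id = metas$metagenome_id[si], sample_date = d,
      expected_hits_per_million = config@copyFactor * diazCov,
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hitRows)) do.call(rbind, hitRows) else
    data.frame(metagenome_id = character(), query_id = character(),
               subject_id = character(), percent_identity = numeric(),
               bitscore = numeric(), stringsAsFactors = FALSE)
  coverage <- do.call(rbind, covRows)
  rownames(coverage) <- rownames(hits) <- NULL
  truth <- list(
    dominant = data.frame(year = years, mag_id = magIds,
                          diazotroph = unname(diaz),
                          stringsAsFactors = FALSE),
    diazotrophs = magIds[diaz],
    expected = do.call(rbind, expRows))
  list(mags = mags, coverage = coverage, metas = metas, hits = hits,
       truth = truth)
}

#' Simulate CAZyme annotations with coupled density and diversity
#'
#' Per MAG, a lognormal carbohydrate-degradation propensity sets the size of
#' its GH family repertoire (Poisson around 8 x propensity, drawn from a
#' 130-family pool); each family in the repertoire then carries one or more
#' gene copies (1 plus negative-binomial). Genomes gain GH breadth mainly by
#' acquiring new families rather than by duplication, so coding density and
#' family diversity are strongly, positively coupled by construction. A
#' small number of non-GH CAZyme rows (GT/CE/CBM/PL families) is added to
#' exercise class filtering.
#'
#' @param config a [SimConfig-class] (seed, dispersion).
#' @param mags data.frame of MAG records with `gene_count`.
#' @return data.frame with columns `mag_id`, `gene_id`, `cazyme_family`.
#' @export
simulateCazymeAnnotations <- function(config, mags) {
  stopifnot(is(config, "SimConfig"))
  .assertCols(mags, c("mag_id", "gene_count"), "MAG table")
  set.seed(config@seed)
  pool <- sprintf("GH%d", 1:130)
  rows <- list()
  for (k in seq_len(nrow(mags))) {
    propensity <- stats::rlnorm(1L, meanlog = 0, sdlog = 1)
    nFam <- min(stats::rpois(1L, propensity * 8), length(pool))
    if (nFam > 0L) {
      fams <- sample(pool, nFam)
      copies <- 1L + stats::rnbinom(nFam, size = config@nbDispersion,
                                    mu = 0.4)
      famPerGene <- rep(fams, copies)
      n <- length(famPerGene)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_id = mags$mag_id[k],
        gene_id = sprintf("%s_gh%04d", mags$mag_id[k], seq_len(n)),
        cazyme_family = famPerGene,
        stringsAsFactors = FALSE)
    }
    nOther <- stats::rpois(1L, 2)
    if (nOther > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_id = mags$mag_id[k],
        gene_id = sprintf("%s_ot%04d", mags$mag_id[k], seq_len(nOther)),
        cazyme_family = sample(c("GT2", "GT4", "CE1", "CBM50", "PL9"),
                               nOther, replace = TRUE),
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mag_id = character(), gene_id = character(),
               cazyme_family = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a full synthetic data set to a directory
#'
#' Materialises every downstream input format (MAG metadata, annotations,
#' marker hits as BLAST tabular, metagenome info, coverage, CAZyme table)
#' plus the planted truth tables under `truth/`, as the `simulate` CLI
#' subcommand does.
#'
#' @param config a [SimConfig-class].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeSimulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  sim <- simulateMags(config)
  .writeTsv(sim$mags, file.path(outdir, "mags.tsv"))
  writeAnnotationTable(sim$annotations, file.path(outdir, "annotations.tsv"))
  .writeTsv(sim$truth, file.path(outdir, "truth", "pathway_presence.tsv"))
  ts <- simulateTimeseries(config)
  .writeTsv(ts$mags, file.path(outdir, "timeseries_mags.tsv"))
  .writeTsv(ts$metas, file.path(outdir, "metagenomes.tsv"))
  .writeTsv(ts$coverage, file.path(outdir, "coverage.tsv"))
  writeBlastTab(ts$hits, file.path(outdir, "nif_hits.tsv"))
  .writeTsv(ts$truth$dominant, file.path(outdir, "truth", "dominant.tsv"))
  caz <- simulateCazymeAnnotations(config, sim$mags)
  .writeTsv(caz, file.path(outdir, "cazymes.tsv"))
  invisible(outdir)
}
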