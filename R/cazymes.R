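## Glycoside hydrolase (GH) metrics from CAZyme annotations: per-MAG coding
## density (% of genes annotated as a GH), family diversity, the
## density-diversity correlation, and order x site aggregation. Non-GH
## CAZyme classes (GT/PL/CE/CBM/AA) are parsed and ignored.

#' Per-MAG glycoside hydrolase profiles
#'
#' Counts, for each MAG, the genes carrying at least one GH annotation and
#' the distinct GH families among them, and derives the GH coding density as
#' a percentage of the MAG's genes. A gene with several GH domains counts
#' once toward the gene count but contributes each of its distinct families.
#' Subfamily labels (e.g. `GH13_10`) are collapsed to the family (`GH13`)
#' unless `collapseSubfamilies = FALSE`.
#'
#' @param cazymeAnnotations data.frame with columns `mag_id`, `gene_id`,
#'   `cazyme_family` (dbCAN-style family strings).
#' @param mags data.frame of MAG records; every annotated MAG must appear and
#'   have `gene_count > 0`. MAGs without GH annotations get a zero profile.
#' @param collapseSubfamilies collapse `GHnn_mm` subfamilies to `GHnn`.
#' @return data.frame with columns `mag_id`, `gh_gene_count`,
#'   `gh_family_count`, `coding_density` (percent).
#' @export
ghProfile <- function(cazymeAnnotations, mags, collapseSubfamilies = TRUE) {
  .assertCols(cazymeAnnotations, c("mag_id", "gene_id", "cazyme_family"),
              "CAZyme annotation table")
  .assertCols(mags, c("mag_id", "gene_count"), "MAG table")
  if (any(is.na(mags$gene_count) | mags$gene_count <= 0))
    stop("every MAG needs gene_count > 0", call. = FALSE)
  miss <- setdiff(unique(cazymeAnnotations$mag_id), mags$mag_id)
  if (length(miss))
    stop(sprintf("annotated MAG(s) absent from the MAG table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  fam <- as.character(cazymeAnnotations$cazyme_family)
  isGH <- grepl("^GH", fam)
  gh <- cazymeAnnotations[isGH, , drop = FALSE]
  ghFam <- fam[isGH]
  if (collapseSubfamilies) ghFam <- sub("_.*$", "", ghFam)
  ids <- as.character(mags$mag_id)
  geneCount <- vapply(ids, function(m) {
    sel <- gh$mag_id == m
    length(unique(gh$gene_id[sel]))
  }, 0L)
  famCount <- vapply(ids, function(m) {
    length(unique(ghFam[gh$mag_id == m]))
  }, 0L)
  data.frame(mag_id = ids, gh_gene_count = unname(geneCount),
             gh_family_count = unname(famCount),
             coding_density = unname(100 * geneCount / mags$gene_count),
             stringsAsFactors = FALSE)
}

#' Correlation between GH coding density and GH family diversity
#'
#' Pearson correlation between per-MAG GH coding density and the number of
#' distinct GH families, with the two-sided p-value from the t transform on
#' n - 2 degrees of freedom. Density is a measure of investment in complex
#' carbon degradation; family diversity proxies the range of substrates.
#'
#' @param profiles data.frame from [ghProfile()], at least 3 rows.
#' @return A list with `r_squared`, `p_value` and `n`.
#' @export
densityDiversityCorrelation <- function(profiles) {
  .assertCols(profiles, c("coding_density", "gh_family_count"), "GH profiles")
  x <- profiles$coding_density
  y <- profiles$gh_family_count
  if (length(x) < 3L)
    stop("need at least 3 profiles", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: density or diversity is constant", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r_squared = unname(ht$estimate)^2, p_value = ht$p.value,
       n = length(x))
}

#' Aggregate GH profiles by site and taxonomic order
#'
#' Arithmetic means of coding density and family count within (site, order)
#' groups. MAGs with a missing order rank are grouped as
#' `"Unclassified-<effective phylum>"` (Proteobacteria split into classes).
#'
#' @param profiles data.frame from [ghProfile()].
#' @param mags data.frame of MAG records with `site` and lineage columns.
#' @return data.frame with columns `site`, `order`, `mean_density`,
#'   `mean_family_count`, `n_mags`.
#' @export
aggregateByOrder <- function(profiles, mags) {
  .assertCols(profiles, c("mag_id", "coding_density", "gh_family_count"),
              "GH profiles")
  .assertCols(mags, c("mag_id", "site", "phylum", "class", "order"),
              "MAG table")
  meta <- mags[match(profiles$mag_id, mags$mag_id), ]
  if (anyNA(meta$mag_id))
    stop("profile MAG(s) absent from the MAG table", call. = FALSE)
  ord <- as.character(meta$order)
  noOrder <- is.na(ord) | !nzchar(ord)
  ord[noOrder] <- paste0("Unclassified-", effectivePhylum(meta)[noOrder])
  key <- paste(meta$site, ord, sep = "\r")
  groups <- split(seq_len(nrow(profiles)), key)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- groups[[g]]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    data.frame(site = parts[1L], order = parts[2L],
               mean_density = mean(profiles$coding_density[rows]),
               mean_family_count = mean(profiles$gh_family_count[rows]),
               n_mags = length(rows), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site, out$order), ]
  rownames(out) <- NULL
  out
}
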