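## MAG catalog handling: quality filtering, ANI-based population grouping,
## the Proteobacteria class split, and the proteome nitrogen metric.

#' Quality-filter MAGs on completeness and contamination
#'
#' Retains MAGs that are at least `minCompleteness` percent complete
#' (inclusive) with contamination strictly below `maxContamination` percent,
#' the medium/high-quality draft genome criterion. Input order is preserved.
#'
#' @param mags data.frame of MAG records (see [readMagTable()]).
#' @param minCompleteness minimum estimated completeness, percent (default 50).
#' @param maxContamination exclusive upper bound on estimated contamination,
#'   percent (default 10).
#' @return The retained subset of `mags`.
#' @export
#' @examples
#' mags <- data.frame(mag_id = c("a", "b"), completeness = c(75, 49.9),
#'                    contamination = c(5, 5))
#' qcFilter(mags)$mag_id
qcFilter <- function(mags, minCompleteness = 50, maxContamination = 10) {
  .assertCols(mags, c("completeness", "contamination"), "MAG table")
  stopifnot(minCompleteness >= 0, minCompleteness <= 100,
            maxContamination >= 0, maxContamination <= 100)
  keep <- mags$completeness >= minCompleteness &
    mags$contamination < maxContamination
  out <- mags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group MAGs into populations by average nucleotide identity
#'
#' Two MAGs with ANI strictly greater than `threshold` percent are flagged as
#' the same population; groups are the connected components of the resulting
#' graph (single-linkage closure, since the pairwise table only flags pairs).
#' Each group's representative is its highest-completeness member, ties
#' broken by lower contamination, then lexicographic `mag_id`. Pairs absent
#' from the ANI table are treated as below threshold.
#'
#' The default threshold is 99 (same population at ANI > 99%); a looser
#' convention of > 97% is also in use and can be selected via `threshold`.
#'
#' @param mags data.frame of MAG records.
#' @param ani data.frame with columns `mag_a`, `mag_b`, `ani` (percent);
#'   lookup is symmetric.
#' @param threshold percent ANI above which two MAGs are the same population.
#' @return data.frame with columns `mag_id`, `population` (the
#'   representative's `mag_id`, shared by all group members) and
#'   `representative` (logical). Every input MAG appears exactly once.
#' @export
flagPopulations <- function(mags, ani, threshold = 99) {
  .assertCols(mags, c("mag_id", "completeness", "contamination"), "MAG table")
  .assertCols(ani, c("mag_a", "mag_b", "ani"), "ANI table")
  stopifnot(threshold >= 0, threshold <= 100)
  if (nrow(ani) && (any(is.na(ani$ani)) || any(ani$ani < 0 | ani$ani > 100)))
    stop("ANI values must lie in [0, 100]", call. = FALSE)
  ids <- sort(unique(as.character(mags$mag_id)))
  edges <- ani[ani$ani > threshold &
                 ani$mag_a %in% ids & ani$mag_b %in% ids &
                 ani$mag_a != ani$mag_b, c("mag_a", "mag_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  ## Representative per component: completeness desc, contamination asc, id.
  meta <- mags[match(names(comp), mags$mag_id), ]
  ord <- order(comp, -meta$completeness, meta$contamination, names(comp))
  first <- !duplicated(comp[ord])
  repId <- names(comp)[ord][first]
  names(repId) <- comp[ord][first]
  out <- data.frame(mag_id = as.character(mags$mag_id),
                    population = unname(repId[as.character(
                      comp[as.character(mags$mag_id)])]),
                    stringsAsFactors = FALSE)
  out$representative <- out$mag_id == out$population
  out
}

#' Effective phylum, with Proteobacteria split into classes
#'
#' Proteobacteria spans too much metabolic diversity to aggregate at the
#' phylum rank, so MAGs of that phylum are keyed by class instead. When the
#' rank that would be used is missing, `"Unclassified-<parent>"` is returned.
#'
#' @param mags data.frame with at least `phylum` and `class` columns.
#' @return Character vector, one effective phylum per row of `mags`.
#' @export
#' @examples
#' effectivePhylum(data.frame(phylum = c("Proteobacteria", "Verrucomicrobia"),
#'                            class = c("Betaproteobacteria", NA)))
effectivePhylum <- function(mags) {
  .assertCols(mags, c("phylum", "class"), "MAG table")
  phylum <- as.character(mags$phylum)
  if (any(is.na(phylum) | !nzchar(phylum)))
    stop("every MAG needs a phylum", call. = FALSE)
  cls <- as.character(mags$class)
  isProteo <- phylum == "Proteobacteria"
  out <- phylum
  out[isProteo] <- ifelse(is.na(cls[isProteo]) | !nzchar(cls[isProteo]),
                          "Unclassified-Proteobacteria", cls[isProteo])
  out
}

## Nitrogen atoms per residue in the polypeptide (backbone amide N plus side
## chain): 14 amino acids carry 1, N/Q/K/W carry 2, H carries 3, R carries 4.
## X (unknown) contributes the unweighted 20-residue average, 29/20.
.AA_NITROGEN <- c(
  G = 1, A = 1, S = 1, T = 1, C = 1, V = 1, L = 1, I = 1, M = 1, P = 1,
  F = 1, Y = 1, D = 1, E = 1, N = 2, Q = 2, K = 2, W = 2, H = 3, R = 4,
  X = 29 / 20)

#' Average nitrogen atoms per residue of a proteome
#'
#' Computes the mean number of nitrogen atoms per amino-acid residue over all
#' translated ORF sequences of a MAG, counting full-molecule nitrogen
#' (backbone plus side chain) per the standard amino-acid formulas. `X`
#' contributes the unweighted average over the 20 standard residues; stop
#' characters (`*`) are ignored.
#'
#' @param proteome named character vector of amino-acid sequences, as from
#'   [readProteinFasta()].
#' @return A single non-negative number.
#' @export
#' @examples
#' nitrogenPerResidue(c(g1 = "GK"))  # (1 + 2) / 2
nitrogenPerResidue <- function(proteome) {
  if (length(proteome) == 0L)
    stop("empty proteome: nitrogen per residue is undefined", call. = FALSE)
  chars <- strsplit(paste(proteome, collapse = ""), "")[[1L]]
  chars <- chars[chars != "*"]
  if (!length(chars))
    stop("proteome contains no residues", call. = FALSE)
  bad <- setdiff(unique(chars), names(.AA_NITROGEN))
  if (length(bad))
    stop(sprintf("illegal amino-acid character '%s'", bad[1L]), call. = FALSE)
  sum(.AA_NITROGEN[chars]) / length(chars)
}
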