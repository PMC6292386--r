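## Pathway presence calling. The scoring rule: a pathway is called present in
## a MAG when at least 50% of its steps are covered by the MAG's functional
## annotations AND, if any steps are unique (diagnostic) to the pathway,
## every unique step is covered. A step is covered when any of its annotation
## synonyms (across KEGG orthologs, COG, PFAM, TIGRFAM) appears in the MAG;
## multi-copy genes count once.

#' Is a pathway step covered by a MAG's annotations?
#'
#' A step is covered when the intersection of its annotation-id synonyms with
#' the MAG's annotation set is non-empty — evidence from any one annotation
#' system suffices.
#'
#' @param step a step entry of a [PathwayDefinition-class] (list with
#'   `step_id`, `annotation_ids`, `unique`).
#' @param magAnnotations character vector (set) of namespaced annotation ids
#'   present in the MAG.
#' @return `TRUE` or `FALSE`.
#' @export
stepCovered <- function(step, magAnnotations) {
  any(step$annotation_ids %in% magAnnotations)
}

#' Score one pathway against one MAG's annotation set
#'
#' @param pathway a [PathwayDefinition-class].
#' @param magAnnotations character vector of namespaced annotation ids.
#' @return A list with `pathway_id`, `completeness_fraction` (covered steps /
#'   total steps), `unique_steps_satisfied` (all unique steps covered;
#'   vacuously `TRUE` when the pathway has none) and `present`
#'   (`completeness_fraction >= 0.5 & unique_steps_satisfied`).
#' @export
#' @examples
#' pw <- PathwayDefinition("demo", list(
#'   list(step_id = "s1", annotation_ids = "KO:K00001", unique = TRUE),
#'   list(step_id = "s2", annotation_ids = "KO:K00002", unique = FALSE)))
#' scorePathway(pw, c("KO:K00001"))
scorePathway <- function(pathway, magAnnotations) {
  stopifnot(is(pathway, "PathwayDefinition"))
  covered <- vapply(pathway@steps, stepCovered, TRUE,
                    magAnnotations = magAnnotations)
  uniq <- vapply(pathway@steps, function(s) s$unique, TRUE)
  frac <- sum(covered) / length(covered)
  uniqOk <- all(covered[uniq])  # vacuously TRUE with no unique steps
  list(pathway_id = pathway@pathwayId,
       completeness_fraction = frac,
       unique_steps_satisfied = uniqOk,
       present = frac >= 0.5 && uniqOk)
}

#' Call all pathways for all MAGs
#'
#' Applies [scorePathway()] to every (MAG, pathway) pair. MAGs listed in
#' `magIds` but absent from the annotation table are scored with an empty
#' annotation set (completeness 0 everywhere), which is how fully
#' unannotated MAGs stay visible in the output.
#'
#' @param annotations annotation data.frame (`mag_id`, `gene_id`,
#'   `annotation_id`), as from [readAnnotationTable()].
#' @param catalog named list of [PathwayDefinition-class] objects, as from
#'   [readPathwayCatalog()].
#' @param magIds optional character vector fixing the MAG universe; defaults
#'   to the MAGs present in `annotations`.
#' @return A [PresenceMatrix-class].
#' @export
callAll <- function(annotations, catalog, magIds = NULL) {
  .assertCols(annotations, c("mag_id", "annotation_id"), "annotation table")
  pids <- vapply(catalog, function(p) p@pathwayId, "")
  if (anyDuplicated(pids))
    stop(sprintf("pathway catalog: duplicate pathway_id '%s'",
                 pids[duplicated(pids)][1L]), call. = FALSE)
  if (is.null(magIds)) magIds <- sort(unique(annotations$mag_id))
  magIds <- as.character(magIds)
  annSets <- split(annotations$annotation_id, annotations$mag_id)
  cf <- matrix(0, nrow = length(magIds), ncol = length(catalog),
               dimnames = list(magIds, unname(pids)))
  uok <- matrix(TRUE, nrow = length(magIds), ncol = length(catalog),
                dimnames = dimnames(cf))
  for (i in seq_along(magIds)) {
    ann <- annSets[[magIds[i]]] %||% character()
    for (j in seq_along(catalog)) {
      sc <- scorePathway(catalog[[j]], ann)
      cf[i, j] <- sc$completeness_fraction
      uok[i, j] <- sc$unique_steps_satisfied
    }
  }
  new("PresenceMatrix", completeness = cf, uniqueOk = uok,
      presence = (cf >= 0.5) & uok)
}

#' Aggregate presence calls by site and effective phylum
#'
#' Summarises a [PresenceMatrix-class] into a long table of (site, effective
#' phylum, pathway) groups, reporting the number of MAGs in the group, how
#' many carry the pathway, and the fraction. Proteobacteria are split into
#' classes via [effectivePhylum()]. Groups with zero presence calls are still
#' reported.
#'
#' @param matrix a [PresenceMatrix-class].
#' @param mags data.frame of MAG records covering every MAG in `matrix`.
#' @return data.frame with columns `site`, `effective_phylum`, `pathway_id`,
#'   `n_mags`, `n_present`, `fraction`.
#' @export
aggregatePresence <- function(matrix, mags) {
  stopifnot(is(matrix, "PresenceMatrix"))
  .assertCols(mags, c("mag_id", "site", "phylum", "class"), "MAG table")
  pres <- pathwayPresence(matrix)
  ids <- rownames(pres)
  miss <- setdiff(ids, mags$mag_id)
  if (length(miss))
    stop(sprintf("MAG(s) in presence matrix but not in metadata: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  meta <- mags[match(ids, mags$mag_id), ]
  key <- data.frame(site = as.character(meta$site),
                    effective_phylum = effectivePhylum(meta),
                    stringsAsFactors = FALSE)
  groups <- split(seq_along(ids), paste(key$site, key$effective_phylum,
                                        sep = "\r"))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- groups[[g]]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    npres <- colSums(pres[rows, , drop = FALSE])
    data.frame(site = parts[1L], effective_phylum = parts[2L],
               pathway_id = colnames(pres),
               n_mags = length(rows), n_present = as.integer(npres),
               fraction = npres / length(rows),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out <- out[order(out$site, out$effective_phylum, out$pathway_id), ]
  rownames(out) <- NULL
  out
}
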