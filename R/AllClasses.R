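#' @import methods
NULL

## The three lake environments of the study design. Mendota's hypolimnion was
## never sequenced, so it is not a level.
.SITES <- c("mendota_epi", "troutbog_epi", "troutbog_hypo")

#' Sampling sites recognised by the package
#'
#' The three lake environments of the underlying study design: the epilimnion
#' of a large eutrophic lake, and the epilimnion and hypolimnion of a small
#' humic bog lake.
#'
#' @return Character vector of the three site codes.
#' @export
#' @examples
#' lakeSites()
lakeSites <- function() .SITES

#' PathwayDefinition: one metabolic pathway as a set of enzymatic steps
#'
#' A pathway is an ordered list of enzymatic steps. Each step carries a
#' non-empty set of namespaced functional annotation identifiers
#' (`KO:`/`COG:`/`PFAM:`/`TIGR:`) that are treated as synonyms: evidence from
#' any one annotation system satisfies the step. Steps flagged `unique` are
#' diagnostic for the pathway and must all be covered for a presence call,
#' in addition to the 50% overall completeness rule.
#'
#' @slot pathwayId single pathway identifier.
#' @slot steps a list; each element a list with entries `step_id` (character),
#'   `annotation_ids` (character vector of namespaced ids) and `unique`
#'   (logical flag).
#'
#' @seealso [scorePathway()], [readPathwayCatalog()]
#' @export
setClass("PathwayDefinition",
  representation(pathwayId = "character", steps = "list"))

setValidity("PathwayDefinition", function(object) {
  msgs <- character()
  if (length(object@pathwayId) != 1L || is.na(object@pathwayId) ||
      !nzchar(object@pathwayId))
    msgs <- c(msgs, "pathwayId must be a single non-empty string")
  if (length(object@steps) < 1L)
    msgs <- c(msgs, "a pathway needs at least one step")
  ids <- vapply(object@steps, function(s) s$step_id %||% NA_character_, "")
  if (anyNA(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "every step needs a non-empty step_id")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate step_id within pathway '%s'",
                            object@pathwayId))
  for (s in object@steps) {
    ann <- s$annotation_ids
    if (length(ann) == 0L)
      msgs <- c(msgs, sprintf("step '%s' has no annotation ids", s$step_id))
    bad <- ann[!grepl(.NS_REGEX, ann)]
    if (length(bad))
      msgs <- c(msgs, sprintf("step '%s': annotation id(s) not namespaced: %s",
                              s$step_id, paste(bad, collapse = ", ")))
    if (!is.logical(s$unique) || length(s$unique) != 1L || is.na(s$unique))
      msgs <- c(msgs, sprintf("step '%s': 'unique' must be TRUE or FALSE",
                              s$step_id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PathwayDefinition
#'
#' @param pathwayId pathway identifier.
#' @param steps list of steps; each a list with `step_id`, `annotation_ids`
#'   and `unique` (see [PathwayDefinition-class]). `unique` defaults to
#'   `FALSE` when absent.
#' @return A [PathwayDefinition-class] object.
#' @export
#' @examples
#' PathwayDefinition("nitrogen_fixation", list(
#'   list(step_id = "nifH", annotation_ids = c("TIGR:TIGR1287", "KO:K02588"),
#'        unique = TRUE),
#'   list(step_id = "nifD", annotation_ids = "TIGR:TIGR1282")))
PathwayDefinition <- function(pathwayId, steps) {
  steps <- lapply(steps, function(s) {
    s$unique <- isTRUE(s$unique)
    s$annotation_ids <- as.character(s$annotation_ids)
    s
  })
  new("PathwayDefinition", pathwayId = pathwayId, steps = steps)
}

setMethod("show", "PathwayDefinition", function(object) {
  nuniq <- sum(vapply(object@steps, function(s) s$unique, TRUE))
  cat(sprintf("PathwayDefinition '%s': %d step(s), %d unique\n",
              object@pathwayId, length(object@steps), nuniq))
  for (s in object@steps)
    cat(sprintf("  %s%s: %s\n", s$step_id, if (s$unique) " [unique]" else "",
                paste(s$annotation_ids, collapse = ", ")))
})

#' PresenceMatrix: per-MAG pathway completeness and presence calls
#'
#' Holds, for every MAG x pathway pair, the fraction of the pathway's steps
#' covered by the MAG's annotations, whether all pathway-unique steps are
#' covered, and the resulting presence call. By construction
#' `present == (completeness >= 0.5 & uniqueOk)`.
#'
#' @slot completeness numeric matrix (MAG x pathway) of step-coverage
#'   fractions in \[0, 1\].
#' @slot uniqueOk logical matrix: all unique steps covered (vacuously `TRUE`
#'   for pathways without unique steps).
#' @slot presence logical matrix of presence calls.
#'
#' @seealso [callAll()], [pathwayCompleteness()], [pathwayPresence()]
#' @export
setClass("PresenceMatrix",
  representation(completeness = "matrix", uniqueOk = "matrix",
                 presence = "matrix"))

setValidity("PresenceMatrix", function(object) {
  msgs <- character()
  d <- dim(object@completeness)
  if (!identical(d, dim(object@uniqueOk)) || !identical(d, dim(object@presence)))
    msgs <- c(msgs, "slot dimensions differ")
  if (!identical(dimnames(object@completeness), dimnames(object@presence)) ||
      !identical(dimnames(object@completeness), dimnames(object@uniqueOk)))
    msgs <- c(msgs, "slot dimnames differ")
  if (is.null(rownames(object@completeness)) && prod(d) > 0)
    msgs <- c(msgs, "matrices must carry MAG row names and pathway column names")
  cf <- object@completeness
  if (length(cf) && (any(cf < 0) || any(cf > 1)))
    msgs <- c(msgs, "completeness fractions must lie in [0, 1]")
  if (!is.logical(object@presence) || !is.logical(object@uniqueOk))
    msgs <- c(msgs, "presence and uniqueOk must be logical matrices")
  else if (length(cf) &&
           !identical(object@presence,
                      (cf >= 0.5) & object@uniqueOk))
    msgs <- c(msgs, "presence must equal (completeness >= 0.5) & uniqueOk")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d MAG(s) x %d pathway(s); %d presence call(s)\n",
              nrow(object@presence), ncol(object@presence),
              sum(object@presence)))
})

#' @describeIn PresenceMatrix-class MAG x pathway matrix of step-coverage
#'   fractions.
#' @param x a `PresenceMatrix`.
#' @export
pathwayCompleteness <- function(x) {
  stopifnot(is(x, "PresenceMatrix"))
  x@completeness
}

#' @describeIn PresenceMatrix-class MAG x pathway logical matrix of presence
#'   calls.
#' @export
pathwayPresence <- function(x) {
  stopifnot(is(x, "PresenceMatrix"))
  x@presence
}

#' @describeIn PresenceMatrix-class MAG x pathway logical matrix recording
#'   whether every pathway-unique step is covered.
#' @export
uniqueStepsOk <- function(x) {
  stopifnot(is(x, "PresenceMatrix"))
  x@uniqueOk
}
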