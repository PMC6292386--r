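## Functional marker gene survey of unassembled metagenomes: filter homology
## hits at an identity cutoff, reduce to the best hit per ORF, normalize per
## metagenome, aggregate by function category, and contrast sites with
## Wilcoxon rank-sum tests under Bonferroni correction. Only two site pairs
## are contrasted — the two epilimnia, and the two layers of the bog lake —
## because the epilimnion of one lake vs the hypolimnion of the other
## confounds too many factors to be informative.

.SITE_PAIRS <- list(c("mendota_epi", "troutbog_epi"),
                    c("troutbog_epi", "troutbog_hypo"))

#' Filter homology hits by identity and reduce to best hit per ORF
#'
#' Retains hits with `percent_identity >= minIdentity` (inclusive cutoff,
#' default 30%), then keeps only the best-scoring hit per query ORF within
#' each metagenome (highest bitscore, ties by lexicographically smallest
#' subject id), so one ORF never counts toward more than one marker.
#'
#' @param hits data.frame of hit records, as from [readBlastTab()].
#' @param minIdentity percent identity cutoff (default 30).
#' @param bestHitOnly if `FALSE`, skip the best-hit reduction and keep every
#'   passing hit.
#' @return The retained subset of `hits`.
#' @export
filterHits <- function(hits, minIdentity = 30, bestHitOnly = TRUE) {
  .assertCols(hits, c("metagenome_id", "query_id", "subject_id",
                      "percent_identity", "bitscore"), "hit table")
  out <- hits[hits$percent_identity >= minIdentity, , drop = FALSE]
  if (bestHitOnly && nrow(out)) {
    ord <- order(out$metagenome_id, out$query_id, -out$bitscore,
                 out$subject_id)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out[, c("metagenome_id", "query_id")]), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-metagenome marker abundance by function category
#'
#' Counts retained hits per (metagenome, function category) and normalizes by
#' metagenome size to hits per million reads. Every combination of
#' metagenome and catalog category is present, zero-filled.
#'
#' @param hits filtered hit records (see [filterHits()]); `subject_id` must
#'   resolve to a `marker_id` of `catalog`.
#' @param catalog marker catalog data.frame (`marker_id`,
#'   `function_category`), as from [readMarkerCatalog()].
#' @param metas metagenome info data.frame (see [readMetagenomeTable()]).
#' @param lenient if `TRUE`, hits whose subject is not in the catalog are
#'   dropped with a warning instead of raising an error.
#' @param perBasePair normalize by base pairs (`base_count` column of
#'   `metas`, or `read_count * 150`) instead of reads; the unit becomes hits
#'   per million base pairs.
#' @return data.frame with columns `metagenome_id`, `function_category`,
#'   `raw_hits`, `hits_per_million`.
#' @export
abundanceTable <- function(hits, catalog, metas, lenient = FALSE,
                           perBasePair = FALSE) {
  .assertCols(hits, c("metagenome_id", "subject_id"), "hit table")
  .assertCols(catalog, c("marker_id", "function_category"), "marker catalog")
  .assertCols(metas, c("metagenome_id", "read_count"), "metagenome table")
  unknownMg <- setdiff(unique(hits$metagenome_id), metas$metagenome_id)
  if (length(unknownMg))
    stop(sprintf("hits reference metagenome(s) not in the metagenome table: %s",
                 paste(unknownMg, collapse = ", ")), call. = FALSE)
  cat2 <- catalog$function_category[match(hits$subject_id, catalog$marker_id)]
  if (anyNA(cat2)) {
    offenders <- sort(unique(hits$subject_id[is.na(cat2)]))
    if (!lenient)
      stop(sprintf("subject id(s) not in the marker catalog: %s",
                   paste(offenders, collapse = ", ")), call. = FALSE)
    warning(sprintf("dropping %d hit(s) with subjects not in the catalog: %s",
                    sum(is.na(cat2)), paste(offenders, collapse = ", ")),
            call. = FALSE)
    hits <- hits[!is.na(cat2), , drop = FALSE]
    cat2 <- cat2[!is.na(cat2)]
  }
  cats <- sort(unique(catalog$function_category))
  mgs <- as.character(metas$metagenome_id)
  counts <- table(factor(hits$metagenome_id, levels = mgs),
                  factor(cat2, levels = cats))
  out <- data.frame(
    metagenome_id = rep(mgs, times = length(cats)),
    function_category = rep(cats, each = length(mgs)),
    raw_hits = as.integer(counts),
    stringsAsFactors = FALSE)
  size <- if (perBasePair) {
    bc <- metas$base_count %||% (metas$read_count * 150)
    bc[match(out$metagenome_id, metas$metagenome_id)]
  } else {
    metas$read_count[match(out$metagenome_id, metas$metagenome_id)]
  }
  out$hits_per_million <- out$raw_hits * 1e6 / size
  out <- out[order(out$metagenome_id, out$function_category), ]
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the smaller group has at most 8 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return A list with `statistic` (the Mann-Whitney U for `x`) and `p_raw`.
#' @export
#' @examples
#' rankSumTest(c(1, 2, 3, 4), c(5, 6, 7, 8))  # exact p = 2/70
rankSumTest <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_raw = ht$p.value)
}

#' Contrast marker abundances between sites
#'
#' For every function category and each of the two tested site pairs
#' (epilimnion vs epilimnion across lakes; epilimnion vs hypolimnion within
#' the bog lake), runs [rankSumTest()] on the per-metagenome
#' `hits_per_million` values and applies a Bonferroni correction over the
#' full family of tests (categories x 2 pairs). A direction (`higher_site`,
#' the site with the larger median) is reported only when the adjusted
#' p-value clears `alpha`; otherwise `"ns"`.
#'
#' @param abund abundance table from [abundanceTable()].
#' @param metas metagenome info data.frame.
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame with columns `function_category`, `site_a`, `site_b`,
#'   `statistic`, `p_raw`, `p_adjusted`, `higher_site`. Comparisons with an
#'   empty site group are reported as `NA` with a warning.
#' @export
compareSites <- function(abund, metas, alpha = 0.05) {
  .assertCols(abund, c("metagenome_id", "function_category",
                       "hits_per_million"), "abundance table")
  .assertCols(metas, c("metagenome_id", "site"), "metagenome table")
  .assertSites(metas$site, "metagenome table")
  site <- metas$site[match(abund$metagenome_id, metas$metagenome_id)]
  if (anyNA(site))
    stop("abundance rows reference metagenomes not in the metagenome table",
         call. = FALSE)
  cats <- sort(unique(abund$function_category))
  nTests <- length(cats) * length(.SITE_PAIRS)
  rows <- list()
  for (cc in cats) {
    for (pair in .SITE_PAIRS) {
      sel <- abund$function_category == cc
      xa <- abund$hits_per_million[sel & site == pair[1L]]
      xb <- abund$hits_per_million[sel & site == pair[2L]]
      if (!length(xa) || !length(xb)) {
        warning(sprintf("no data for '%s' in pair %s vs %s; reported as NA",
                        cc, pair[1L], pair[2L]), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          function_category = cc, site_a = pair[1L], site_b = pair[2L],
          statistic = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
          higher_site = NA_character_, stringsAsFactors = FALSE)
        next
      }
      ht <- rankSumTest(xa, xb)
      padj <- min(1, ht$p_raw * nTests)
      higher <- if (!is.na(padj) && padj < alpha) {
        if (stats::median(xa) >= stats::median(xb)) pair[1L] else pair[2L]
      } else "ns"
      rows[[length(rows) + 1L]] <- data.frame(
        function_category = cc, site_a = pair[1L], site_b = pair[2L],
        statistic = ht$statistic, p_raw = ht$p_raw, p_adjusted = padj,
        higher_site = higher, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
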