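## Linking MAG population dynamics to marker gene dynamics over a sampling
## season: genome-length- and metagenome-size-normalized read coverage,
## per-year dominant MAG selection, dated marker abundance series, and their
## correlation.

#' Normalize MAG read coverage by genome length and metagenome size
#'
#' `normalized_coverage = (mapped_bases / genome_length) / metagenome
#' gigabases`, i.e. mean per-base coverage depth per gigabase of sequencing.
#' Metagenome size is taken from a `base_count` column of `metas` when
#' present, otherwise `read_count * 150` (150 bp reads). Missing (MAG,
#' metagenome) pairs are zero-filled.
#'
#' @param raw data.frame with columns `mag_id`, `metagenome_id`,
#'   `mapped_bases` (see [readCoverageTable()]).
#' @param mags data.frame of MAG records (for `genome_length`).
#' @param metas metagenome info data.frame (for dates and sizes).
#' @return data.frame with columns `mag_id`, `metagenome_id`, `sample_date`,
#'   `normalized_coverage`, ordered by MAG then date.
#' @export
normalizeCoverage <- function(raw, mags, metas) {
  .assertCols(raw, c("mag_id", "metagenome_id", "mapped_bases"),
              "coverage table")
  .assertCols(mags, c("mag_id", "genome_length"), "MAG table")
  .assertCols(metas, c("metagenome_id", "sample_date", "read_count"),
              "metagenome table")
  badMag <- setdiff(unique(raw$mag_id), mags$mag_id)
  if (length(badMag))
    stop(sprintf("coverage references unknown MAG(s): %s",
                 paste(badMag, collapse = ", ")), call. = FALSE)
  badMg <- setdiff(unique(raw$metagenome_id), metas$metagenome_id)
  if (length(badMg))
    stop(sprintf("coverage references unknown metagenome(s): %s",
                 paste(badMg, collapse = ", ")), call. = FALSE)
  ids <- sort(unique(as.character(raw$mag_id)))
  mgs <- as.character(metas$metagenome_id)
  grid <- expand.grid(mag_id = ids, metagenome_id = mgs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(raw$mag_id, raw$metagenome_id, sep = "\r")
  gkey <- paste(grid$mag_id, grid$metagenome_id, sep = "\r")
  mapped <- raw$mapped_bases[match(gkey, key)]
  mapped[is.na(mapped)] <- 0
  glen <- mags$genome_length[match(grid$mag_id, mags$mag_id)]
  bases <- (metas$base_count %||% (metas$read_count * 150))
  gb <- bases[match(grid$metagenome_id, metas$metagenome_id)] / 1e9
  grid$sample_date <- metas$sample_date[match(grid$metagenome_id,
                                              metas$metagenome_id)]
  grid$normalized_coverage <- (mapped / glen) / gb
  grid <- grid[order(grid$mag_id, grid$sample_date, grid$metagenome_id), ]
  rownames(grid) <- NULL
  grid[, c("mag_id", "metagenome_id", "sample_date", "normalized_coverage")]
}

#' Most abundant MAG of a group in one year
#'
#' Among `group`, returns the MAG with the highest mean normalized coverage
#' over the year's samples (ties broken lexicographically, and logged), plus
#' a dominance ratio (top mean / runner-up mean; `Inf` for a single-member
#' group or a zero runner-up).
#'
#' @param coverage data.frame from [normalizeCoverage()].
#' @param group character vector of candidate `mag_id`s (e.g. all
#'   Cyanobacteria MAGs).
#' @param year calendar year to evaluate.
#' @return A list with `mag_id`, `dominance_ratio` and `means` (named vector
#'   of within-year mean coverages).
#' @export
dominantMagPerYear <- function(coverage, group, year) {
  .assertCols(coverage, c("mag_id", "sample_date", "normalized_coverage"),
              "coverage series")
  sel <- coverage$mag_id %in% group & .yearOf(coverage$sample_date) == year
  if (!any(sel))
    stop(sprintf("no coverage points for the group in year %d", year),
         call. = FALSE)
  sub <- coverage[sel, , drop = FALSE]
  means <- tapply(sub$normalized_coverage, sub$mag_id, mean)
  means <- means[order(-means, names(means))]
  if (length(means) > 1L && means[1L] == means[2L])
    message(sprintf("dominance tie in %d between %s and %s; using %s",
                    year, names(means)[1L], names(means)[2L],
                    names(means)[1L]))
  ratio <- if (length(means) > 1L && means[2L] > 0)
    unname(means[1L] / means[2L]) else Inf
  list(mag_id = names(means)[1L], dominance_ratio = ratio,
       means = means)
}

#' Dated abundance series for one function category
#'
#' Sums the normalized hit abundance of a function category per sample date
#' (several metagenomes on the same date are summed), date-ordered.
#'
#' @param abund abundance table from [abundanceTable()].
#' @param metas metagenome info data.frame (for sample dates).
#' @param category function category name, e.g. `"nitrogen fixation"`.
#' @return data.frame with columns `sample_date`, `value`.
#' @export
markerSeries <- function(abund, metas, category) {
  .assertCols(abund, c("metagenome_id", "function_category",
                       "hits_per_million"), "abundance table")
  .assertCols(metas, c("metagenome_id", "sample_date"), "metagenome table")
  if (!category %in% abund$function_category)
    stop(sprintf("unknown function category '%s'", category), call. = FALSE)
  sub <- abund[abund$function_category == category, , drop = FALSE]
  dates <- metas$sample_date[match(sub$metagenome_id, metas$metagenome_id)]
  if (anyNA(dates))
    stop("abundance rows reference metagenomes not in the metagenome table",
         call. = FALSE)
  agg <- tapply(sub$hits_per_million, as.character(dates), sum)
  out <- data.frame(sample_date = as.Date(names(agg)), value = unname(agg))
  out <- out[order(out$sample_date), ]
  rownames(out) <- NULL
  out
}

#' Correlate two dated series
#'
#' Inner-joins the two series on `sample_date` and computes a correlation
#' with its two-sided p-value (t transform, n - 2 degrees of freedom for
#' Pearson). Requires at least 3 shared dates.
#'
#' @param a,b data.frames with columns `sample_date` and `value` (the second
#'   column is used as the value when named differently).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log1p transform both series with `log1p()` before correlating.
#' @return A list with `r`, `p_value`, `n`.
#' @export
correlateSeries <- function(a, b, method = c("pearson", "spearman"),
                            log1p = FALSE) {
  method <- match.arg(method)
  .assertCols(a, "sample_date", "series a")
  .assertCols(b, "sample_date", "series b")
  va <- a[[setdiff(names(a), "sample_date")[1L]]]
  vb <- b[[setdiff(names(b), "sample_date")[1L]]]
  idx <- match(as.character(a$sample_date), as.character(b$sample_date))
  keep <- !is.na(idx)
  x <- va[keep]
  y <- vb[idx[keep]]
  if (length(x) < 3L)
    stop(sprintf("need >= 3 shared dates, found %d", length(x)),
         call. = FALSE)
  if (log1p) {
    x <- log1p(x)
    y <- log1p(y)
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
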