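## Shared internal helpers: column checks, namespace rules, small utilities.

.NS_REGEX <- "^(KO|COG|PFAM|TIGR):\\S+$"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Error if any required column is missing; names the first offender.
.assertCols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.assertSites <- function(site, what) {
  bad <- setdiff(unique(as.character(site)), .SITES)
  if (length(bad))
    stop(sprintf("%s: unknown site(s): %s (expected one of %s)", what,
                 paste(bad, collapse = ", "), paste(.SITES, collapse = ", ")),
         call. = FALSE)
  invisible(site)
}

## Read a headered TSV without any type mangling of id columns.
.readTsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), colClasses = NA,
                    comment.char = "")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Calendar year of a Date vector.
.yearOf <- function(d) as.integer(format(as.Date(d), "%Y"))
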