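## Readers and writers for the tabular and sequence formats the pipeline
## consumes. Everything is plain headered TSV (diff-friendly, matching the
## tabular shape of IMG-style exports), BLAST 12-column tabular,
## protein FASTA, or a YAML pathway catalog. Readers validate hard and never
## silently drop rows: malformed content is an error with a line number,
## duplicates are collapsed with a warning.

#' Read a per-gene functional annotation table
#'
#' Reads a tab-separated table with header columns `mag_id`, `gene_id`,
#' `annotation_id` as exported (after normalization) from an IMG-style
#' annotation of MAGs. Annotation ids must be namespaced with one of the four
#' annotation systems the pipeline pools: `KO:`, `COG:`, `PFAM:`, `TIGR:`.
#' Exact duplicate rows are collapsed with a warning.
#'
#' @param path path to a TSV file.
#' @return A data.frame with columns `mag_id`, `gene_id`, `annotation_id`;
#'   rows unique.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("mag_id\tgene_id\tannotation_id",
#'              "m1\tg1\tKO:K02588", "m1\tg2\tTIGR:TIGR1287"), f)
#' readAnnotationTable(f)
readAnnotationTable <- function(path) {
  df <- .readTsv(path)
  .assertCols(df, c("mag_id", "gene_id", "annotation_id"),
              sprintf("annotation table '%s'", path))
  df <- df[, c("mag_id", "gene_id", "annotation_id")]
  for (cl in names(df)) df[[cl]] <- as.character(df[[cl]])
  if (any(is.na(df$gene_id)) || any(!nzchar(df$gene_id))) {
    line <- which(is.na(df$gene_id) | !nzchar(df$gene_id))[1L] + 1L
    stop(sprintf("annotation table '%s': empty gene_id at line %d",
                 path, line), call. = FALSE)
  }
  bad <- !grepl(.NS_REGEX, df$annotation_id)
  if (any(bad)) {
    line <- which(bad)[1L] + 1L  # +1 for the header line
    stop(sprintf(paste0("annotation table '%s': annotation_id '%s' at line %d",
                        " lacks a KO:/COG:/PFAM:/TIGR: namespace"),
                 path, df$annotation_id[which(bad)[1L]], line), call. = FALSE)
  }
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("annotation table '%s': collapsed %d duplicate row(s)",
                    path, sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write an annotation table
#'
#' @param annotations data.frame as returned by [readAnnotationTable()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeAnnotationTable <- function(annotations, path) {
  .assertCols(annotations, c("mag_id", "gene_id", "annotation_id"),
              "annotation table")
  .writeTsv(annotations[, c("mag_id", "gene_id", "annotation_id")], path)
}

#' Read BLAST tabular output for one metagenome
#'
#' Parses the conventional 12-column BLAST tabular dialect (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`),
#' keeping the fields the marker survey uses. Lines with a different column
#' count raise a format error naming the line.
#'
#' @param path path to a (headerless) BLAST tabular file.
#' @param metagenomeId identifier of the metagenome the ORFs come from.
#' @return A data.frame of hit records with columns `metagenome_id`,
#'   `query_id`, `subject_id`, `percent_identity`, `bitscore`. Empty file
#'   gives zero rows.
#' @export
readBlastTab <- function(path, metagenomeId) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  stopifnot(is.character(metagenomeId), length(metagenomeId) == 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(metagenome_id = character(), query_id = character(),
                      subject_id = character(), percent_identity = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop(sprintf("BLAST tabular '%s': expected 12 columns, found %d at line %d",
                 path, nf[nf != 12L][1L], which(nf != 12L)[1L]), call. = FALSE)
  m <- do.call(rbind, fields)
  pid <- as.numeric(m[, 3L])
  bits <- as.numeric(m[, 12L])
  if (anyNA(pid) || any(pid < 0) || any(pid > 100)) {
    line <- which(is.na(pid) | pid < 0 | pid > 100)[1L]
    stop(sprintf("BLAST tabular '%s': percent identity out of [0,100] at line %d",
                 path, line), call. = FALSE)
  }
  if (anyNA(bits) || any(bits < 0)) {
    line <- which(is.na(bits) | bits < 0)[1L]
    stop(sprintf("BLAST tabular '%s': negative or unparseable bitscore at line %d",
                 path, line), call. = FALSE)
  }
  data.frame(metagenome_id = metagenomeId, query_id = m[, 1L],
             subject_id = m[, 2L], percent_identity = pid, bitscore = bits,
             stringsAsFactors = FALSE)
}

#' Write hit records as BLAST 12-column tabular
#'
#' Unused intermediate columns are filled with neutral values so that
#' `readBlastTab(writeBlastTab(x))` reproduces the retained fields exactly.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `bitscore` (a `metagenome_id` column is ignored).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeBlastTab <- function(hits, path) {
  .assertCols(hits, c("query_id", "subject_id", "percent_identity", "bitscore"),
              "hit table")
  n <- nrow(hits)
  lines <- sprintf("%s\t%s\t%s\t100\t0\t0\t1\t100\t1\t100\t1e-10\t%s",
                   hits$query_id, hits$subject_id,
                   vapply(hits$percent_identity, function(v) sprintf("%.17g", v), ""),
                   vapply(hits$bitscore, function(v) sprintf("%.17g", v), ""))
  writeLines(if (n) lines else character(), path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Sequences are keyed by the first whitespace-delimited token of each
#' header. Trailing stop characters (`*`) are stripped. Only the 20 standard
#' amino-acid letters plus `X` (unknown residue) and `*` are accepted;
#' any other letter is an error naming the character.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return Named character vector: gene id to amino-acid string.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop(sprintf("protein FASTA '%s': duplicate record id '%s'",
                 path, ids[duplicated(ids)][1L]), call. = FALSE)
  seqs <- as.character(aa)
  seqs <- sub("\\*+$", "", seqs)
  allowed <- c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]], "*")
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1L]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop(sprintf("protein FASTA '%s': illegal character '%s' in record '%s'",
                   path, bad[1L], ids[i]), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write a labeled numeric matrix as TSV
#'
#' Values are written at full double precision so that [readMatrixTsv()]
#' reproduces the matrix exactly.
#'
#' @param matrix numeric matrix with unique row and column names.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeMatrixTsv <- function(matrix, path) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix must have row and column names", call. = FALSE)
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate row labels", call. = FALSE)
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate column labels", call. = FALSE)
  header <- paste(c("", colnames(matrix)), collapse = "\t")
  body <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.17g", matrix[i, ])),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a labeled numeric matrix written by [writeMatrixTsv()]
#'
#' @param path path to the TSV file.
#' @return Numeric matrix with row and column names.
#' @export
readMatrixTsv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Read a functional marker gene catalog
#'
#' A TSV with columns `marker_id` and `function_category` mapping each marker
#' protein family (TIGRFAM/COG/PFAM id) to the metabolic function it is
#' diagnostic for (e.g. `nitrogen fixation`). Every marker must map to
#' exactly one category.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `marker_id`, `function_category`.
#' @export
readMarkerCatalog <- function(path) {
  df <- .readTsv(path)
  .assertCols(df, c("marker_id", "function_category"),
              sprintf("marker catalog '%s'", path))
  df <- df[, c("marker_id", "function_category")]
  df$marker_id <- as.character(df$marker_id)
  df$function_category <- as.character(df$function_category)
  dup <- unique(df$marker_id[duplicated(df$marker_id)])
  if (length(dup))
    stop(sprintf("marker catalog '%s': marker(s) mapped more than once: %s",
                 path, paste(dup, collapse = ", ")), call. = FALSE)
  df
}

#' Read a MAG metadata table
#'
#' TSV with one row per MAG: `mag_id`, `site`, the lineage ranks `phylum`,
#' `class`, `order`, `family`, `genus`, `species` (any rank may be NA),
#' `completeness` and `contamination` (percent), `genome_length` (bases) and
#' `gene_count`.
#'
#' @param path path to the TSV file.
#' @return Validated data.frame of MAG records.
#' @export
readMagTable <- function(path) {
  df <- .readTsv(path)
  need <- c("mag_id", "site", "phylum", "class", "order", "family", "genus",
            "species", "completeness", "contamination", "genome_length",
            "gene_count")
  .assertCols(df, need, sprintf("MAG table '%s'", path))
  df <- df[, need]
  df$mag_id <- as.character(df$mag_id)
  .assertSites(df$site, sprintf("MAG table '%s'", path))
  if (anyDuplicated(df$mag_id))
    stop(sprintf("MAG table '%s': duplicate mag_id", path), call. = FALSE)
  num <- c("completeness", "contamination", "genome_length", "gene_count")
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  if (any(df$completeness < 0 | df$completeness > 100) ||
      any(df$contamination < 0 | df$contamination > 100))
    stop(sprintf("MAG table '%s': completeness/contamination outside [0,100]",
                 path), call. = FALSE)
  if (any(df$genome_length <= 0))
    stop(sprintf("MAG table '%s': genome_length must be positive", path),
         call. = FALSE)
  df
}

#' Read a pairwise ANI table
#'
#' TSV with columns `mag_a`, `mag_b`, `ani` (percent average nucleotide
#' identity). Lookup is symmetric; pairs absent from the table are treated as
#' below any grouping threshold.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `mag_a`, `mag_b`, `ani`.
#' @export
readAniTable <- function(path) {
  df <- .readTsv(path)
  .assertCols(df, c("mag_a", "mag_b", "ani"), sprintf("ANI table '%s'", path))
  df <- df[, c("mag_a", "mag_b", "ani")]
  df$mag_a <- as.character(df$mag_a)
  df$mag_b <- as.character(df$mag_b)
  df$ani <- as.numeric(df$ani)
  if (anyNA(df$ani) || any(df$ani < 0 | df$ani > 100))
    stop(sprintf("ANI table '%s': ani values must lie in [0,100]", path),
         call. = FALSE)
  df
}

#' Read a metagenome information table
#'
#' TSV with columns `metagenome_id`, `site`, `sample_date` (ISO date) and
#' `read_count` (merged reads); an optional `base_count` column gives the
#' metagenome size in base pairs directly.
#'
#' @param path path to the TSV file.
#' @return data.frame with `sample_date` parsed as `Date`.
#' @export
readMetagenomeTable <- function(path) {
  df <- .readTsv(path)
  .assertCols(df, c("metagenome_id", "site", "sample_date", "read_count"),
              sprintf("metagenome table '%s'", path))
  df$metagenome_id <- as.character(df$metagenome_id)
  .assertSites(df$site, sprintf("metagenome table '%s'", path))
  if (anyDuplicated(df$metagenome_id))
    stop(sprintf("metagenome table '%s': duplicate metagenome_id", path),
         call. = FALSE)
  df$sample_date <- as.Date(df$sample_date)
  df$read_count <- as.numeric(df$read_count)
  if (anyNA(df$read_count) || any(df$read_count <= 0))
    stop(sprintf("metagenome table '%s': read_count must be positive", path),
         call. = FALSE)
  df
}

#' Read a per-sample MAG read-coverage table
#'
#' TSV with columns `mag_id`, `metagenome_id`, `mapped_bases` (total bases of
#' the metagenome's reads mapping to the MAG).
#'
#' @param path path to the TSV file.
#' @return data.frame with those three columns.
#' @export
readCoverageTable <- function(path) {
  df <- .readTsv(path)
  .assertCols(df, c("mag_id", "metagenome_id", "mapped_bases"),
              sprintf("coverage table '%s'", path))
  df <- df[, c("mag_id", "metagenome_id", "mapped_bases")]
  df$mapped_bases <- as.numeric(df$mapped_bases)
  if (anyNA(df$mapped_bases) || any(df$mapped_bases < 0))
    stop(sprintf("coverage table '%s': mapped_bases must be >= 0", path),
         call. = FALSE)
  df
}

#' Read a pathway catalog from YAML
#'
#' The catalog is a YAML document with a top-level `pathways` list; each
#' entry has `pathway_id` and a `steps` list of `{step_id, annotation_ids,
#' unique}`. See `system.file("extdata", "pathways.yaml", package =
#' "limnoMAGs")` for the demonstration catalog shipped with the package.
#'
#' @param path path to the YAML file.
#' @return Named list of [PathwayDefinition-class] objects.
#' @export
#' @examples
#' cat <- readPathwayCatalog(system.file("extdata", "pathways.yaml",
#'                                       package = "limnoMAGs"))
#' names(cat)
readPathwayCatalog <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$pathways))
    stop(sprintf("pathway catalog '%s': missing top-level 'pathways' key",
                 path), call. = FALSE)
  defs <- lapply(doc$pathways, function(p) {
    if (is.null(p$pathway_id))
      stop(sprintf("pathway catalog '%s': entry without pathway_id", path),
           call. = FALSE)
    PathwayDefinition(p$pathway_id, p$steps)
  })
  ids <- vapply(defs, function(p) p@pathwayId, "")
  if (anyDuplicated(ids))
    stop(sprintf("pathway catalog '%s': duplicate pathway_id '%s'",
                 path, ids[duplicated(ids)][1L]), call. = FALSE)
  names(defs) <- ids
  defs
}

#' The demonstration pathway catalog shipped with the package
#'
#' A small curated catalog of freshwater-relevant metabolic pathways
#' (nitrogen fixation, sulfate reduction, carbon fixation, polyamine
#' metabolism, sugar degradation) used by the synthetic-data generator and
#' the examples. It is a demonstration catalog, not a curation of KEGG or
#' MetaCyc content.
#'
#' @return Named list of [PathwayDefinition-class] objects.
#' @export
demoPathwayCatalog <- function() {
  readPathwayCatalog(system.file("extdata", "pathways.yaml",
                                 package = "limnoMAGs"))
}

#' The demonstration marker catalog shipped with the package
#'
#' @return data.frame with columns `marker_id`, `function_category`.
#' @export
demoMarkerCatalog <- function() {
  readMarkerCatalog(system.file("extdata", "markers.tsv",
                                package = "limnoMAGs"))
}
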