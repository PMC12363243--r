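#' Read sequencing reads from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that auto-detects
#' the format from the first record marker (`>` FASTA, `@` FASTQ) and
#' handles gzip transparently. Lowercase bases are normalized to uppercase
#' by the DNA alphabet; ambiguity codes (N etc.) are retained and simply
#' never contribute tetranucleotide windows downstream.
#'
#' @param path path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return A [Biostrings::DNAStringSet] in file order, names = record ids.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    first <- ""
    while (!length(first) || !nzchar(first)) {
      first <- readLines(con, n = 1L)
      if (!length(first)) break  # empty file
    }
    close(con); on.exit()
    if (!length(first)) return(Biostrings::DNAStringSet())
    marker <- substr(first, 1L, 1L)
    format <- switch(marker, ">" = "fasta", "@" = "fastq",
      stop("cannot auto-detect format of '", path,
           "': first record starts with '", marker, "', expected '>' or '@'"))
  }
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop("malformed ", format, " in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  # keep only the id token, as FASTQ/FASTA headers may carry descriptions
  if (length(res)) names(res) <- sub("\\s.*$", "", names(res))
  res
}

#' Load per-metagenome ecosystem metadata
#'
#' Reads a delimited table carrying one row per metagenome with its
#' GOLD-style ecosystem classification path. The grouping key used
#' throughout the pipeline is `"<category>><type>"` (e.g.
#' `"Environmental>Aquatic"`), following the convention of grouping
#' metagenomes by the first two classification levels.
#'
#' @param path delimited text file with a header row.
#' @param sep field delimiter (default TAB).
#' @param id_col name of the sample-id column.
#' @param path_cols ordered names of the classification-level columns; the
#'   first two (category and type) are mandatory per row, deeper levels may
#'   be missing.
#' @param assembled_bases_col optional column of total assembled bases (bp);
#'   used for gene-abundance normalization. Missing column or `NA` entries
#'   are allowed and propagate as `NA`.
#' @return A `data.frame` of class `sample_metadata` with columns
#'   `sample_id`, the classification levels, `group_key`, `assembled_bases`.
#' @export
load_metadata <- function(path, sep = "\t", id_col = "sample_id",
                          path_cols = c("ecosystem_category", "ecosystem_type",
                                        "ecosystem_subtype", "specific_ecosystem"),
                          assembled_bases_col = "assembled_bases") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_cols <- setdiff(c(id_col, path_cols[1:2]), names(tab))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate sample_id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  if (any(blank(tab[[path_cols[1]]])) || any(blank(tab[[path_cols[2]]])))
    stop("every row needs non-empty '", path_cols[1], "' and '",
         path_cols[2], "'")
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (pc in path_cols)
    out[[pc]] <- if (pc %in% names(tab)) as.character(tab[[pc]]) else NA_character_
  out$group_key <- paste0(out[[path_cols[1]]], ">", out[[path_cols[2]]])
  out$assembled_bases <-
    if (assembled_bases_col %in% names(tab)) {
      ab <- suppressWarnings(as.numeric(tab[[assembled_bases_col]]))
      if (any(!is.na(ab) & ab < 0)) stop("assembled_bases must be nonnegative")
      ab
    } else NA_real_
  attr(out, "path_cols") <- path_cols
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Filter metadata to natural, non-host-restricted ecosystems
#'
#' Removes metagenomes whose top-level ecosystem category is `"Engineered"`
#' or `"Host-associated"`, or whose ecosystem type is `"Nest"` — classes
#' whose tetranucleotide signatures reflect engineering or host constraints
#' rather than environmental physicochemical pressures. Matching is exact
#' and case-sensitive by default since the labels come from a controlled
#' vocabulary. Row order is preserved; the operation is idempotent.
#'
#' @param metadata a `sample_metadata` table from [load_metadata()].
#' @param drop_categories categories to remove (level 1 of the path).
#' @param drop_types types to remove (level 2 of the path).
#' @param ignore_case compare case-insensitively.
#' @return the filtered `sample_metadata` table.
#' @export
filter_metadata <- function(metadata,
                            drop_categories = c("Engineered", "Host-associated"),
                            drop_types = "Nest",
                            ignore_case = FALSE) {
  pc <- attr(metadata, "path_cols") %||%
    c("ecosystem_category", "ecosystem_type")
  cat_v <- metadata[[pc[1]]]
  type_v <- metadata[[pc[2]]]
  if (ignore_case) {
    cat_v <- tolower(cat_v); drop_categories <- tolower(drop_categories)
    type_v <- tolower(type_v); drop_types <- tolower(drop_types)
  }
  keep <- !(cat_v %in% drop_categories) & !(type_v %in% drop_types)
  out <- metadata[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count gene-annotation identifiers in a GFF3 file
#'
#' Counts protein-coding annotation identifiers (COG, KO, Pfam, EC) carried
#' in GFF3 attribute fields, one count per identifier occurrence per feature
#' line. A feature annotated in several namespaces increments each of them;
#' comma-separated multi-valued attributes contribute one count per value.
#' Lines carrying none of the recognized keys are skipped silently.
#'
#' @param path a GFF3 file (attributes in column 9 as `key=value;...`).
#' @param sample_id sample identifier to attach; defaults to the file name
#'   without extension.
#' @param keys character vector of attribute keys to count, named or not.
#'   Defaults to the IMG-style `c("cog", "ko", "pfam", "ec_number")`.
#' @return An object of class `annotation_counts`: list with `sample_id`
#'   and `counts`, a named integer vector over observed identifiers.
#' @export
parse_gff3_annotations <- function(path, sample_id = NULL,
                                   keys = c("cog", "ko", "pfam", "ec_number")) {
  if (!file.exists(path)) stop("no such file: ", path)
  sample_id <- sample_id %||% sub("\\.gff3?(\\.gz)?$", "", basename(path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("cannot read GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  mc <- S4Vectors::mcols(gr)
  vals <- character(0)
  for (key in keys) {
    if (!key %in% names(mc)) next
    v <- mc[[key]]
    v <- if (is(v, "List") || is.list(v)) unlist(v, use.names = FALSE)
         else as.character(v)
    v <- v[!is.na(v) & nzchar(v)]
    vals <- c(vals, v)
  }
  counts <- if (length(vals)) {
    tab <- table(vals)
    setNames(as.integer(tab), names(tab))
  } else integer(0)
  structure(list(sample_id = sample_id, counts = counts),
            class = "annotation_counts")
}
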