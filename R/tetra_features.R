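#' Count canonical tetranucleotides in a set of reads
#'
#' Slides a width-4 window with step 1 over every read, skipping any window
#' that contains a character outside \{A,C,G,T\}, and accumulates counts over
#' the 136 canonical reverse-complement classes. Counting is single-strand:
#' the canonical collapse already makes the reverse strand redundant, so a
#' read and its reverse complement produce identical profiles.
#'
#' Raw 256-mer window counts come from
#' [Biostrings::oligonucleotideFrequency()]; the canonical collapse sums
#' each class's members.
#'
#' @param reads a [Biostrings::DNAStringSet], character vector of sequences,
#'   or a file path accepted by [read_sequences()].
#' @param sample_id identifier to attach to the profile.
#' @param index a `canonical_index`; built on demand.
#' @return An object of class `tetra_profile`: list with `sample_id`,
#'   `counts` (named integer vector over the 136 classes, in class order)
#'   and `total_windows` (= `sum(counts)`).
#' @examples
#' p <- count_tetramers("GATTACA", sample_id = "toy")
#' p$total_windows  # 4 windows
#' @export
count_tetramers <- function(reads, sample_id = "sample",
                            index = build_canonical_index()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  counts <- setNames(integer(length(index$classes)), index$classes)
  if (length(reads)) {
    raw <- Biostrings::oligonucleotideFrequency(reads, width = 4L,
                                                simplify.as = "collapsed")
    # collapse 256 raw 4-mers onto canonical classes
    cls <- index$lookup[names(raw)]
    agg <- vapply(split(raw, cls), sum, numeric(1))
    counts[as.integer(names(agg))] <- as.integer(agg)
    names(counts) <- index$classes
  }
  structure(list(sample_id = sample_id, counts = counts,
                 total_windows = sum(counts)),
            class = "tetra_profile")
}

#' @export
print.tetra_profile <- function(x, ...) {
  cat("Tetranucleotide profile '", x$sample_id, "': ", x$total_windows,
      " windows over ", length(x$counts), " canonical classes\n", sep = "")
  invisible(x)
}

#' Convert a tetranucleotide profile to frequencies
#'
#' Divides each canonical class count by the total number of valid windows.
#' Naturally occurring metagenomes contain every tetranucleotide, but tiny
#' synthetic inputs may not; because downstream pairwise ratios are
#' undefined at zero, the default policy adds 1 to every class count when
#' any class count is zero (reported via a message), preserving the
#' all-classes-present assumption. The `"error"` policy refuses instead.
#'
#' @param profile a `tetra_profile`.
#' @param pseudocount_policy `"add_one"` (default) or `"error"`.
#' @return named numeric vector of 136 frequencies summing to 1.
#' @export
to_frequencies <- function(profile, pseudocount_policy = c("add_one", "error")) {
  pseudocount_policy <- match.arg(pseudocount_policy)
  counts <- profile$counts
  if (profile$total_windows == 0L)
    stop("profile '", profile$sample_id, "' has no valid 4-mer windows")
  if (any(counts == 0L)) {
    if (pseudocount_policy == "error")
      stop("zero count for class(es) ",
           paste(head(names(counts)[counts == 0L], 5L), collapse = ", "),
           " in '", profile$sample_id, "' (pseudocount_policy = \"error\")")
    message("adding pseudocount of 1 to all 136 classes for '",
            profile$sample_id, "' (", sum(counts == 0L), " empty classes)")
    counts <- counts + 1L
  }
  counts / sum(counts)
}

#' Build the 9,316-element tetranucleotide feature vector
#'
#' Emits the 136 canonical frequencies followed by one ratio per unordered
#' pair of classes — the lexicographically earlier class's frequency divided
#' by the later's — for 136 + choose(136, 2) = 9,316 features in total.
#' Feature names are stable: `freq:<class>` then `ratio:<class_i>/<class_j>`
#' with i < j in class order.
#'
#' @param freqs named numeric vector of 136 strictly positive frequencies
#'   (class order of [build_canonical_index()]).
#' @param sample_id identifier attached as an attribute.
#' @param index a `canonical_index`.
#' @return named numeric vector of length 9,316 with attribute `sample_id`.
#' @export
build_feature_vector <- function(freqs, sample_id = "sample",
                                 index = build_canonical_index()) {
  n <- length(index$classes)
  if (length(freqs) != n)
    stop("expected ", n, " frequencies, got ", length(freqs))
  if (!is.null(names(freqs)) && !identical(names(freqs), index$classes))
    stop("frequency names do not match canonical class order")
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("all frequencies must be strictly positive and finite")
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  ratios <- freqs[ut[, 1L]] / freqs[ut[, 2L]]
  out <- c(freqs, ratios)
  names(out) <- c(paste0("freq:", index$classes),
                  paste0("ratio:", index$classes[ut[, 1L]], "/",
                         index$classes[ut[, 2L]]))
  attr(out, "sample_id") <- sample_id
  out
}

#' Feature matrix over a list of profiles
#'
#' Convenience wrapper: frequencies then feature vectors for each profile,
#' assembled into a samples-by-9,316 matrix with sample ids as row names.
#'
#' @param profiles list of `tetra_profile` objects.
#' @param pseudocount_policy passed to [to_frequencies()].
#' @return numeric matrix, rows = samples, columns = the 9,316 features.
#' @export
feature_matrix <- function(profiles, pseudocount_policy = "add_one") {
  idx <- build_canonical_index()
  rows <- lapply(profiles, function(p) {
    fr <- to_frequencies(p, pseudocount_policy)
    build_feature_vector(fr, p$sample_id, idx)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(profiles, `[[`, character(1), "sample_id")
  m
}

#' Write / read a feature matrix as TSV
#'
#' Samples-by-features table with a `sample_id` first column and the 9,316
#' stable feature names as the header.
#'
#' @param m feature matrix from [feature_matrix()].
#' @param path output / input TSV path.
#' @return `read_feature_matrix` returns the numeric matrix.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Write tetranucleotide profiles as a counts TSV
#'
#' @param profiles list of `tetra_profile`.
#' @param path output TSV (sample_id column + 136 class columns).
#' @export
write_profiles <- function(profiles, path) {
  m <- do.call(rbind, lapply(profiles, `[[`, "counts"))
  df <- data.frame(sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
                   m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
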