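# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (per-window loops, full distance sorts) so they share
# no code path with the implementation they check.

# reverse complement via Biostrings (independent of the package's own
# character-level revcomp)
bs_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# per-window canonical tetramer counting by explicit enumeration
oracle_count_tetramers <- function(seqs) {
  idx <- build_canonical_index()
  counts <- setNames(integer(length(idx$classes)), idx$classes)
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) < 4L) next
    for (i in seq_len(nchar(s) - 3L)) {
      w <- substr(s, i, i + 3L)
      if (grepl("[^ACGT]", w)) next
      canon <- min(w, bs_revcomp(w))
      counts[canon] <- counts[canon] + 1L
    }
  }
  counts
}

# raw 256-mer counting then reverse-complement class collapse
oracle_collapse_256 <- function(seqs) {
  idx <- build_canonical_index()
  raw <- setNames(integer(256), names(idx$lookup))
  for (s in seqs) {
    s <- toupper(s)
    if (nchar(s) < 4L) next
    for (i in seq_len(nchar(s) - 3L)) {
      w <- substr(s, i, i + 3L)
      if (!grepl("[^ACGT]", w)) raw[w] <- raw[w] + 1L
    }
  }
  out <- setNames(numeric(length(idx$classes)), idx$classes)
  for (w in names(raw)) {
    cls <- idx$classes[idx$lookup[[w]]]
    out[cls] <- out[cls] + raw[[w]]
  }
  out
}

# exhaustive sort-all-distances KNN with the documented tie rules
oracle_knn <- function(train_xy, labels, q, k) {
  d <- sqrt((train_xy[, 1] - q[1])^2 + (train_xy[, 2] - q[2])^2)
  k <- min(k, length(d))
  sel <- order(d)[seq_len(k)]
  votes <- table(labels[sel])
  cand <- names(votes)[votes == max(votes)]
  if (length(cand) > 1L) {
    sums <- sapply(cand, function(cl) sum(d[sel][labels[sel] == cl]))
    cand <- cand[sums == min(sums)]
    cand <- sort(cand)
  }
  cand[1L]
}

random_reads <- function(n, min_len = 10, max_len = 80, with_n = FALSE) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1L)
    alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    paste(sample(alpha, len, replace = TRUE,
                 prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
          collapse = "")
  }, character(1))
}

write_toy_metadata <- function(path, rows) {
  header <- "sample_id\tecosystem_category\tecosystem_type\tecosystem_subtype\tspecific_ecosystem\tassembled_bases"
  writeLines(c(header, rows), path)
  path
}

# well-separated 2D Gaussian feature clouds embedded in a wider matrix
gaussian_classes <- function(n_per, means, p = 20, sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- length(means)
  X <- matrix(rnorm(n_per * k * p, sd = sd), n_per * k, p)
  labels <- rep(paste0("Environmental>Class", LETTERS[seq_len(k)]),
                each = n_per)
  for (i in seq_len(k)) X[labels == unique(labels)[i], i] <-
      X[labels == unique(labels)[i], i] + means[[i]]
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  list(X = X, labels = labels)
}
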