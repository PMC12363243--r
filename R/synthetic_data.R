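.BASES <- c("A", "C", "G", "T")

.all_trimers <- function() {
  g <- expand.grid(b3 = .BASES, b2 = .BASES, b1 = .BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

.softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

#' Generate synthetic ecosystem sequence models
#'
#' Each ecosystem group is an order-3 Markov chain over \{A,C,G,T\}: a
#' 64 x 4 table of next-base probabilities given the previous trimer.
#' 4-mer frequencies are exactly the sufficient statistics of such a chain,
#' so groups built this way differ in tetranucleotide signature by
#' construction — the synthetic analogue of taxonomically distinct
#' communities. All groups start from one shared base table (logit-space
#' Gaussian, scale `base_scale`); each group then receives independent
#' logit-space perturbations of scale `separation` and is renormalized.
#' `separation = 0` yields identical groups.
#'
#' @param n_groups number of ecosystem groups.
#' @param separation nonnegative scale of between-group divergence.
#' @param seed integer seed; models are fully reproducible from it.
#' @param base_scale logit sd of the shared base table (default 0.5).
#' @param group_keys optional group names; default
#'   `"Environmental>Ecosystem A"`, `"...B"`, ...
#' @param gene_bias optional named list (per group key) of named abundance
#'   multipliers used by [simulate_annotations()].
#' @return list of `ecosystem_model` objects: `group_key`, `transition`
#'   (64 x 4 matrix, rows = trimers, rownames/colnames set), `gene_bias`.
#' @export
make_ecosystem_models <- function(n_groups, separation = 0.8, seed = 1,
                                  base_scale = 0.5, group_keys = NULL,
                                  gene_bias = NULL) {
  stopifnot(n_groups >= 1, separation >= 0)
  if (is.null(group_keys)) {
    tag <- if (n_groups <= 26) LETTERS[seq_len(n_groups)]
           else as.character(seq_len(n_groups))
    group_keys <- paste0("Environmental>Ecosystem ", tag)
  }
  stopifnot(length(group_keys) == n_groups)
  trimers <- .all_trimers()
  with_seed(seed, {
    base <- matrix(rnorm(64L * 4L, sd = base_scale), 64L, 4L,
                   dimnames = list(trimers, .BASES))
    lapply(seq_len(n_groups), function(i) {
      logits <- base + matrix(rnorm(64L * 4L, sd = separation), 64L, 4L)
      structure(list(group_key = group_keys[i],
                     transition = .softmax_rows(logits),
                     gene_bias = gene_bias[[group_keys[i]]]),
                class = "ecosystem_model")
    })
  })
}

#' Define a synthetic metagenome cohort
#'
#' Bundles the ecosystem models with the sampling design. The defaults are
#' the package's standard desk-scale study conditions: 5 ecosystem groups,
#' 40 metagenomes per group, 300 reads of 150 bp each, separation 0.8.
#' `assembled_bases` defaults to `reads_per_sample * read_length` per
#' sample, standing in for an assembly size.
#'
#' @param n_groups,separation,seed,base_scale,group_keys,gene_bias passed
#'   to [make_ecosystem_models()].
#' @param samples_per_group metagenomes per ecosystem group.
#' @param reads_per_sample reads simulated per metagenome.
#' @param read_length read length (bp).
#' @param assembled_bases per-sample assembled bases; default
#'   `reads_per_sample * read_length`.
#' @return object of class `synthetic_cohort`.
#' @export
synthetic_cohort <- function(n_groups = 5, samples_per_group = 40,
                             reads_per_sample = 300, read_length = 150,
                             separation = 0.8, seed = 1, base_scale = 0.5,
                             group_keys = NULL, gene_bias = NULL,
                             assembled_bases = reads_per_sample * read_length) {
  stopifnot(samples_per_group >= 1, reads_per_sample >= 1, read_length >= 4)
  models <- make_ecosystem_models(n_groups, separation, seed, base_scale,
                                  group_keys, gene_bias)
  structure(list(models = models, samples_per_group = samples_per_group,
                 reads_per_sample = reads_per_sample,
                 read_length = read_length, separation = separation,
                 seed = seed, assembled_bases = assembled_bases),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$models), "groups x",
      x$samples_per_group, "samples,", x$reads_per_sample, "reads x",
      x$read_length, "bp, separation", x$separation, ", seed", x$seed, "\n")
  invisible(x)
}

# Vectorized order-3 Markov simulation of n reads of length L.
# States are trimer indices 1..64 in base-4 encoding (A=0..T=3); a uniform
# random trimer seeds each read.
.simulate_chain_reads <- function(transition, n, L) {
  stopifnot(L >= 4)
  cum <- t(apply(transition, 1L, cumsum))
  chars <- matrix("", n, L)
  state <- sample.int(64L, n, replace = TRUE)
  s0 <- state - 1L
  chars[, 1L] <- .BASES[s0 %/% 16L + 1L]
  chars[, 2L] <- .BASES[(s0 %/% 4L) %% 4L + 1L]
  chars[, 3L] <- .BASES[s0 %% 4L + 1L]
  for (pos in 4:L) {
    u <- runif(n)
    cc <- cum[state, , drop = FALSE]
    nb <- 1L + (u > cc[, 1L]) + (u > cc[, 2L]) + (u > cc[, 3L])
    chars[, pos] <- .BASES[nb]
    state <- ((state - 1L) %% 16L) * 4L + nb
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Simulate cohort reads in memory
#'
#' Draws every sample's reads from its group's Markov model. Fully
#' reproducible from the cohort seed; [simulate_reads()] writes the same
#' sequences to FASTA.
#'
#' @param cohort a `synthetic_cohort`.
#' @return list with `reads` (named list of [Biostrings::DNAStringSet],
#'   one per sample) and `metadata` (a `sample_metadata` table whose
#'   category/type levels split the models' group keys).
#' @export
simulate_read_sets <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n_groups <- length(cohort$models)
  sample_ids <- character(0)
  groups <- character(0)
  reads <- list()
  with_seed(cohort$seed + 1L, {
    for (gi in seq_len(n_groups)) {
      model <- cohort$models[[gi]]
      for (si in seq_len(cohort$samples_per_group)) {
        sid <- sprintf("G%02d_S%02d", gi, si)
        seqs <- .simulate_chain_reads(model$transition,
                                      cohort$reads_per_sample,
                                      cohort$read_length)
        dss <- Biostrings::DNAStringSet(seqs)
        names(dss) <- sprintf("%s_read%04d", sid,
                              seq_len(cohort$reads_per_sample))
        reads[[sid]] <- dss
        sample_ids <- c(sample_ids, sid)
        groups <- c(groups, model$group_key)
      }
    }
  })
  lv <- strsplit(groups, ">", fixed = TRUE)
  metadata <- data.frame(
    sample_id = sample_ids,
    ecosystem_category = vapply(lv, `[`, character(1), 1L),
    ecosystem_type = vapply(lv, `[`, character(1), 2L),
    ecosystem_subtype = NA_character_,
    specific_ecosystem = NA_character_,
    group_key = groups,
    assembled_bases = cohort$assembled_bases,
    stringsAsFactors = FALSE)
  attr(metadata, "path_cols") <- c("ecosystem_category", "ecosystem_type",
                                   "ecosystem_subtype", "specific_ecosystem")
  class(metadata) <- c("sample_metadata", "data.frame")
  list(reads = reads, metadata = metadata)
}

#' Write simulated cohort reads and metadata to disk
#'
#' Emits one FASTA per metagenome plus a `metadata.tsv` — exactly the
#' formats [read_sequences()] and [load_metadata()] consume. Byte-identical
#' for identical cohort parameters and seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param gzip write gzip-compressed FASTA.
#' @return list with `dir`, `metadata_path`, `fasta` (named vector of
#'   paths) and the in-memory `metadata`.
#' @export
simulate_reads <- function(cohort, dir, gzip = FALSE) {
  rs <- simulate_read_sets(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fasta.gz" else ".fasta"
  fasta <- setNames(file.path(dir, paste0(names(rs$reads), ext)),
                    names(rs$reads))
  for (sid in names(rs$reads))
    Biostrings::writeXStringSet(rs$reads[[sid]], fasta[[sid]],
                                compress = gzip)
  meta_path <- file.path(dir, "metadata.tsv")
  write.table(rs$metadata, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(dir = dir, metadata_path = meta_path, fasta = fasta,
       metadata = rs$metadata)
}

#' Default synthetic gene panel
#'
#' Fixed panel of gene identifiers across the four namespaces (COG, KO,
#' Pfam, EC) with a common negative-binomial baseline.
#'
#' @param n_per_namespace identifiers per namespace (default 10).
#' @param base_mean baseline mean count per metagenome (default 20).
#' @param dispersion negative-binomial size parameter (default 2;
#'   smaller = more overdispersed).
#' @return data.frame `gene_id`, `namespace`, `attr_key`, `base_mean`,
#'   `dispersion`.
#' @export
default_gene_panel <- function(n_per_namespace = 10, base_mean = 20,
                               dispersion = 2) {
  i <- seq_len(n_per_namespace)
  df <- rbind(
    data.frame(gene_id = sprintf("COG%04d", i), namespace = "cog",
               attr_key = "cog"),
    data.frame(gene_id = sprintf("KO:K%05d", i), namespace = "ko",
               attr_key = "ko"),
    data.frame(gene_id = sprintf("PF%05d", i), namespace = "pfam",
               attr_key = "pfam"),
    data.frame(gene_id = sprintf("EC:1.1.1.%d", i), namespace = "ec",
               attr_key = "ec_number"))
  df$base_mean <- base_mean
  df$dispersion <- dispersion
  df
}

#' Simulate per-metagenome GFF3 annotation files
#'
#' Draws each gene's count per metagenome from a negative binomial with
#' mean `base_mean * multiplier` (the multiplier from the group's
#' `gene_bias`, default 1) and writes one minimal valid GFF3 per annotated
#' metagenome, one feature line per identifier occurrence, with IMG-style
#' attribute keys (`cog`, `ko`, `pfam`, `ec_number`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @param gene_panel panel from [default_gene_panel()].
#' @param seed seed for the count draws; default derived from the cohort
#'   seed.
#' @param annotated_fraction fraction of metagenomes (per group, rounded
#'   up) that receive an annotation file; the rest emulate metagenomes
#'   whose annotations are unavailable. Default 1.
#' @return named vector of GFF3 paths (annotated samples only).
#' @export
simulate_annotations <- function(cohort, dir,
                                 gene_panel = default_gene_panel(),
                                 seed = cohort$seed + 2L,
                                 annotated_fraction = 1) {
  stopifnot(nrow(gene_panel) >= 1, annotated_fraction > 0,
            annotated_fraction <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_groups <- length(cohort$models)
  paths <- character(0)
  with_seed(seed, {
    for (gi in seq_len(n_groups)) {
      model <- cohort$models[[gi]]
      bias <- model$gene_bias
      n_annot <- ceiling(annotated_fraction * cohort$samples_per_group)
      for (si in seq_len(cohort$samples_per_group)) {
        sid <- sprintf("G%02d_S%02d", gi, si)
        mult <- rep(1, nrow(gene_panel))
        if (!is.null(bias)) {
          hit <- match(gene_panel$gene_id, names(bias))
          mult[!is.na(hit)] <- bias[hit[!is.na(hit)]]
        }
        counts <- rnbinom(nrow(gene_panel), size = gene_panel$dispersion,
                          mu = gene_panel$base_mean * mult)
        if (si > n_annot) next  # draws consumed to keep streams aligned
        lines <- c("##gff-version 3")
        pos <- 1L
        for (j in seq_len(nrow(gene_panel))) {
          cj <- counts[j]
          if (cj == 0L) next
          starts <- pos + (seq_len(cj) - 1L) * 1000L
          lines <- c(lines, sprintf(
            "contig1\tsynth\tCDS\t%d\t%d\t.\t+\t0\tID=%s_g%d_%d;%s=%s",
            starts, starts + 899L, sid, j, seq_len(cj),
            gene_panel$attr_key[j], gene_panel$gene_id[j]))
          pos <- max(starts) + 1000L
        }
        p <- file.path(dir, paste0(sid, ".gff3"))
        writeLines(lines, p)
        paths[sid] <- p
      }
    }
  })
  paths
}

#' Stationary canonical 4-mer distribution of an ecosystem model
#'
#' Closed-form oracle for what [count_tetramers()] should converge to on
#' reads from the model: the stationary distribution \eqn{\pi} of the
#' trimer chain (by power iteration on the 64 x 64 transition operator)
#' gives each raw 4-mer probability \eqn{\pi(abc) P(d | abc)}, which is
#' then collapsed onto the 136 canonical classes.
#'
#' @param model an `ecosystem_model`.
#' @param index a `canonical_index`.
#' @return named numeric vector of 136 canonical frequencies (sums to 1).
#' @export
stationary_tetramer_freqs <- function(model, index = build_canonical_index()) {
  trimers <- rownames(model$transition)
  n <- length(trimers)
  Tm <- matrix(0, n, n, dimnames = list(trimers, trimers))
  for (s in seq_len(n)) {
    nxt <- ((s - 1L) %% 16L) * 4L + 1:4
    Tm[s, nxt] <- model$transition[s, ]
  }
  pi_v <- rep(1 / n, n)
  for (it in seq_len(10000L)) {
    nv <- as.vector(pi_v %*% Tm)
    nv <- nv / sum(nv)
    if (sum(abs(nv - pi_v)) < 1e-14) { pi_v <- nv; break }
    pi_v <- nv
  }
  p4 <- as.vector(t(model$transition * pi_v))
  names(p4) <- paste0(rep(trimers, each = 4L), .BASES)
  p4 <- p4[order(names(p4))]
  canon <- vapply(split(p4, index$lookup[names(p4)]), sum, numeric(1))
  out <- setNames(numeric(length(index$classes)), index$classes)
  out[as.integer(names(canon))] <- canon
  names(out) <- index$classes
  out / sum(out)
}

#' Feature matrix and labels for a synthetic cohort
#'
#' End-to-end in-memory convenience: simulate reads, count canonical
#' tetranucleotides, and assemble the 9,316-feature matrix.
#'
#' @param cohort a `synthetic_cohort`.
#' @param pseudocount_policy passed to [to_frequencies()].
#' @return list with `features` (samples x 9,316 matrix), `labels`
#'   (group keys) and `metadata`.
#' @export
cohort_features <- function(cohort, pseudocount_policy = "add_one") {
  rs <- simulate_read_sets(cohort)
  idx <- build_canonical_index()
  profiles <- lapply(names(rs$reads), function(sid)
    count_tetramers(rs$reads[[sid]], sid, idx))
  feats <- suppressMessages(feature_matrix(profiles, pseudocount_policy))
  list(features = feats,
       labels = setNames(rs$metadata$group_key,
                         rs$metadata$sample_id)[rownames(feats)],
       metadata = rs$metadata)
}
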