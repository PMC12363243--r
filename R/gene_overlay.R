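#' Normalize an annotation count per billion assembled bases
#'
#' `raw_count / assembled_bases * 1e9`: the "Map Value" scale used to
#' overlay gene abundances on the stability diagram. Vectorized.
#'
#' @param raw_count nonnegative count(s).
#' @param assembled_bases positive total assembled bases (bp).
#' @return normalized abundance (counts per 10^9 assembled bases).
#' @examples
#' normalize_abundance(2, 5e8)  # 4
#' @export
normalize_abundance <- function(raw_count, assembled_bases) {
  if (any(is.na(assembled_bases)) || any(assembled_bases <= 0))
    stop("assembled_bases must be positive")
  if (any(raw_count < 0)) stop("raw_count must be nonnegative")
  raw_count / assembled_bases * 1e9
}

#' Build the per-metagenome gene abundance table
#'
#' Assembles annotation counts from many metagenomes into one matrix of
#' normalized abundances (per 10^9 assembled bases) over the union of
#' observed gene identifiers. A metagenome present in the metadata but
#' lacking an annotation file gets a row of `NA` — missing, never zero:
#' absence of a file is an availability fact, while a zero says the
#' identifier was truly not counted in an annotated metagenome.
#'
#' @param annotations list of `annotation_counts`
#'   (from [parse_gff3_annotations()]).
#' @param metadata `sample_metadata` with `assembled_bases` for every
#'   annotated sample.
#' @return numeric matrix of class `gene_abundance_table`; rows = all
#'   metadata samples, columns = sorted gene identifiers, `NA` rows for
#'   unannotated samples.
#' @export
build_abundance_table <- function(annotations, metadata) {
  ids <- vapply(annotations, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id among annotations: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  unknown <- setdiff(ids, metadata$sample_id)
  if (length(unknown))
    stop("annotated sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  genes <- sort(unique(unlist(lapply(annotations,
                                     function(a) names(a$counts)))))
  m <- matrix(NA_real_, nrow = nrow(metadata), ncol = length(genes),
              dimnames = list(metadata$sample_id, genes))
  ab <- setNames(metadata$assembled_bases, metadata$sample_id)
  for (a in annotations) {
    if (is.na(ab[[a$sample_id]]))
      stop("annotated sample '", a$sample_id, "' has no assembled_bases")
    row <- setNames(numeric(length(genes)), genes)  # annotated => zeros
    row[names(a$counts)] <- a$counts
    m[a$sample_id, ] <- normalize_abundance(row, ab[[a$sample_id]])
  }
  structure(m, class = c("gene_abundance_table", class(m)))
}

.star_tag <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
    ifelse(p <= 0.05, "*", "ns")))
}

#' Welch's ANOVA with Games-Howell post hoc comparisons
#'
#' Heteroscedastic one-way comparison of a gene's normalized abundance
#' between ecosystem groups: Welch's ANOVA (Welch-Satterthwaite degrees of
#' freedom, via [stats::oneway.test()]) for the omnibus test, then the
#' Games-Howell procedure for every unordered pair of groups. For groups i
#' and j with means \eqn{m}, variances \eqn{s^2} and sizes \eqn{n}, the
#' Games-Howell statistic is
#' \eqn{t = |m_i - m_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}} with
#' Welch-Satterthwaite degrees of freedom, and its p-value is taken from
#' the studentized-range distribution with the total number of groups,
#' \eqn{p = P(q \ge t\sqrt{2})} ([stats::ptukey()], computed numerically).
#' Pairwise significance tags: `*` p <= 0.05, `**` p <= 0.01,
#' `***` p <= 0.001, else `ns`.
#'
#' @param values named list of numeric vectors, one per group; names are
#'   the group keys. `NA`s are dropped per group.
#' @return An object of class `group_comparison`: list with `groups`,
#'   `n`, `welch_F`, `welch_p`, and `pairwise` — a data.frame
#'   (`group1`, `group2`, `diff`, `t`, `df`, `p`, `star`) covering all
#'   unordered pairs.
#' @export
welch_games_howell <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("'values' must be a named list of groups")
  values <- lapply(values, function(v) v[!is.na(v)])
  ns <- vapply(values, length, integer(1))
  vs <- vapply(values, function(v) if (length(v) > 1) var(v) else NA_real_,
               numeric(1))
  bad <- ns < 2 | is.na(vs) | vs == 0
  if (any(bad))
    stop("degenerate group(s) (n < 2 or zero variance): ",
         paste(names(values)[bad], collapse = ", "))
  if (length(values) < 2L) stop("need at least 2 groups")
  groups <- names(values)
  ms <- vapply(values, mean, numeric(1))

  long <- data.frame(v = unlist(values, use.names = FALSE),
                     g = factor(rep(groups, ns), levels = groups))
  ow <- oneway.test(v ~ g, data = long, var.equal = FALSE)

  pairs <- utils::combn(groups, 2L)
  k <- length(groups)
  pw <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    sei2 <- vs[[i]] / ns[[i]]; sej2 <- vs[[j]] / ns[[j]]
    se <- sqrt(sei2 + sej2)
    tval <- abs(ms[[i]] - ms[[j]]) / se
    df <- (sei2 + sej2)^2 / (sei2^2 / (ns[[i]] - 1) + sej2^2 / (ns[[j]] - 1))
    p <- ptukey(tval * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    c(diff = ms[[i]] - ms[[j]], t = tval, df = df, p = p)
  })
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         t(pw), stringsAsFactors = FALSE)
  pairwise$star <- .star_tag(pairwise$p)
  structure(list(groups = groups, n = ns,
                 welch_F = unname(ow$statistic),
                 welch_p = unname(ow$p.value),
                 pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F = %.4g, p = %.4g (%d groups)\n",
              x$welch_F, x$welch_p, length(x$groups)))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Welch two-sample two-tailed t-test
#'
#' Unequal-variance two-sided comparison (via [stats::t.test()]) with the
#' same significance tags as the pairwise panels.
#'
#' @param values_a,values_b numeric vectors, `NA`s dropped, each n >= 2.
#' @return list with `t`, `p`, `star`, `df`.
#' @export
two_tailed_t <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("both samples need n >= 2")
  tt <- t.test(values_a, values_b, var.equal = FALSE,
               alternative = "two.sided")
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       star = .star_tag(tt$p.value), df = unname(tt$parameter))
}

#' Group comparison of one gene's abundance
#'
#' Splits a gene's normalized abundances by ecosystem group (missing
#' values excluded listwise) and runs [welch_games_howell()].
#'
#' @param table a `gene_abundance_table`.
#' @param gene_id column to test.
#' @param groups named character vector mapping `sample_id` to group key
#'   (or a `sample_metadata` table).
#' @return a `group_comparison`.
#' @export
compare_gene_groups <- function(table, gene_id, groups) {
  if (inherits(groups, "sample_metadata"))
    groups <- setNames(groups$group_key, groups$sample_id)
  if (!gene_id %in% colnames(table)) stop("unknown gene_id: ", gene_id)
  v <- table[, gene_id]
  g <- groups[rownames(table)]
  keep <- !is.na(v) & !is.na(g)
  welch_games_howell(split(v[keep], g[keep]))
}

#' Map gene abundances to overlay colour positions
#'
#' Linear mapping of one gene's normalized abundance onto [0, 1] colormap
#' positions (clipped at the range ends). Metagenomes with missing
#' abundance are flagged `hidden` and given no position, mirroring the
#' NaN-hiding behaviour of the diagram overlay. An optional `midpoint`
#' rescales the map piecewise-linearly so that abundance `midpoint` lands
#' at position 0.5 — the "Heat"-style adjustment for genes with skewed
#' count ranges.
#'
#' @param table a `gene_abundance_table`.
#' @param gene_id column to overlay.
#' @param range optional `c(min, max)` colormap range; default the observed
#'   finite range of the gene.
#' @param midpoint optional abundance mapped to colour position 0.5.
#' @return data.frame `sample_id`, `abundance`, `position`, `hidden`.
#' @export
overlay_values <- function(table, gene_id, range = NULL, midpoint = NULL) {
  if (!gene_id %in% colnames(table)) stop("unknown gene_id: ", gene_id)
  v <- table[, gene_id]
  pres <- v[!is.na(v)]
  if (is.null(range)) {
    range <- if (length(pres)) base::range(pres) else c(0, 1)
    if (range[1L] == range[2L]) range <- range + c(-0.5, 0.5)
  }
  if (range[2L] <= range[1L]) stop("range must satisfy min < max")
  pos <- pmin(1, pmax(0, (v - range[1L]) / (range[2L] - range[1L])))
  if (!is.null(midpoint)) {
    mp <- pmin(1, pmax(0, (midpoint - range[1L]) / (range[2L] - range[1L])))
    if (mp > 0 && mp < 1)
      pos <- ifelse(pos <= mp, 0.5 * pos / mp,
                    0.5 + 0.5 * (pos - mp) / (1 - mp))
  }
  data.frame(sample_id = rownames(table), abundance = v, position = pos,
             hidden = is.na(v), stringsAsFactors = FALSE)
}

#' Write a gene abundance table as TSV
#'
#' @param table a `gene_abundance_table`.
#' @param path output TSV; missing values written as `NA`.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
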