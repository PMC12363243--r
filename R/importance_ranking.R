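# Shared forest fit: stratified split, impurity importances, held-out
# accuracy. Missing abundances are imputed as 0 for the model only (the
# forest needs complete inputs; missingness reflects annotation-file
# availability, not biology) — recorded in the returned metadata.
.fit_forest <- function(x, y, seed, train_fraction, num_trees, ...) {
  x[is.na(x)] <- 0
  tr <- stratified_split(as.character(y), train_fraction, seed)
  te <- setdiff(seq_along(y), tr)
  rf <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                       num.trees = num_trees, importance = "impurity",
                       seed = seed, num.threads = 1L, ...)
  pred <- predict(rf, data = x[te, , drop = FALSE],
                  num.threads = 1L)$predictions
  list(importance = rf$variable.importance,
       accuracy = mean(pred == y[te]))
}

.sorted_entries <- function(imp) {
  # descending importance, exact ties broken by gene id
  ord <- order(-imp, names(imp))
  data.frame(gene_id = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Rank gene annotations by random-forest importance
#'
#' Trains a random forest (via \pkg{ranger}) of gene-abundance features
#' against ecosystem group labels on a stratified 75%/25% train/test split
#' and returns gene identifiers ordered by mean decrease in impurity
#' (normalized to sum to 1), with the held-out accuracy alongside.
#'
#' @param table a `gene_abundance_table` (missing values are imputed as 0
#'   for the model input only).
#' @param labels group keys, one per table row (or a named vector over
#'   sample ids).
#' @param seed integer seed (split and forest).
#' @param train_fraction training fraction (default 0.75).
#' @param num_trees forest size (default 500).
#' @param ... further arguments to [ranger::ranger()].
#' @return An object of class `importance_list`: list with
#'   `scope = "overall"`, `entries` (data.frame `gene_id`, `importance`,
#'   sorted descending), `accuracy`, `split`.
#' @export
rank_importances <- function(table, labels, seed = 1, train_fraction = 0.75,
                             num_trees = 500, ...) {
  x <- unclass(as.matrix(table))
  if (!is.null(names(labels))) labels <- labels[rownames(x)]
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  fit <- .fit_forest(x, y, seed, train_fraction, num_trees, ...)
  imp <- fit$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(scope = "overall", entries = .sorted_entries(imp),
                 accuracy = fit$accuracy,
                 split = c(train_fraction = train_fraction, seed = seed)),
            class = "importance_list")
}

#' Per-ecosystem gene importance with abundance/sparsity direction
#'
#' One-vs-rest random forests, one per ecosystem group, each ranking the
#' genes that most distinguish that group from everything else. Every entry
#' carries a direction tag: `"abundance"` when the group's mean abundance
#' for the gene exceeds the mean over all other samples, `"sparsity"` when
#' the gene is depleted in the group. Direction is computed on the same
#' zero-imputed values the model sees and is invariant to uniform positive
#' rescaling of the table.
#'
#' @inheritParams rank_importances
#' @return named list of `importance_list` objects (scope
#'   `per_class:<group_key>`), entries carrying a `direction` column.
#' @export
per_class_rankings <- function(table, labels, seed = 1, train_fraction = 0.75,
                               num_trees = 500, ...) {
  x <- unclass(as.matrix(table))
  if (!is.null(names(labels))) labels <- labels[rownames(x)]
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  xz <- x; xz[is.na(xz)] <- 0
  out <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, cl, ".rest"), levels = c(".rest", cl))
    fit <- .fit_forest(x, y, seed, train_fraction, num_trees, ...)
    entries <- .sorted_entries(fit$importance)
    in_mean <- colMeans(xz[labels == cl, , drop = FALSE])
    out_mean <- colMeans(xz[labels != cl, , drop = FALSE])
    entries$direction <- ifelse(in_mean[entries$gene_id] >
                                  out_mean[entries$gene_id],
                                "abundance", "sparsity")
    structure(list(scope = paste0("per_class:", cl), entries = entries,
                   accuracy = fit$accuracy,
                   split = c(train_fraction = train_fraction, seed = seed)),
              class = "importance_list")
  })
  names(out) <- classes
  out
}

#' @export
print.importance_list <- function(x, n = 10, ...) {
  cat("Gene importance [", x$scope, "] held-out accuracy ",
      sprintf("%.3f", x$accuracy), "\n", sep = "")
  print(head(x$entries, n), row.names = FALSE)
  invisible(x)
}

#' Write importance rankings as TSV
#'
#' @param rankings an `importance_list` or a list of them.
#' @param path output TSV (`scope`, `rank`, `gene_id`, `importance`,
#'   `direction` where present); held-out accuracies go in `#` header
#'   comments.
#' @export
write_importances <- function(rankings, path) {
  if (inherits(rankings, "importance_list")) rankings <- list(rankings)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in rankings)
    writeLines(sprintf("# %s heldout_accuracy=%.6f", r$scope, r$accuracy),
               con)
  rows <- do.call(rbind, lapply(rankings, function(r) {
    e <- r$entries
    if (!"direction" %in% names(e)) e$direction <- NA_character_
    data.frame(scope = r$scope, rank = seq_len(nrow(e)), e,
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  suppressWarnings(write.table(rows, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
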