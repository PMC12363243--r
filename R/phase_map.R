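# Majority vote among the k nearest training points, with deterministic
# tie-breaking: (1) most votes; (2) among tied classes, smallest summed
# distance from the query to that class's voters; (3) lexicographically
# smallest group key. k is clamped to the number of training points.
.knn_vote_one <- function(d, labels, k) {
  k <- min(k, length(d))
  sel <- order(d)[seq_len(k)]
  votes <- table(labels[sel])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    dsel <- sqrt(d[sel])  # d holds squared distances; sum plain distances
    sums <- vapply(top, function(cl) sum(dsel[labels[sel] == cl]),
                   numeric(1))
    top <- top[sums == min(sums)]
    if (length(top) > 1L) top <- sort(top)[1L]
  }
  top
}

.knn_classify <- function(train_xy, labels, query_xy, k) {
  dx <- outer(query_xy[, 1L], train_xy[, 1L], `-`)
  dy <- outer(query_xy[, 2L], train_xy[, 2L], `-`)
  D <- dx * dx + dy * dy                      # squared Euclidean, rank-equal
  vapply(seq_len(nrow(D)), function(i) .knn_vote_one(D[i, ], labels, k),
         character(1))
}

#' Classify diagram coordinates by k-nearest metagenomes
#'
#' Assigns an ecosystem group to arbitrary (x, y) positions in the
#' stability diagram by majority vote among the `k` nearest metagenomes in
#' Euclidean coordinate distance (uniform votes). Vote ties are broken by
#' the smallest summed distance to the tied classes' voters, then by
#' lexicographic group key; `k` larger than the number of metagenomes is
#' clamped.
#'
#' @param coords a `stability_diagram` or its `coords` data.frame
#'   (`sample_id`, `x`, `y`, `group_key`).
#' @param query_xy numeric matrix (or length-2 vector) of query coordinates.
#' @param k number of neighbours (diagram default 500, chosen for
#'   >10,000-metagenome collections; scale down with smaller data).
#' @return character vector of group keys, one per query row.
#' @export
classify_point <- function(coords, query_xy, k = 500) {
  coords <- .as_coords(coords)
  if (!nrow(coords)) stop("empty training coordinate set")
  if (k < 1L) stop("k must be >= 1")
  if (is.null(dim(query_xy))) query_xy <- matrix(query_xy, ncol = 2L)
  .knn_classify(as.matrix(coords[, c("x", "y")]), coords$group_key,
                as.matrix(query_xy), k)
}

.as_coords <- function(coords) {
  if (inherits(coords, "stability_diagram")) coords$coords else coords
}

#' Build the KNN ecosystem phase grid
#'
#' Lays a regular grid of cells over the coordinate bounding box (expanded
#' by `margin` on each side) and labels every cell centre with the KNN
#' ecosystem classification of [classify_point()]. The labelled grid is the
#' background "phase" layer of the stability diagram: contiguous regions of
#' one label mark where that ecosystem's tetranucleotide signature is
#' locally dominant.
#'
#' @param coords a `stability_diagram` or coordinates data.frame.
#' @param k neighbours per vote (default 500; clamped to the sample count).
#' @param resolution cells per axis (default 200).
#' @param margin fractional bounding-box expansion per side (default 0.05).
#' @return An object of class `phase_grid`: list with `x_edges`, `y_edges`,
#'   `cells` (data.frame `x`, `y`, `label` over all cell centres), `k`,
#'   `resolution`.
#' @export
build_phase_grid <- function(coords, k = 500, resolution = 200,
                             margin = 0.05) {
  coords <- .as_coords(coords)
  if (!nrow(coords)) stop("empty coordinate set")
  if (resolution < 2L) stop("resolution must be >= 2")
  rng_x <- range(coords$x); rng_y <- range(coords$y)
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1L]), 1)     # degenerate axis: symmetric pad
    r + c(-1, 1) * margin * w
  }
  rng_x <- pad(rng_x); rng_y <- pad(rng_y)
  x_edges <- seq(rng_x[1L], rng_x[2L], length.out = resolution + 1L)
  y_edges <- seq(rng_y[1L], rng_y[2L], length.out = resolution + 1L)
  xc <- (x_edges[-1L] + x_edges[-length(x_edges)]) / 2
  yc <- (y_edges[-1L] + y_edges[-length(y_edges)]) / 2
  cells <- expand.grid(x = xc, y = yc, KEEP.OUT.ATTRS = FALSE)
  train_xy <- as.matrix(coords[, c("x", "y")])
  # classify in blocks to bound the distance-matrix memory
  block <- 4000L
  lab <- character(nrow(cells))
  for (start in seq(1L, nrow(cells), by = block)) {
    ii <- start:min(start + block - 1L, nrow(cells))
    lab[ii] <- .knn_classify(train_xy, coords$group_key,
                             as.matrix(cells[ii, , drop = FALSE]), k)
  }
  cells$label <- lab
  structure(list(x_edges = x_edges, y_edges = y_edges, cells = cells,
                 k = k, resolution = resolution),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat("KNN phase grid:", x$resolution, "x", x$resolution, "cells, k =",
      x$k, "-", length(unique(x$cells$label)), "phases\n")
  invisible(x)
}

#' Phase concordance of each metagenome
#'
#' Classifies every metagenome at its own diagram coordinates (not its
#' containing grid cell) and compares the KNN ecosystem phase with the
#' declared ecosystem label. Discordant metagenomes sit inside another
#' ecosystem's phase: their tetranucleotide composition more closely
#' resembles that ecosystem than their own classification.
#'
#' @param coords a `stability_diagram` or coordinates data.frame.
#' @param grid optional `phase_grid`; supplies `k` when given.
#' @param k neighbours per vote when `grid` is absent.
#' @return data.frame with `sample_id`, `knn_label`, `gold_label`,
#'   `concordant`.
#' @export
assign_phases <- function(coords, grid = NULL, k = if (!is.null(grid)) grid$k else 500) {
  coords <- .as_coords(coords)
  knn_label <- classify_point(coords, as.matrix(coords[, c("x", "y")]), k)
  data.frame(sample_id = coords$sample_id,
             knn_label = knn_label,
             gold_label = coords$group_key,
             concordant = knn_label == coords$group_key,
             stringsAsFactors = FALSE)
}

#' Write a phase grid as TSV
#'
#' @param grid a `phase_grid`.
#' @param path output TSV (cell centre `x`, `y`, `label`).
#' @export
write_phase_grid <- function(grid, path) {
  write.table(grid$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
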