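#' Fit the supervised discriminant projection of a stability diagram
#'
#' Linear discriminant analysis of the tetranucleotide feature matrix
#' against ecosystem group labels, returning the first two discriminant
#' axes as diagram coordinates. With 9,316 features and (typically) far
#' fewer samples the within-class scatter is singular, so the solver works
#' in the span of the centred data: a thin SVD reduces the problem to at
#' most n - 1 dimensions, where the generalized eigenproblem
#' \eqn{S_B w = \lambda (S_W + \epsilon I) w} is solved with a small ridge
#' on the within-class scatter (`shrink` times its mean diagonal). Axis
#' signs are fixed so that the lexicographically first class has a
#' nonnegative mean coordinate on every axis, making outputs reproducible.
#'
#' The fitted model classifies by nearest class centroid in the
#' within-class-whitened discriminant space (all `n_classes - 1` axes),
#' adjusted by log class priors (proportional to training class sizes).
#'
#' @param features numeric matrix, samples x features, with sample ids as
#'   row names and stable feature names as column names.
#' @param labels character vector of group keys, one per sample.
#' @param shrink ridge weight on the within-class scatter, as a fraction of
#'   its mean diagonal element. Default `1e-3`.
#' @return An object of class `stability_diagram`: list with
#'   \describe{
#'     \item{coords}{data.frame `sample_id`, `x`, `y`, `group_key`.}
#'     \item{model}{the fitted projection (class `stability_lda`).}
#'   }
#' @export
fit_lda <- function(features, labels, shrink = 1e-3) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least 2 distinct labels, got ", length(classes))
  sizes <- table(factor(labels, levels = classes))
  if (any(sizes < 2L))
    stop("every class needs >= 2 samples; too small: ",
         paste(classes[sizes < 2L], collapse = ", "))

  n <- nrow(features)
  center <- colMeans(features)
  xc <- sweep(features, 2L, center)
  sv <- svd(xc, nu = min(n, ncol(features)), nv = min(n, ncol(features)))
  keep <- sv$d > max(sv$d) * 1e-9
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]          # p x r basis of the data span
  Z <- xc %*% V                             # n x r scores (= U d)
  r <- ncol(Z)

  # scatter decomposition in the reduced space
  cls_means <- rowsum(Z, labels) / as.vector(sizes[rownames(rowsum(Z, labels))])
  cls_means <- cls_means[classes, , drop = FALSE]
  Sw <- matrix(0, r, r)
  for (cl in classes) {
    zi <- sweep(Z[labels == cl, , drop = FALSE], 2L, cls_means[cl, ])
    Sw <- Sw + crossprod(zi)
  }
  Sb <- crossprod(sweep(cls_means, 1L, sqrt(as.vector(sizes)), `*`))
  lambda <- shrink * mean(diag(Sw)) + 1e-12
  Swr <- Sw + diag(lambda, r)

  L <- chol(Swr)                            # Swr = t(L) %*% L
  M <- backsolve(L, t(backsolve(L, Sb, transpose = TRUE)), transpose = TRUE)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(length(classes) - 1L, r)
  Wz <- backsolve(L, eg$vectors[, seq_len(n_axes), drop = FALSE])
  # normalize so the discriminant space is within-class whitened
  wn <- sqrt(colSums((Swr %*% Wz) * Wz))
  Wz <- sweep(Wz, 2L, wn, `/`) * sqrt(max(n - length(classes), 1L))

  scaling <- V %*% Wz                       # p x n_axes, original space
  disc <- Z %*% Wz                          # n x n_axes training coordinates

  # sign convention: first class (lexicographic) has nonnegative mean
  first_means <- colMeans(disc[labels == classes[1L], , drop = FALSE])
  flip <- ifelse(first_means < 0, -1, 1)
  scaling <- sweep(scaling, 2L, flip, `*`)
  disc <- sweep(disc, 2L, flip, `*`)

  centroids <- rowsum(disc, labels) / as.vector(sizes[classes])
  model <- structure(
    list(center = center, scaling = scaling,
         feature_names = colnames(features),
         classes = classes, centroids = centroids,
         priors = as.vector(sizes) / n, n_axes = n_axes,
         eigenvalues = eg$values[seq_len(n_axes)], shrink = shrink),
    class = "stability_lda")

  xy <- .axes_to_xy(disc)
  coords <- data.frame(sample_id = rownames(features) %||%
                         paste0("s", seq_len(n)),
                       x = xy[, 1L], y = xy[, 2L],
                       group_key = labels, stringsAsFactors = FALSE)
  structure(list(coords = coords, model = model), class = "stability_diagram")
}

.axes_to_xy <- function(disc) {
  if (ncol(disc) >= 2L) disc[, 1:2, drop = FALSE]
  else cbind(disc[, 1L], 0)  # 2-class fit has a single discriminant axis
}

#' @export
print.stability_diagram <- function(x, ...) {
  cat("Metagenome stability diagram:", nrow(x$coords), "samples,",
      length(x$model$classes), "ecosystem groups\n")
  invisible(x)
}

#' Project feature vectors onto fitted discriminant axes
#'
#' Applies the fitted linear map to new samples. Re-projecting the training
#' matrix reproduces the training coordinates exactly.
#'
#' @param model a `stability_lda` (from `fit_lda(...)$model`).
#' @param features matrix with the same named feature columns as training.
#' @return matrix of coordinates (columns `x`, `y`).
#' @export
project <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$center))
    stop("feature dimension mismatch: model has ", length(model$center),
         ", input has ", ncol(features))
  if (!is.null(colnames(features)) && !is.null(model$feature_names) &&
      !identical(colnames(features), model$feature_names))
    stop("feature names/order differ from the training matrix")
  disc <- sweep(features, 2L, model$center) %*% model$scaling
  xy <- .axes_to_xy(disc)
  colnames(xy) <- c("x", "y")
  rownames(xy) <- rownames(features)
  xy
}

# full-discriminant-space class prediction (nearest whitened centroid with
# log-prior adjustment)
predict_lda <- function(model, features) {
  features <- as.matrix(features)
  disc <- sweep(features, 2L, model$center) %*% model$scaling
  d2 <- outer(rowSums(disc^2), rowSums(model$centroids^2), `+`) -
    2 * disc %*% t(model$centroids)
  score <- sweep(d2, 2L, 2 * log(model$priors), `-`)
  model$classes[max.col(-score, ties.method = "first")]
}

#' Held-out evaluation of the discriminant classifier
#'
#' Stratified train/test split, fit on the training part, predict the test
#' part, and report accuracy plus class-weighted precision and F1 (weights
#' are the test-set class supports; classes never predicted contribute
#' precision 0).
#'
#' @param features samples x features matrix.
#' @param labels group keys.
#' @param train_fraction fraction of each class used for training
#'   (default 0.8).
#' @param seed integer seed controlling the split.
#' @param shrink passed to [fit_lda()].
#' @return An object of class `split_metrics`: list with `accuracy`,
#'   `precision`, `f1`, `split` (train_fraction, seed), `n_test`,
#'   `confusion` (test-set confusion table).
#' @export
evaluate_split <- function(features, labels, train_fraction = 0.8, seed = 1,
                           shrink = 1e-3) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("cannot stratify; class(es) with < 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  tr <- stratified_split(labels, train_fraction, seed)
  te <- setdiff(seq_along(labels), tr)
  fit <- fit_lda(features[tr, , drop = FALSE], labels[tr], shrink = shrink)
  pred <- predict_lda(fit$model, features[te, , drop = FALSE])
  truth <- labels[te]

  lev <- sort(unique(c(truth, pred)))
  conf <- table(factor(truth, lev), factor(pred, lev))
  support <- rowSums(conf)
  tp <- diag(conf)
  prec_c <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support / sum(support)
  structure(list(accuracy = sum(tp) / sum(conf),
                 precision = sum(w * prec_c),
                 f1 = sum(w * f1_c),
                 split = c(train_fraction = train_fraction, seed = seed),
                 n_test = length(te), confusion = conf),
            class = "split_metrics")
}

#' @export
print.split_metrics <- function(x, ...) {
  cat(sprintf(
    "Held-out split (train %.0f%%, seed %d, n_test %d):\n  accuracy %.3f  weighted precision %.3f  weighted F1 %.3f\n",
    100 * x$split[["train_fraction"]], x$split[["seed"]], x$n_test,
    x$accuracy, x$precision, x$f1))
  invisible(x)
}

#' Write diagram coordinates as TSV
#'
#' @param diagram a `stability_diagram`.
#' @param path output TSV (`sample_id`, `x`, `y`, `group_key`).
#' @export
write_coordinates <- function(diagram, path) {
  write.table(diagram$coords, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
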