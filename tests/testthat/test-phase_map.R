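make_coords <- function(xy, labels) {
  data.frame(sample_id = paste0("s", seq_len(nrow(xy))),
             x = xy[, 1], y = xy[, 2], group_key = labels,
             stringsAsFactors = FALSE)
}

test_that("classify_point matches the exhaustive distance-sort oracle", {
  set.seed(21)
  n <- 180
  xy <- cbind(rnorm(n), rnorm(n))
  labels <- sample(paste0("Environmental>E", 1:4), n, replace = TRUE)
  coords <- make_coords(xy, labels)
  queries <- cbind(runif(60, -2, 2), runif(60, -2, 2))
  for (k in c(1, 3, 17)) {
    got <- classify_point(coords, queries, k)
    want <- apply(queries, 1, function(q) oracle_knn(xy, labels, q, k))
    expect_identical(got, unname(want))
  }
})

test_that("vote ties break by summed distance then lexicographic key", {
  # two equidistant points, distinct classes, equal summed distances
  coords <- make_coords(rbind(c(-1, 0), c(1, 0)),
                        c("Environmental>Zeta", "Environmental>Alpha"))
  expect_equal(classify_point(coords, c(0, 0), k = 2),
               "Environmental>Alpha")
  # unequal summed distances: the summed-distance rule precedes the
  # lexicographic one (Zeta: 1.0 + 1.2 = 2.2 beats Alpha: 0.5 + 2.0 = 2.5)
  coords2 <- make_coords(rbind(c(-1, 0), c(-1.2, 0), c(0.5, 0), c(2, 0)),
                         rep(c("Environmental>Zeta", "Environmental>Alpha"),
                             each = 2))
  expect_equal(classify_point(coords2, c(0, 0), k = 4),
               "Environmental>Zeta")
  # query at a training point inside a pure neighbourhood
  expect_equal(classify_point(coords2, c(-1, 0), k = 2),
               "Environmental>Zeta")
  expect_error(classify_point(coords[0, ], c(0, 0), k = 1), "empty")
  expect_error(classify_point(coords, c(0, 0), k = 0), "k must be")
})

test_that("k clamps to the number of samples", {
  set.seed(3)
  xy <- cbind(rnorm(30), rnorm(30))
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"), 10)
  coords <- make_coords(xy, labels)
  q <- cbind(runif(10, -1, 1), runif(10, -1, 1))
  expect_identical(classify_point(coords, q, k = 500),
                   classify_point(coords, q, k = 30))
})

test_that("phase grid covers the padded bounding box with voted labels", {
  set.seed(5)
  a <- cbind(rnorm(40, -5, 0.5), rnorm(40, 0, 0.5))
  b <- cbind(rnorm(40, 5, 0.5), rnorm(40, 0, 0.5))
  coords <- make_coords(rbind(a, b),
                        rep(c("Environmental>Left", "Environmental>Right"),
                            each = 40))
  g <- build_phase_grid(coords, k = 1, resolution = 24)
  expect_s3_class(g, "phase_grid")
  expect_equal(nrow(g$cells), 24^2)
  # with k = 1 each cell is labeled by its nearest point's class
  want <- apply(as.matrix(g$cells[, c("x", "y")]), 1, function(q)
    oracle_knn(rbind(a, b), coords$group_key, q, 1))
  expect_identical(g$cells$label, unname(want))
  # the two phases split along the midline
  expect_true(all(g$cells$label[g$cells$x < -1] == "Environmental>Left"))
  expect_true(all(g$cells$label[g$cells$x > 1] == "Environmental>Right"))
  # margin expands the box by 5% per side
  expect_lt(min(g$x_edges), min(coords$x))
  expect_gt(max(g$x_edges), max(coords$x))
  expect_error(build_phase_grid(coords, resolution = 1), "resolution")

  # single-class data: every cell carries that class
  g1 <- build_phase_grid(make_coords(a, rep("Environmental>Only", 40)),
                         k = 7, resolution = 8)
  expect_true(all(g1$cells$label == "Environmental>Only"))
})

test_that("phase labels are equivariant under class renaming", {
  set.seed(9)
  xy <- cbind(rnorm(60), rnorm(60))
  labels <- sample(c("Environmental>A", "Environmental>B"), 60, replace = TRUE)
  coords <- make_coords(xy, labels)
  g <- build_phase_grid(coords, k = 5, resolution = 10)
  ren <- c("Environmental>A" = "Environmental>X",
           "Environmental>B" = "Environmental>Y")
  coords2 <- coords; coords2$group_key <- unname(ren[coords$group_key])
  g2 <- build_phase_grid(coords2, k = 5, resolution = 10)
  expect_identical(g2$cells$label, unname(ren[g$cells$label]))
})

test_that("assign_phases reports concordance against the declared label", {
  set.seed(13)
  a <- cbind(rnorm(25, -6, 0.4), rnorm(25, 0, 0.4))
  b <- cbind(rnorm(25, 6, 0.4), rnorm(25, 0, 0.4))
  coords <- make_coords(rbind(a, b),
                        rep(c("Environmental>A", "Environmental>B"), each = 25))
  ph <- assign_phases(coords, k = 5)
  expect_true(all(ph$concordant))
  expect_identical(ph$concordant, ph$knn_label == ph$gold_label)

  # relocate one sample into the heart of the other cluster -> discordant
  coords$x[1] <- 6; coords$y[1] <- 0
  ph2 <- assign_phases(coords, k = 5)
  expect_false(ph2$concordant[1])
  expect_equal(ph2$knn_label[1], "Environmental>B")
  expect_equal(sum(ph2$concordant), nrow(coords) - sum(!ph2$concordant))

  # a class can lose all its grid cells while its members sit in another
  # phase (small-scale analogue of an ecosystem with no stable region)
  tiny <- make_coords(rbind(a, c(0.1, 0.1)),
                      c(rep("Environmental>A", 25), "Environmental>Rare"))
  gt <- build_phase_grid(tiny, k = 3, resolution = 10)
  expect_false("Environmental>Rare" %in% gt$cells$label)
  expect_true(all(gt$cells$label %in% tiny$group_key))
})
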