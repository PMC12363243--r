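# abundance-like matrix with a planted perfectly informative feature
planted_table <- function(n_per = 12, n_noise = 30, seed = 1, lift = 8) {
  set.seed(seed)
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"),
                each = n_per)
  n <- length(labels)
  m <- matrix(rpois(n * n_noise, 20), n, n_noise,
              dimnames = list(paste0("s", 1:n),
                              sprintf("NOISE%03d", 1:n_noise)))
  signal <- rpois(n, 20) + ifelse(labels == "Environmental>A", lift * 20, 0)
  m <- cbind(m, SIGNAL1 = signal, CONST1 = 5)
  structure(m, class = c("gene_abundance_table", "matrix", "array"))
}

test_that("rank_importances finds a planted signal and is seed-deterministic", {
  tab <- planted_table(seed = 3)
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"),
                each = 12)
  r1 <- rank_importances(tab, labels, seed = 42, num_trees = 300)
  expect_s3_class(r1, "importance_list")
  expect_equal(r1$entries$gene_id[1], "SIGNAL1")
  # impurity importances are normalized and sorted
  expect_lte(sum(r1$entries$importance), 1 + 1e-9)
  expect_true(all(diff(r1$entries$importance) <= 0))
  # a constant feature carries no importance
  expect_equal(r1$entries$importance[r1$entries$gene_id == "CONST1"], 0)
  # determinism given the seed
  r2 <- rank_importances(tab, labels, seed = 42, num_trees = 300)
  expect_identical(r1$entries, r2$entries)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_error(rank_importances(tab, rep("one", nrow(tab))), "2 classes")
})

test_that("rankings are stable under column permutation", {
  tab <- planted_table(seed = 5)
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"),
                each = 12)
  r1 <- rank_importances(tab, labels, seed = 7, num_trees = 200)
  perm <- sample(ncol(tab))
  tabp <- structure(unclass(tab)[, perm],
                    class = c("gene_abundance_table", "matrix", "array"))
  r2 <- rank_importances(tabp, labels, seed = 7, num_trees = 200)
  s1 <- setNames(r1$entries$importance, r1$entries$gene_id)
  s2 <- setNames(r2$entries$importance, r2$entries$gene_id)
  expect_equal(s2[names(s1)], s1, tolerance = 0.05)
  expect_equal(r1$entries$gene_id[1], r2$entries$gene_id[1])
})

test_that("per-class rankings tag abundance vs sparsity correctly", {
  set.seed(9)
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"),
                each = 12)
  n <- length(labels)
  m <- matrix(rpois(n * 25, 20), n, 25,
              dimnames = list(paste0("s", 1:n), sprintf("NOISE%03d", 1:25)))
  up_in_a <- rpois(n, 20) + ifelse(labels == "Environmental>A", 160, 0)
  down_in_b <- ifelse(labels == "Environmental>B", rpois(n, 1), rpois(n, 60))
  tab <- structure(cbind(m, UPGENE = up_in_a, DOWNGENE = down_in_b),
                   class = c("gene_abundance_table", "matrix", "array"))
  rk <- per_class_rankings(tab, labels, seed = 11, num_trees = 300)
  expect_named(rk, sort(unique(labels)))
  ea <- rk[["Environmental>A"]]$entries
  expect_equal(ea$gene_id[1], "UPGENE")
  expect_equal(ea$direction[ea$gene_id == "UPGENE"], "abundance")
  eb <- rk[["Environmental>B"]]$entries
  expect_equal(eb$gene_id[1], "DOWNGENE")
  expect_equal(eb$direction[eb$gene_id == "DOWNGENE"], "sparsity")
  # held-out accuracy on planted one-vs-rest signal is high
  expect_gte(rk[["Environmental>A"]]$accuracy, 0.9)
  # direction tags are invariant to uniform positive rescaling
  rk2 <- per_class_rankings(structure(unclass(tab) * 1000,
                                      class = class(tab)),
                            labels, seed = 11, num_trees = 300)
  for (cl in names(rk))
    expect_identical(
      setNames(rk[[cl]]$entries$direction, rk[[cl]]$entries$gene_id),
      setNames(rk2[[cl]]$entries$direction, rk2[[cl]]$entries$gene_id))
})

test_that("missing abundances are imputed as zero only for the model", {
  tab <- planted_table(seed = 13)
  tab[3, "NOISE001"] <- NA
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"),
                each = 12)
  r <- rank_importances(tab, labels, seed = 1, num_trees = 100)
  expect_equal(r$entries$gene_id[1], "SIGNAL1")
  expect_true(is.na(tab[3, "NOISE001"]))  # input untouched
})

test_that("importance TSV export carries scopes, ranks and accuracies", {
  tab <- planted_table(seed = 17, n_per = 8, n_noise = 10)
  labels <- rep(c("Environmental>A", "Environmental>B", "Environmental>C"),
                each = 8)
  rk <- c(list(overall = rank_importances(tab, labels, seed = 2,
                                          num_trees = 100)),
          per_class_rankings(tab, labels, seed = 2, num_trees = 100))
  path <- tempfile(fileext = ".tsv")
  write_importances(rk, path)
  raw <- readLines(path)
  expect_equal(sum(startsWith(raw, "#")), 4L)
  body <- read.delim(text = raw[!startsWith(raw, "#")])
  expect_setequal(unique(body$scope),
                  c("overall", paste0("per_class:", sort(unique(labels)))))
  expect_equal(body$rank[body$scope == "overall"], seq_len(ncol(tab)))
})
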