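# Reference values for the fixed fixture below were computed with an
# independent implementation of Welch's ANOVA, Games-Howell and the Welch
# t-test (pingouin 0.6.1) and frozen here.
gh_fix <- list(
  a = c(10.1, 9.8, 10.5, 11.0, 9.6),
  b = c(12.3, 13.1, 11.8, 12.9, 13.5, 12.0),
  c = c(9.0, 8.5, 9.9, 8.8))
gh_ref <- list(
  welch_F = 37.76933593688999, welch_p = 0.00012394844370143554,
  pairs = data.frame(
    group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
    t = c(6.468399624683104, 2.932058391957, 8.726284218029),
    df = c(8.993670068466608, 6.323262937049094, 7.086274821690105),
    p = c(0.0003053383181629288, 0.0561981622306138, 0.0001235124091119033)))
t_ref <- list(t = -6.468399624683104, p = 0.0001159944630388532)

test_that("normalization is exact arithmetic per 1e9 assembled bases", {
  expect_identical(normalize_abundance(5, 1e9), 5)
  expect_identical(normalize_abundance(2, 5e8), 4)
  expect_identical(normalize_abundance(0, 1e9), 0)
  # joint scaling of counts and bases leaves abundance unchanged
  expect_equal(normalize_abundance(7 * 13, 3e8 * 13),
               normalize_abundance(7, 3e8))
  expect_error(normalize_abundance(1, 0), "positive")
  expect_error(normalize_abundance(-1, 10), "nonnegative")
})

test_that("abundance table distinguishes zero from missing", {
  md <- load_metadata(write_toy_metadata(tempfile(), c(
    "s1\tEnvironmental\tAquatic\t\t\t1000000000",
    "s2\tEnvironmental\tAquatic\t\t\t500000000",
    "s3\tEnvironmental\tTerrestrial\t\t\t1000000000")))
  ann <- list(
    structure(list(sample_id = "s1", counts = c(COG0001 = 4L)),
              class = "annotation_counts"),
    structure(list(sample_id = "s2", counts = c(KO1 = 2L)),
              class = "annotation_counts"))
  tab <- build_abundance_table(ann, md)
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(tab["s1", "COG0001"], 4)       # 4 / 1e9 * 1e9
  expect_equal(tab["s2", "KO1"], 4)           # 2 / 5e8 * 1e9
  expect_equal(tab["s1", "KO1"], 0)           # annotated, identifier absent
  expect_true(all(is.na(tab["s3", ])))        # no annotation file: missing

  # identical counts with half the assembled bases double the abundance
  ann2 <- list(
    structure(list(sample_id = "s1", counts = c(G = 6L)),
              class = "annotation_counts"),
    structure(list(sample_id = "s2", counts = c(G = 6L)),
              class = "annotation_counts"))
  tab2 <- build_abundance_table(ann2, md)
  expect_equal(tab2["s2", "G"], 2 * tab2["s1", "G"])

  # no annotations at all: empty table, no error
  tab0 <- build_abundance_table(list(), md)
  expect_equal(dim(tab0), c(3L, 0L))

  md$assembled_bases[1] <- NA
  expect_error(build_abundance_table(ann, md), "s1")
})

test_that("Welch ANOVA and Games-Howell match the frozen reference", {
  gc <- welch_games_howell(gh_fix)
  expect_equal(gc$welch_F, gh_ref$welch_F, tolerance = 1e-9)
  expect_equal(gc$welch_p, gh_ref$welch_p, tolerance = 1e-9)
  pw <- gc$pairwise[order(gc$pairwise$group1, gc$pairwise$group2), ]
  expect_equal(pw$t, gh_ref$pairs$t, tolerance = 1e-6)
  expect_equal(pw$df, gh_ref$pairs$df, tolerance = 1e-6)
  expect_equal(pw$p, gh_ref$pairs$p, tolerance = 1e-6)
  expect_equal(pw$star, c("***", "ns", "***"))

  # identical groups: F = 0, p = 1
  same <- welch_games_howell(list(u = c(1, 2, 3), v = c(1, 2, 3)))
  expect_equal(same$welch_F, 0)
  expect_equal(same$welch_p, 1)

  # far-separated groups: every pair maximally significant
  set.seed(2)
  far <- welch_games_howell(list(lo = rnorm(20), hi = rnorm(20, 10)))
  expect_equal(far$pairwise$star, "***")

  expect_error(welch_games_howell(list(a = 1, b = c(1, 2))), "degenerate")
  expect_error(welch_games_howell(list(a = c(2, 2, 2), b = c(1, 2))),
               "degenerate")
  expect_error(welch_games_howell(list(c(1, 2), c(3, 4))), "named")
})

test_that("Games-Howell p-values are shift- and relabel-invariant; F = t^2 for 2 groups", {
  set.seed(31)
  vals <- list(g1 = rnorm(8), g2 = rnorm(10, 1), g3 = rnorm(7, 2, 2))
  gc <- welch_games_howell(vals)
  shifted <- welch_games_howell(lapply(vals, `+`, 100))
  expect_equal(gc$pairwise$p, shifted$pairwise$p, tolerance = 1e-9)
  ren <- welch_games_howell(setNames(vals, c("x1", "x2", "x3")))
  expect_equal(sort(gc$pairwise$p), sort(ren$pairwise$p), tolerance = 1e-12)

  for (i in 1:5) {
    a <- rnorm(6 + i); b <- rnorm(9, 0.5)
    two <- welch_games_howell(list(a = a, b = b))
    tt <- two_tailed_t(a, b)
    expect_equal(two$welch_F, tt$t^2, tolerance = 1e-9)
  }
})

test_that("two-tailed t matches the reference and is antisymmetric", {
  tt <- two_tailed_t(gh_fix$a, gh_fix$b)
  expect_equal(tt$t, t_ref$t, tolerance = 1e-10)
  expect_equal(tt$p, t_ref$p, tolerance = 1e-10)
  expect_equal(tt$star, "***")

  swap <- two_tailed_t(gh_fix$b, gh_fix$a)
  expect_equal(swap$t, -tt$t, tolerance = 1e-12)
  expect_equal(swap$p, tt$p, tolerance = 1e-12)

  ident <- two_tailed_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(two_tailed_t(1, c(1, 2)), "n >= 2")
})

test_that("overlay positions map linearly, clip, hide missing, honour midpoint", {
  tab <- structure(matrix(c(0, 5, 10, NA), 4, 1,
                          dimnames = list(paste0("s", 1:4), "G1")),
                   class = c("gene_abundance_table", "matrix", "array"))
  ov <- overlay_values(tab, "G1")
  expect_equal(ov$position[1:3], c(0, 0.5, 1))      # endpoints exact
  expect_true(ov$hidden[4] && is.na(ov$abundance[4]))
  # clipping outside an explicit range
  ov2 <- overlay_values(tab, "G1", range = c(2, 8))
  expect_equal(ov2$position[c(1, 3)], c(0, 1))
  # all-equal abundances land at one position
  tabe <- structure(matrix(3, 3, 1, dimnames = list(paste0("s", 1:3), "G")),
                    class = c("gene_abundance_table", "matrix", "array"))
  expect_length(unique(overlay_values(tabe, "G")$position), 1L)
  # midpoint rescales its abundance to colour position 0.5
  ov3 <- overlay_values(tab, "G1", midpoint = 2.5)
  expect_equal(ov3$position[2], 0.5 + 0.5 * (0.5 - 0.25) / 0.75)
  expect_equal(overlay_values(tab, "G1", midpoint = 5)$position[2], 0.5)
  expect_error(overlay_values(tab, "nope"), "unknown gene_id")
})

test_that("compare_gene_groups excludes missing values listwise", {
  md <- load_metadata(write_toy_metadata(tempfile(), sprintf(
    "s%d\tEnvironmental\t%s\t\t\t1000000000",
    1:12, rep(c("Aquatic", "Terrestrial"), each = 6))))
  set.seed(4)
  ann <- lapply(1:11, function(i) structure(
    list(sample_id = paste0("s", i),
         counts = c(G1 = rpois(1, if (i <= 6) 50 else 200))),
    class = "annotation_counts"))  # s12 missing
  tab <- build_abundance_table(ann, md)
  gc <- compare_gene_groups(tab, "G1", md)
  expect_equal(sort(unname(gc$n)), c(5L, 6L))  # listwise exclusion of s12
  expect_lt(gc$welch_p, 0.01)
})
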