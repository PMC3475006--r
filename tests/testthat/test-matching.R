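# The chromosome-14 worked example: one ~71 kb gene and 25 oligo probes,
# 10 of which fall inside the gene.
example <- example_annotations()

test_that("distance matching picks the probe whose midpoint is nearest", {
  map <- match_distance(example$cn, example$ge)
  expect_identical(nrow(map), 1L)
  expect_identical(example$cn$start[map$cn_index], 38609230)
  expect_identical(map$weight, 1)
  # a single probe on the chromosome is matched by every gene there
  one <- data.frame(feature_id = "solo", chromosome = "14",
                    start = 1, end = 100)
  map1 <- match_distance(one, example$ge)
  expect_identical(map1$cn_id, "solo")
})

test_that("distanceAny keeps probes strictly within the window, weights 1/(d+offset)", {
  m10 <- match_distance_any(example$cn, example$ge, window = 1e4)
  expect_setequal(example$cn$start[m10$cn_index],
                  c(38597108, 38602277, 38609230, 38614898))
  m100 <- match_distance_any(example$cn, example$ge, window = 1e5)
  expect_identical(sort(m100$cn_id), sort(example$cn$feature_id))
  expect_equal(sum(m100$weight), 1)
  # raw weight at zero distance with offset 1 is 1 before normalization
  g <- data.frame(feature_id = "g", chromosome = "1", start = 100, end = 200)
  cn <- data.frame(feature_id = c("at", "far"), chromosome = "1",
                   start = c(100, 1000), end = c(200, 1100))
  m <- match_distance_any(cn, g, window = 1e4, offset = 1)
  w <- m$weight[m$cn_id == "at"]
  expect_equal(w, 1 / (1 + 1 / 901))  # 1/(0+1) vs 1/(900+1), normalized
  expect_error(match_distance_any(cn, g, window = 0), "window")
  expect_error(match_distance_any(cn, g, window = 10, offset = 0), "offset")
})

test_that("overlap matching maximizes the fraction with leftmost tie-break", {
  map <- match_overlap(example$cn, example$ge)
  # ten probes are fully contained (all tied at fraction 1); leftmost wins
  expect_identical(example$cn$start[map$cn_index], 38571564)
  # disjoint platforms yield an empty map, reported as unmatched
  other <- transform(example$ge, chromosome = "2")
  empty <- match_overlap(example$cn, other)
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(unmatched_report(empty)), 1L)
})

test_that("overlapAny includes all probes above the threshold, weights by fraction", {
  map <- match_overlap_any(example$cn, example$ge)
  starts <- sort(example$cn$start[map$cn_index])
  expect_identical(length(starts), 10L)
  expect_identical(range(starts), c(38571564, 38639169))
  expect_equal(sum(map$weight), 1)
  # single probe fully inside the gene: weight 1
  solo <- example$cn[example$cn$feature_id == "p05", ]
  msolo <- match_overlap_any(solo, example$ge)
  expect_identical(msolo$weight, 1)
  expect_error(match_overlap_any(example$cn, example$ge, min_fraction = 1),
               "min_fraction")
})

test_that("overlapPlus equals overlap when the gene already overlaps a probe", {
  set.seed(3)
  cn_set <- random_cn_set(example$cn)
  plus <- match_overlap_plus(cn_set, example$ge)
  base <- match_overlap(example$cn, example$ge)
  expect_identical(map_as_list(plus), map_as_list(base))
})

test_that("overlapPlus interpolates only across breakpoint-free flanks", {
  cn_ann <- data.frame(feature_id = c("L", "U"), chromosome = "1",
                       start = c(100, 901), end = c(200, 1001))
  gene <- data.frame(feature_id = "g", chromosome = "1",
                     start = 320, end = 380)  # overlaps neither
  flat <- matrix(c(0.3, 0.3, -0.1, -0.1), 2, 2,
                 dimnames = list(c("L", "U"), c("s1", "s2")))
  cn_flat <- copy_number_set(cn_ann, flat, flat, sign(flat))
  m <- match_overlap_plus(cn_flat, gene)
  expect_identical(m$cn_id, "L")  # nearer flank (gene midpoint 350)
  expect_identical(m$weight, 1)
  # one sample with a breakpoint between the flanks blocks interpolation
  broken <- flat
  broken["U", "s2"] <- 0.8
  cn_broken <- copy_number_set(cn_ann, broken, broken, sign(broken))
  m2 <- match_overlap_plus(cn_broken, gene)
  expect_identical(nrow(m2), 0L)
  expect_match(unmatched_report(m2)$reason, "breakpoint")
  # a gene with only one flank (chromosome end) stays unmatched
  lonely <- data.frame(feature_id = "g2", chromosome = "1",
                       start = 2000, end = 2100)
  m3 <- match_overlap_plus(cn_flat, lonely)
  expect_identical(nrow(m3), 0L)
  expect_match(unmatched_report(m3)$reason, "flank")
  expect_error(match_overlap_plus(cn_ann, gene), "cn_set")
})

test_that("label matching joins platforms through common descriptors", {
  # one-to-one map
  m <- match_label("x", "A", c(x = "GS1"), c(A = "GS1"))
  expect_identical(m$cn_id, "x")
  expect_identical(m$weight, 1)
  # two CN features sharing the descriptor: uniform weights
  m2 <- match_label(c("x", "y"), "A", c(x = "GS1", y = "GS1"),
                    c(A = "GS1"))
  expect_setequal(m2$cn_id, c("x", "y"))
  expect_equal(m2$weight, c(0.5, 0.5))
  # disjoint descriptors: unmatched, not an error
  m3 <- match_label("x", "A", c(x = "GS2"), c(A = "GS1"))
  expect_identical(nrow(m3), 0L)
  expect_identical(unmatched_report(m3)$gene_id, "A")
  # empty maps give an empty map
  m4 <- match_label("x", "A", NULL, NULL)
  expect_identical(nrow(m4), 0L)
  # strict chromosome filtering drops cross-chromosome pairs
  cn_ann <- data.frame(feature_id = "x", chromosome = "2",
                       start = 1, end = 10)
  ge_ann <- data.frame(feature_id = "A", chromosome = "1",
                       start = 1, end = 10)
  m5 <- match_label("x", "A", c(x = "GS1"), c(A = "GS1"),
                    cn_annotation = cn_ann, ge_annotation = ge_ann,
                    strict_chromosome = TRUE)
  expect_identical(nrow(m5), 0L)
})

test_that("procedures agree with exhaustive oracles on random instances", {
  set.seed(101)
  for (i in 1:30) {
    cn_ann <- random_annotation(sample(10:60, 1), "c", max_len = 2e4)
    ge_ann <- random_annotation(sample(3:15, 1), "g")
    cn_set <- random_cn_set(cn_ann)
    expect_map_matches_oracle(match_distance(cn_ann, ge_ann),
                              oracle_distance(cn_ann, ge_ann))
    w <- sample(c(1e4, 1e5), 1)
    expect_map_matches_oracle(match_distance_any(cn_ann, ge_ann, window = w),
                              oracle_distance_any(cn_ann, ge_ann, window = w))
    expect_map_matches_oracle(match_overlap(cn_ann, ge_ann),
                              oracle_overlap(cn_ann, ge_ann))
    expect_map_matches_oracle(match_overlap_any(cn_ann, ge_ann),
                              oracle_overlap_any(cn_ann, ge_ann))
    expect_map_matches_oracle(match_overlap_plus(cn_set, ge_ann),
                              oracle_overlap_plus(cn_set, ge_ann))
  }
})

test_that("label matching agrees with an enumeration oracle", {
  set.seed(55)
  for (i in 1:20) {
    cn_ids <- sprintf("c%02d", 1:20)
    ge_ids <- sprintf("g%02d", 1:8)
    cn_map <- data.frame(id = sample(cn_ids, 25, replace = TRUE),
                         common = sample(sprintf("GS%d", 1:6), 25,
                                         replace = TRUE))
    ge_map <- data.frame(id = sample(ge_ids, 10, replace = TRUE),
                         common = sample(sprintf("GS%d", 1:6), 10,
                                         replace = TRUE))
    got <- match_label(cn_ids, ge_ids, cn_map, ge_map)
    expect_map_matches_oracle(got, oracle_label(cn_ids, ge_ids,
                                                cn_map, ge_map))
  }
})

test_that("results are invariant under row permutation of either input", {
  set.seed(19)
  cn_ann <- random_annotation(40, "c")
  ge_ann <- random_annotation(12, "g")
  ref <- list(
    map_as_list(match_distance(cn_ann, ge_ann)),
    map_as_list(match_distance_any(cn_ann, ge_ann, window = 1e5)),
    map_as_list(match_overlap_any(cn_ann, ge_ann))
  )
  for (i in 1:5) {
    cn_p <- cn_ann[sample.int(nrow(cn_ann)), ]
    ge_p <- ge_ann[sample.int(nrow(ge_ann)), ]
    expect_identical(map_as_list(match_distance(cn_p, ge_p)), ref[[1]])
    expect_identical(
      map_as_list(match_distance_any(cn_p, ge_p, window = 1e5)), ref[[2]])
    expect_identical(map_as_list(match_overlap_any(cn_p, ge_p)), ref[[3]])
  }
})

test_that("distance matching reaches every gene whose chromosome has a probe", {
  set.seed(23)
  for (i in 1:10) {
    cn_ann <- random_annotation(30, "c", n_chrom = 2)
    ge_ann <- random_annotation(15, "g", n_chrom = 2)
    map <- match_distance(cn_ann, ge_ann)
    covered <- ge_ann$chromosome %in% cn_ann$chromosome
    expect_setequal(matched_genes(map), ge_ann$feature_id[covered])
  }
})

test_that("far matches are flagged in the distance report", {
  cn <- data.frame(feature_id = "p", chromosome = "1",
                   start = 5e6, end = 5e6 + 59)
  ge <- data.frame(feature_id = "g", chromosome = "1", start = 1, end = 100)
  map <- match_distance(cn, ge, warn_distance = 1e6)
  far <- attr(map, "far_matches")
  expect_identical(far$gene_id, "g")
  expect_gt(far$distance, 1e6)
})
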