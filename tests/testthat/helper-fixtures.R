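# Programmatic fixtures shared across the suite. Callers control the RNG
# with set.seed(); nothing here seeds on its own.

# Random annotation table; rows are deliberately shuffled so tests also
# exercise canonicalization. Features may overlap one another.
random_annotation <- function(n, prefix, n_chrom = 2, region = 1e6,
                              min_len = 20, max_len = 5e4) {
  chrom <- as.character(sample.int(n_chrom, n, replace = TRUE))
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  start <- sample.int(region, n, replace = TRUE)
  ann <- data.frame(feature_id = sprintf("%s%04d", prefix, seq_len(n)),
                    chromosome = chrom, start = start, end = start + len - 1)
  ann[sample.int(n), , drop = FALSE]
}

# cn_set over a random annotation; segmented values are drawn from a small
# set of levels so consecutive features sometimes agree (no breakpoint)
# and sometimes do not.
random_cn_set <- function(ann, n_samples = 4,
                          levels = c(-0.7, 0, 0, 0.58)) {
  n <- nrow(ann)
  seg <- matrix(sample(levels, n * n_samples, replace = TRUE), n, n_samples)
  rownames(seg) <- ann$feature_id
  norm <- seg + matrix(rnorm(n * n_samples, 0, 0.2), n, n_samples)
  rownames(norm) <- ann$feature_id
  calls <- sign(seg)
  copy_number_set(ann, norm, seg, calls)
}

# Map a match_map to a comparable canonical form: per gene, matched CN ids
# and weights sorted by cn_id.
map_as_list <- function(map) {
  if (!nrow(map)) return(list())
  out <- lapply(split(seq_len(nrow(map)), map$gene_id), function(i) {
    d <- data.frame(cn_id = map$cn_id[i], weight = map$weight[i])
    d[order(d$cn_id), , drop = FALSE]
  })
  out[order(names(out))]
}

expect_map_matches_oracle <- function(map, oracle, tol = 1e-12) {
  got <- map_as_list(map)
  if (!length(oracle)) {
    expect_identical(length(got), 0L)
    return(invisible())
  }
  oracle <- oracle[order(names(oracle))]
  expect_identical(names(got), names(oracle))
  for (g in names(oracle)) {
    expect_identical(got[[g]]$cn_id, oracle[[g]]$cn_id,
                     info = paste("gene", g))
    expect_equal(got[[g]]$weight, oracle[[g]]$weight, tolerance = tol,
                 info = paste("gene", g))
  }
}
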