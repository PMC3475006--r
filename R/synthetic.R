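#' Configuration for the paired-platform simulator
#'
#' Collects and validates the parameters of [simulate_platforms()]. The
#' defaults describe a desk-scale oligo aCGH experiment paired with an
#' expression array: two 100 Mb chromosomes carrying 2000 short (~60 bp)
#' copy number probes laid out non-overlapping along the genome, ten copy
#' number segments per chromosome with log2-ratio levels typical of
#' tumour data (single-copy loss -0.7, normal 0, gain 0.58, amplification
#' 1.3), measurement noise of sd 0.2 on the normalized values, 500 genes
#' of which 30% carry a cis-effect of slope 0.8 on their local segmented
#' dosage, and 30 samples. Setting \code{cn_probe_length} to ~150000
#' emulates a legacy BAC platform whose probes are long compared to the
#' genes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_cn_features total number of copy number probes (split evenly
#'   over chromosomes).
#' @param cn_probe_length,cn_probe_length_sd mean and sd of probe length
#'   in bp (~60 oligo-like, ~150000 BAC-like).
#' @param n_ge_features number of expression features.
#' @param gene_length_mean,gene_length_sd mean and sd of gene length in bp
#'   (lengths truncated below at 200 bp).
#' @param n_samples number of samples.
#' @param n_segments copy number segments per chromosome.
#' @param segment_means log2-ratio level of each call state
#'   (loss, normal, gain, amplification).
#' @param segment_probs probability of each state per segment and sample.
#' @param noise_sd sd of the Gaussian noise added to segmented values to
#'   form the normalized data.
#' @param call_thresholds named thresholds (loss, gain, amp) applied to
#'   segmented values to produce calls on the \{-1, 0, 1, 2\} scale
#'   (-2 is reserved but unused by default).
#' @param cis_fraction fraction of genes whose expression depends on their
#'   dosage.
#' @param beta expression slope on the segmented dosage for cis genes.
#' @param expr_noise_sd sd of expression noise.
#' @param expr_baseline_mean,expr_baseline_sd per-gene expression
#'   baseline distribution.
#' @param genes_mirror_probes if \code{TRUE}, gene intervals coincide
#'   exactly with the probe intervals (one gene per probe), a layout in
#'   which every coordinate-based procedure must recover the true probe.
#' @param seed integer seed; identical seeds give identical output.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 1e8,
                       n_cn_features = 2000,
                       cn_probe_length = 60,
                       cn_probe_length_sd = cn_probe_length / 20,
                       n_ge_features = 500,
                       gene_length_mean = 30000,
                       gene_length_sd = 20000,
                       n_samples = 30,
                       n_segments = 10,
                       segment_means = c(loss = -0.7, normal = 0,
                                         gain = 0.58, amp = 1.3),
                       segment_probs = c(loss = 0.1, normal = 0.7,
                                         gain = 0.15, amp = 0.05),
                       noise_sd = 0.2,
                       call_thresholds = c(loss = -0.35, gain = 0.29,
                                           amp = 0.9),
                       cis_fraction = 0.3,
                       beta = 0.8,
                       expr_noise_sd = 0.5,
                       expr_baseline_mean = 7,
                       expr_baseline_sd = 1,
                       genes_mirror_probes = FALSE,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_cn_features = n_cn_features, n_ge_features = n_ge_features,
              n_samples = n_samples, n_segments = n_segments)
  bad <- counts <= 0
  if (any(bad)) {
    stop("configuration counts must be positive: ",
         paste(names(counts)[bad], collapse = ", "))
  }
  if (cis_fraction < 0 || cis_fraction > 1) {
    stop("cis_fraction must lie in [0, 1]")
  }
  if (length(segment_means) != length(segment_probs)) {
    stop("segment_means and segment_probs must have equal length")
  }
  probes_per_chrom <- ceiling(n_cn_features / n_chromosomes)
  if (chrom_length / probes_per_chrom < 2 * cn_probe_length) {
    stop("infeasible layout: ", probes_per_chrom, " probes of ~",
         cn_probe_length, " bp do not fit non-overlapping in a ",
         chrom_length, " bp chromosome")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired copy number / expression data set
#'
#' Generates the data structures the matching procedures assume:
#' non-overlapping copy number probes sorted along each chromosome;
#' piecewise-constant segmented profiles whose breakpoints sit at segment
#' borders; normalized values equal to segmented plus Gaussian noise;
#' calls obtained by thresholding; genes placed over the same genome; and
#' expression equal to a per-gene baseline plus, for cis genes,
#' \code{beta} times the segmented dosage at the gene's locus, plus noise.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements \code{cn} (a \code{cn_set}), \code{ge} (a
#'   \code{ge_set}) and \code{truth}: a data.frame (\code{gene_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{cis}), plus
#'   attributes \code{overlap} (named list of truly overlapping probe IDs
#'   per gene) and \code{dosage} (the true gene-level segmented matrix).
#' @export
simulate_platforms <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)
  n_chr <- cfg$n_chromosomes
  chroms <- as.character(seq_len(n_chr))
  per_chrom <- diff(round(seq(0, cfg$n_cn_features, length.out = n_chr + 1)))
  samples <- sprintf("s%02d", seq_len(cfg$n_samples))

  probe <- list()
  seg_lookup <- list()   # per chromosome: cut points + state values
  for (c in seq_len(n_chr)) {
    m <- per_chrom[c]
    slot <- floor(cfg$chrom_length / m)
    len <- round(stats::rnorm(m, cfg$cn_probe_length, cfg$cn_probe_length_sd))
    len <- pmin(pmax(len, 1), slot - 1)
    start <- (seq_len(m) - 1) * slot + 1 +
      floor(stats::runif(m) * (slot - len))
    probe[[c]] <- data.frame(
      feature_id = "",  # assigned after assembly
      chromosome = chroms[c], start = start, end = start + len - 1)
    cuts <- if (cfg$n_segments > 1)
      sort(stats::runif(cfg$n_segments - 1, 1, cfg$chrom_length)) else numeric()
    states <- matrix(
      sample(seq_along(cfg$segment_means), cfg$n_segments * cfg$n_samples,
             replace = TRUE, prob = cfg$segment_probs),
      nrow = cfg$n_segments)
    seg_lookup[[c]] <- list(
      cuts = cuts,
      values = matrix(cfg$segment_means[states], nrow = cfg$n_segments))
  }
  cn_ann <- do.call(rbind, probe)
  cn_ann$feature_id <- sprintf("cn%05d", seq_len(nrow(cn_ann)))

  dosage_at <- function(chrom_idx, pos) {
    lk <- seg_lookup[[chrom_idx]]
    lk$values[findInterval(pos, lk$cuts) + 1, , drop = FALSE]
  }
  chrom_idx <- match(cn_ann$chromosome, chroms)
  segmented <- dosage_at_rows(dosage_at, chrom_idx, feature_midpoint(cn_ann))
  normalized <- segmented +
    matrix(stats::rnorm(length(segmented), 0, cfg$noise_sd),
           nrow = nrow(segmented))
  calls <- call_states(segmented, cfg$call_thresholds)
  dimnames(segmented) <- dimnames(normalized) <- dimnames(calls) <-
    list(cn_ann$feature_id, samples)

  if (cfg$genes_mirror_probes) {
    ge_ann <- cn_ann
    ge_ann$feature_id <- sprintf("g%05d", seq_len(nrow(ge_ann)))
  } else {
    glen <- round(pmax(200, stats::rnorm(cfg$n_ge_features,
                                         cfg$gene_length_mean,
                                         cfg$gene_length_sd)))
    glen <- pmin(glen, cfg$chrom_length - 1)
    gchr <- sample(chroms, cfg$n_ge_features, replace = TRUE)
    gstart <- 1 + floor(stats::runif(cfg$n_ge_features) *
                          (cfg$chrom_length - glen))
    ge_ann <- data.frame(feature_id = sprintf("g%05d",
                                              seq_len(cfg$n_ge_features)),
                         chromosome = gchr, start = gstart,
                         end = gstart + glen - 1)
  }
  g_idx <- match(ge_ann$chromosome, chroms)
  dosage <- dosage_at_rows(dosage_at, g_idx, feature_midpoint(ge_ann))
  dimnames(dosage) <- list(ge_ann$feature_id, samples)

  n_ge <- nrow(ge_ann)
  n_cis <- round(cfg$cis_fraction * n_ge)
  cis <- seq_len(n_ge) %in% sample.int(n_ge, n_cis)
  baseline <- stats::rnorm(n_ge, cfg$expr_baseline_mean, cfg$expr_baseline_sd)
  expression <- matrix(baseline, n_ge, cfg$n_samples) +
    dosage * (cfg$beta * cis) +
    matrix(stats::rnorm(n_ge * cfg$n_samples, 0, cfg$expr_noise_sd),
           nrow = n_ge)
  dimnames(expression) <- list(ge_ann$feature_id, samples)

  overlap <- lapply(seq_len(n_ge), function(g) {
    on_chr <- cn_ann$chromosome == ge_ann$chromosome[g]
    hit <- on_chr & cn_ann$start <= ge_ann$end[g] &
      cn_ann$end >= ge_ann$start[g]
    cn_ann$feature_id[hit]
  })
  names(overlap) <- ge_ann$feature_id

  truth <- data.frame(gene_id = ge_ann$feature_id,
                      chromosome = ge_ann$chromosome,
                      start = ge_ann$start, end = ge_ann$end, cis = cis)
  attr(truth, "overlap") <- overlap
  attr(truth, "dosage") <- dosage

  list(cn = copy_number_set(cn_ann, normalized, segmented, calls),
       ge = expression_set(ge_ann, expression),
       truth = truth)
}

dosage_at_rows <- function(dosage_at, chrom_idx, pos) {
  out <- matrix(NA_real_, length(pos), ncol(dosage_at(1, 1)))
  for (c in unique(chrom_idx)) {
    i <- chrom_idx == c
    out[i, ] <- dosage_at(c, pos[i])
  }
  out
}

call_states <- function(segmented, thresholds) {
  calls <- matrix(0, nrow(segmented), ncol(segmented))
  calls[segmented <= thresholds[["loss"]]] <- -1
  calls[segmented >= thresholds[["gain"]]] <- 1
  calls[segmented >= thresholds[["amp"]]] <- 2
  calls
}
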