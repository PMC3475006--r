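#' Gene-wise cis-effect analysis of a matched data set
#'
#' For every row of a matched pair, computes the Spearman rank correlation
#' between the gene's expression values and its assigned copy number
#' signature (segmented data) across samples, with a two-sided p-value
#' from the asymptotic rank test and Benjamini-Hochberg adjustment across
#' rows. A positive cis-effect of gene dosage on expression manifests as a
#' positive rho. Rows in which either vector is constant (or has fewer
#' than three complete sample pairs) get missing rho/p and are excluded
#' from the adjustment denominator.
#'
#' @param pair a \code{matched_pair} (see [summarize_matched()]) with at
#'   least three samples.
#' @param alpha significance level applied to the adjusted p-values for
#'   the \code{significant} flag.
#' @return a data.frame with one row per matched entry: \code{entry_id},
#'   \code{gene_id}, \code{rho}, \code{p}, \code{p_adj},
#'   \code{significant}, \code{cn_ids}, \code{weights}.
#' @export
cis_correlations <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "matched_pair"))
  if (length(pair$samples) < 3) {
    stop("cis analysis needs at least 3 samples")
  }
  k <- nrow(pair$annotation)
  rho <- p <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    x <- pair$expression[j, ]
    y <- pair$segmented[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rho[j] <- unname(ct$estimate)
    # the asymptotic test underflows to 0 for perfect correlations;
    # p-values live in (0, 1]
    p[j] <- min(max(ct$p.value, .Machine$double.xmin), 1)
  }
  p_adj <- rep(NA_real_, k)
  ok <- !is.na(p)
  if (any(ok)) p_adj[ok] <- bh_adjust(p[ok])
  data.frame(entry_id = pair$annotation$entry_id,
             gene_id = pair$annotation$gene_id,
             rho = rho, p = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha,
             cn_ids = pair$provenance$cn_ids,
             weights = pair$provenance$weights)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment (via
#' [stats::p.adjust()]) with input validation: p-values must lie in
#' (0, 1]. Output is order-preserving with the input.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must be numbers in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Pairwise win counts of cis-correlations across matching procedures
#'
#' The best matching procedure should assign each gene the dosage
#' signature most correlated with its expression. To compare procedures,
#' this counts, over the genes present in all matched versions of the data
#' set, how often procedure A yields a strictly higher Spearman rho than
#' procedure B. Ties count for neither, so
#' \code{count[A,B] + count[B,A] <= number of genes}.
#'
#' @param rho_by_procedure named list; each element a named numeric vector
#'   of per-gene rho values (names are gene IDs) for one procedure.
#' @param genes optional character vector restricting the comparison;
#'   defaults to the genes present in every procedure's vector.
#' @return integer matrix \code{count} with
#'   \code{count[A, B] = #\{genes : rho_A > rho_B\}}; attribute
#'   \code{"genes"} carries the gene set used.
#' @export
pairwise_win_counts <- function(rho_by_procedure, genes = NULL) {
  stopifnot(is.list(rho_by_procedure), length(rho_by_procedure) >= 1)
  nms <- names(rho_by_procedure)
  if (is.null(nms) || any(nms == "")) {
    stop("rho_by_procedure must be a named list")
  }
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(rho_by_procedure, names))
  }
  k <- length(nms)
  counts <- matrix(0L, k, k, dimnames = list(nms, nms))
  if (!length(genes)) {
    warning("no genes common to all procedures; returning zero counts")
    attr(counts, "genes") <- character()
    return(counts)
  }
  vals <- lapply(rho_by_procedure, function(v) v[genes])
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      va <- vals[[a]]
      vb <- vals[[b]]
      ok <- !is.na(va) & !is.na(vb)
      counts[a, b] <- sum(va[ok] > vb[ok])
    }
  }
  attr(counts, "genes") <- genes
  counts
}
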