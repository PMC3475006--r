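#' Summarize matched copy number data into a row-aligned pair
#'
#' Turns a match map plus the two platform sets into a matched data set:
#' one row per map entry, with the copy number data of the matched
#' features summarized into a single signature and the gene's expression
#' row carried alongside.
#'
#' Two summaries are available. \code{"weighted"} takes, per sample, the
#' weight-weighted mean of the matched features' normalized and segmented
#' values; missing values are excluded with per-sample renormalization of
#' the weights, and a sample in which every matched value is missing
#' stays missing. Calls are categorical, so they are not averaged: the
#' call of the dominant-weight feature is used, with weight ties broken
#' per sample toward the call closest to 0 (the least aberrant
#' interpretation), then toward the smaller start. \code{"maximum"}
#' selects, per sample, the most extreme segmented value (largest absolute
#' deviation from zero) among the matched features and carries the
#' normalized value and call of that same feature; ties go to the feature
#' with the smaller start. The most-aberrant summary yields more variable
#' dosage signatures, which can help cis-effect discovery at the price of
#' more false positives.
#'
#' @param cn a \code{cn_set}.
#' @param ge a \code{ge_set}.
#' @param map a [match_map()] produced from the same (canonicalized) sets.
#' @param method \code{"weighted"} or \code{"maximum"}.
#' @return an object of class \code{matched_pair}: a list with
#'   \code{annotation} (one row per entry: entry label, gene ID,
#'   chromosome, matched span), \code{normalized}, \code{segmented},
#'   \code{calls}, \code{expression} (row-aligned matrices), \code{samples}
#'   and \code{provenance} (per entry: gene ID, matched CN IDs and
#'   weights, comma-separated).
#' @export
summarize_matched <- function(cn, ge, map, method = c("weighted", "maximum")) {
  method <- match.arg(method)
  stopifnot(inherits(cn, "cn_set"), inherits(ge, "ge_set"))
  if (!identical(cn$samples, ge$samples)) {
    stop("copy number and expression sets must share the same samples ",
         "in the same order")
  }
  ns <- length(cn$samples)
  ids <- unique(map$entry)
  k <- length(ids)
  norm_out <- seg_out <- matrix(NA_real_, k, ns)
  calls_out <- matrix(NA_real_, k, ns)
  expr_out <- matrix(NA_real_, k, ns)
  ann <- data.frame(entry_id = character(k), gene_id = character(k),
                    chromosome = character(k), start = numeric(k),
                    end = numeric(k))
  prov <- data.frame(entry = integer(k), gene_id = character(k),
                     cn_ids = character(k), weights = character(k))
  for (j in seq_len(k)) {
    rows <- map[map$entry == ids[j], , drop = FALSE]
    i <- rows$cn_index
    wts <- rows$weight
    gi <- rows$gene_index[1]
    if (method == "weighted") {
      summ <- weighted_rows(cn, i, wts)
    } else {
      summ <- maximum_rows(cn, i)
    }
    norm_out[j, ] <- summ$normalized
    seg_out[j, ] <- summ$segmented
    calls_out[j, ] <- summ$calls
    expr_out[j, ] <- ge$expression[gi, ]
    ann$gene_id[j] <- rows$gene_id[1]
    ann$chromosome[j] <- cn$annotation$chromosome[i[1]]
    ann$start[j] <- min(cn$annotation$start[i])
    ann$end[j] <- max(cn$annotation$end[i])
    prov$entry[j] <- ids[j]
    prov$gene_id[j] <- rows$gene_id[1]
    prov$cn_ids[j] <- paste(rows$cn_id, collapse = ",")
    prov$weights[j] <- paste(format(wts, digits = 10, trim = TRUE),
                             collapse = ",")
  }
  ann$entry_id <- make.unique(ann$gene_id, sep = "__part")
  dimnames(norm_out) <- dimnames(seg_out) <- dimnames(calls_out) <-
    dimnames(expr_out) <- list(ann$entry_id, cn$samples)
  structure(list(annotation = ann, normalized = norm_out,
                 segmented = seg_out, calls = calls_out,
                 expression = expr_out, samples = cn$samples,
                 provenance = prov,
                 params = c(attr(map, "params"), list(summary = method)),
                 unmatched = unmatched_report(map)),
            class = "matched_pair")
}

# Weighted mean of CN rows with per-sample NA renormalization.
weighted_rows <- function(cn, i, wts) {
  norm <- cn$normalized[i, , drop = FALSE]
  seg <- cn$segmented[i, , drop = FALSE]
  calls <- cn$calls[i, , drop = FALSE]
  wmean <- function(m) {
    apply_w <- function(col) {
      ok <- !is.na(col)
      if (!any(ok)) return(NA_real_)
      sum(wts[ok] * col[ok]) / sum(wts[ok])
    }
    apply(m, 2, apply_w)
  }
  # dominant-weight feature's call; weight ties broken per sample toward
  # the call nearest zero, then the smaller start (rows come in canonical
  # start order, so "first" realizes that)
  top <- which(wts >= max(wts) - 1e-12)
  call_out <- vapply(seq_len(ncol(calls)), function(s) {
    cc <- calls[top, s]
    if (all(is.na(cc))) return(NA_real_)
    cand <- which(!is.na(cc))
    cc[cand[order(abs(cc[cand]))][1]]
  }, numeric(1))
  list(normalized = wmean(norm), segmented = wmean(seg), calls = call_out)
}

# Per-sample most aberrant segmented value; normalized and call follow the
# selected feature.
maximum_rows <- function(cn, i) {
  seg <- cn$segmented[i, , drop = FALSE]
  norm <- cn$normalized[i, , drop = FALSE]
  calls <- cn$calls[i, , drop = FALSE]
  pick <- vapply(seq_len(ncol(seg)), function(s) {
    v <- abs(seg[, s])
    if (all(is.na(v))) return(NA_integer_)
    which.max(replace(v, is.na(v), -Inf))  # first max = smaller start
  }, integer(1))
  sel <- function(m) {
    vapply(seq_along(pick), function(s) {
      if (is.na(pick[s])) NA_real_ else m[pick[s], s]
    }, numeric(1))
  }
  list(normalized = sel(norm), segmented = sel(seg), calls = sel(calls))
}

#' Split match map entries at copy number breakpoints
#'
#' Within each entry, the matched features (in genome order) are cut at
#' every position where any sample's segmented value changes between
#' consecutive features. Each resulting part becomes its own entry with
#' weights renormalized within the part, so the subsequent weighted
#' average never mixes values from different copy number segments. A gene
#' may afterwards appear multiple times in the matched data set -- each
#' time with the same expression signature but a different dosage
#' signature -- which inflates the multiple-testing correction downstream.
#'
#' @param map a [match_map()].
#' @param cn the \code{cn_set} whose segmented matrix defines breakpoints.
#' @param tol absolute tolerance for "no change" between consecutive
#'   segmented values.
#' @return a new [match_map()]; entries whose features span no breakpoint
#'   are unchanged.
#' @export
split_at_breakpoints <- function(map, cn, tol = 1e-8) {
  stopifnot(inherits(cn, "cn_set"))
  seg <- cn$segmented
  ids <- unique(map$entry)
  out <- vector("list", length(ids))
  next_entry <- 1L
  for (j in seq_along(ids)) {
    rows <- map[map$entry == ids[j], , drop = FALSE]
    o <- order(cn$annotation$start[rows$cn_index],
               cn$annotation$end[rows$cn_index])
    rows <- rows[o, , drop = FALSE]
    m <- nrow(rows)
    part <- integer(m)
    part[1] <- 1L
    if (m > 1) {
      for (r in 2:m) {
        a <- seg[rows$cn_index[r - 1], ]
        b <- seg[rows$cn_index[r], ]
        same <- (is.na(a) & is.na(b)) |
          (!is.na(a) & !is.na(b) & abs(a - b) <= tol)
        part[r] <- part[r - 1] + as.integer(!all(same))
      }
    }
    rows$entry <- next_entry + part - 1L
    next_entry <- next_entry + max(part)
    pieces <- split(seq_len(m), part)
    for (p in pieces) {
      rows$weight[p] <- rows$weight[p] / sum(rows$weight[p])
    }
    out[[j]] <- rows
  }
  entries <- if (length(out)) do.call(rbind, out) else empty_entries()
  params <- attr(map, "params")
  params$extension <- "split"
  match_map(entries, unmatched_report(map), params)
}

#' Expand a match map to singleton entries
#'
#' Splits every entry into one entry per matched copy number feature, each
#' with weight 1, so every feature contributes its own (unaveraged) dosage
#' signature. Idempotent on already-singleton maps.
#'
#' @param map a [match_map()].
#' @return a new [match_map()] with one feature per entry.
#' @export
expand_to_single <- function(map) {
  entries <- as.data.frame(map)
  if (nrow(entries)) {
    # keep original entry blocks contiguous
    entries <- entries[order(match(entries$entry, unique(entries$entry))), ,
                       drop = FALSE]
    entries$entry <- seq_len(nrow(entries))
    entries$weight <- rep(1, nrow(entries))
  }
  params <- attr(map, "params")
  params$extension <- "expand"
  match_map(entries, unmatched_report(map), params)
}

#' @export
print.matched_pair <- function(x, ...) {
  cat("Matched pair:", nrow(x$annotation), "entries (",
      length(unique(x$annotation$gene_id)), "genes ) x",
      length(x$samples), "samples; summary =",
      x$params$summary %||% "?", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
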