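#' @name matching
#' @title Matching procedures for copy number and expression features
#'
#' @description
#' Six procedures assign DNA copy number (aCGH) features to expression
#' features prior to integrative analysis. They differ in how they use the
#' annotation (and, for \code{overlapPlus}, the segmented data):
#'
#' \describe{
#'   \item{label}{features of both platforms are mapped to a common
#'     descriptor set (e.g. gene symbols) and matched when they share a
#'     descriptor; weights uniform.}
#'   \item{distance}{each gene is assigned the single same-chromosome
#'     copy number feature whose midpoint is closest to the gene midpoint.}
#'   \item{distanceAny}{each gene is assigned all same-chromosome features
#'     whose midpoints lie strictly within a window of the gene midpoint;
#'     weights reciprocal to distance plus a small offset (which avoids
#'     infinite weight at zero distance), normalized to sum one.}
#'   \item{overlap}{each gene is assigned the single feature with the
#'     largest overlap fraction (overlapping bp divided by the copy number
#'     probe length), provided it is positive.}
#'   \item{overlapAny}{each gene is assigned all features whose overlap
#'     fraction exceeds a threshold; weights proportional to the
#'     fractions.}
#'   \item{overlapPlus}{overlap matching first; genes left unmatched are
#'     then assigned the nearer of their two flanking features, but only
#'     when no sample shows a breakpoint (a change in segmented value)
#'     between the flanks, so that the interpolated dosage is unambiguous.}
#' }
#'
#' Ties (equal distance or equal overlap fraction) are broken
#' deterministically toward the smallest start, then smallest end, then
#' lexicographic feature ID. All procedures canonicalize their inputs, so
#' results are invariant under row permutation of either annotation.
#'
#' @param cn copy number platform: a \code{cn_set} or an annotation
#'   data.frame (\code{match_overlap_plus} requires a \code{cn_set} for its
#'   segmented matrix).
#' @param ge expression platform: a \code{ge_set} or annotation data.frame.
#' @return a [match_map()].
NULL

# Canonicalize both annotations and precompute per-chromosome indexing.
prep_matching <- function(cn, ge) {
  cn_ann <- canonicalize_annotation(get_annotation(cn), "copy number annotation")
  ge_ann <- canonicalize_annotation(get_annotation(ge), "expression annotation")
  list(cn = cn_ann, ge = ge_ann,
       cn_mid = feature_midpoint(cn_ann),
       ge_mid = feature_midpoint(ge_ann),
       cn_by_chr = split(seq_len(nrow(cn_ann)), cn_ann$chromosome))
}

# Assemble a match_map from per-gene lists of matched indices and weights.
build_map <- function(ge_ann, cn_ann, idx_list, w_list, unmatched, params) {
  matched <- which(lengths(idx_list) > 0)
  if (!length(matched)) {
    return(match_map(empty_entries(), unmatched, params))
  }
  sizes <- lengths(idx_list[matched])
  entry <- rep(seq_along(matched), sizes)
  gene_index <- rep(matched, sizes)
  cn_index <- unlist(idx_list[matched], use.names = FALSE)
  weight <- unlist(w_list[matched], use.names = FALSE)
  entries <- data.frame(
    entry = entry,
    gene_index = gene_index,
    gene_id = ge_ann$feature_id[gene_index],
    cn_index = cn_index,
    cn_id = cn_ann$feature_id[cn_index],
    weight = weight
  )
  match_map(entries, unmatched, params)
}

record_unmatched <- function(unmatched, g, gene_id, reason) {
  rbind(unmatched, data.frame(gene_index = g, gene_id = gene_id,
                              reason = reason))
}

#' @describeIn matching nearest-midpoint matching; every gene whose
#'   chromosome carries at least one copy number feature is matched
#'   (weight 1). Matches farther than \code{warn_distance} bp are reported
#'   in the \code{far_matches} attribute, since a distant feature's dosage
#'   need not be the gene's.
#' @param warn_distance distance in bp beyond which a match is flagged.
#' @export
match_distance <- function(cn, ge, warn_distance = 1e6) {
  p <- prep_matching(cn, ge)
  n <- nrow(p$ge)
  idx <- vector("list", n)
  w <- vector("list", n)
  unmatched <- empty_unmatched()
  far <- list()
  for (g in seq_len(n)) {
    cand <- p$cn_by_chr[[p$ge$chromosome[g]]]
    if (is.null(cand)) {
      unmatched <- record_unmatched(unmatched, g, p$ge$feature_id[g],
                                    "no copy number feature on chromosome")
      next
    }
    d <- abs(p$cn_mid[cand] - p$ge_mid[g])
    best <- tie_break_first(p$cn, cand[d == min(d)])
    idx[[g]] <- best
    w[[g]] <- 1
    if (min(d) > warn_distance) {
      far[[length(far) + 1]] <- data.frame(
        gene_id = p$ge$feature_id[g], cn_id = p$cn$feature_id[best],
        distance = min(d))
    }
  }
  map <- build_map(p$ge, p$cn, idx, w, unmatched,
                   list(method = "distance", warn_distance = warn_distance))
  attr(map, "far_matches") <- if (length(far)) do.call(rbind, far) else
    data.frame(gene_id = character(), cn_id = character(),
               distance = numeric())
  map
}

#' @describeIn matching windowed reciprocal-distance matching. A feature
#'   is included when its midpoint lies strictly within \code{window} bp of
#'   the gene midpoint; raw weights are \code{1 / (distance + offset)},
#'   normalized to sum one.
#' @param window half-width of the search window in bp (strict comparison).
#' @param offset positive bp offset added to distances before taking
#'   reciprocals.
#' @export
match_distance_any <- function(cn, ge, window = 1e5, offset = 1) {
  if (!is.numeric(window) || length(window) != 1 || window <= 0) {
    stop("'window' must be a positive number of base pairs")
  }
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0) {
    stop("'offset' must be a positive number of base pairs")
  }
  p <- prep_matching(cn, ge)
  n <- nrow(p$ge)
  idx <- vector("list", n)
  w <- vector("list", n)
  unmatched <- empty_unmatched()
  for (g in seq_len(n)) {
    cand <- p$cn_by_chr[[p$ge$chromosome[g]]]
    if (is.null(cand)) {
      unmatched <- record_unmatched(unmatched, g, p$ge$feature_id[g],
                                    "no copy number feature on chromosome")
      next
    }
    d <- abs(p$cn_mid[cand] - p$ge_mid[g])
    keep <- d < window
    if (!any(keep)) {
      unmatched <- record_unmatched(unmatched, g, p$ge$feature_id[g],
                                    "no feature midpoint within window")
      next
    }
    raw <- 1 / (d[keep] + offset)
    idx[[g]] <- cand[keep]
    w[[g]] <- raw / sum(raw)
  }
  build_map(p$ge, p$cn, idx, w, unmatched,
            list(method = "distanceAny", window = window, offset = offset))
}

#' @describeIn matching maximum-overlap matching; genes whose best overlap
#'   fraction is zero remain unmatched.
#' @export
match_overlap <- function(cn, ge) {
  p <- prep_matching(cn, ge)
  n <- nrow(p$ge)
  idx <- vector("list", n)
  w <- vector("list", n)
  unmatched <- empty_unmatched()
  for (g in seq_len(n)) {
    cand <- p$cn_by_chr[[p$ge$chromosome[g]]]
    fr <- if (is.null(cand)) numeric() else
      gene_overlap_fractions(p$ge[g, ], p$cn, cand)
    if (!length(fr) || max(fr) <= 0) {
      unmatched <- record_unmatched(
        unmatched, g, p$ge$feature_id[g],
        if (is.null(cand)) "no copy number feature on chromosome"
        else "no overlapping copy number feature")
      next
    }
    idx[[g]] <- tie_break_first(p$cn, cand[fr == max(fr)])
    w[[g]] <- 1
  }
  build_map(p$ge, p$cn, idx, w, unmatched, list(method = "overlap"))
}

#' @describeIn matching any-overlap matching with weights proportional to
#'   the overlap fractions; a feature is included when its fraction is
#'   strictly greater than \code{min_fraction}.
#' @param min_fraction inclusion threshold on the overlap fraction, in
#'   [0, 1) (strict comparison).
#' @export
match_overlap_any <- function(cn, ge, min_fraction = 0) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction < 0 || min_fraction >= 1) {
    stop("'min_fraction' must lie in [0, 1)")
  }
  p <- prep_matching(cn, ge)
  n <- nrow(p$ge)
  idx <- vector("list", n)
  w <- vector("list", n)
  unmatched <- empty_unmatched()
  for (g in seq_len(n)) {
    cand <- p$cn_by_chr[[p$ge$chromosome[g]]]
    fr <- if (is.null(cand)) numeric() else
      gene_overlap_fractions(p$ge[g, ], p$cn, cand)
    keep <- fr > min_fraction
    if (!any(keep)) {
      unmatched <- record_unmatched(
        unmatched, g, p$ge$feature_id[g],
        if (is.null(cand)) "no copy number feature on chromosome"
        else "no overlap fraction above threshold")
      next
    }
    idx[[g]] <- cand[keep]
    w[[g]] <- fr[keep] / sum(fr[keep])
  }
  build_map(p$ge, p$cn, idx, w, unmatched,
            list(method = "overlapAny", min_fraction = min_fraction))
}

# Overlap fractions of one gene against candidate CN rows (same chromosome
# by construction, so the closed-interval formula applies directly).
gene_overlap_fractions <- function(gene, cn_ann, cand) {
  s <- as.numeric(cn_ann$start[cand])
  e <- as.numeric(cn_ann$end[cand])
  ov <- pmax(0, pmin(as.numeric(gene$end), e) -
               pmax(as.numeric(gene$start), s) + 1)
  ov / (e - s + 1)
}

#' @describeIn matching overlap matching plus breakpoint-checked
#'   interpolation for unmatched genes. For a gene with no overlapping
#'   feature, the nearest features strictly down- and upstream (by
#'   midpoint) are located; when both exist and their segmented rows agree
#'   in every sample (within \code{tol}), the gene dosage between them is
#'   unambiguous and the nearer flank is assigned with weight 1. A
#'   breakpoint in any sample, or a missing flank (chromosome end), leaves
#'   the gene unmatched.
#' @param tol absolute tolerance when comparing segmented values of the
#'   two flanking features.
#' @export
match_overlap_plus <- function(cn, ge, tol = 1e-8) {
  if (!inherits(cn, "cn_set")) {
    stop("match_overlap_plus requires a cn_set (its segmented data is ",
         "used to check for breakpoints between flanking features)")
  }
  base <- match_overlap(cn, ge)
  p <- prep_matching(cn, ge)
  seg <- cn$segmented
  pending <- unmatched_report(base)
  n <- nrow(p$ge)
  idx <- vector("list", n)
  w <- vector("list", n)
  # carry over the overlap matches
  for (e in unique(base$entry)) {
    rows <- base[base$entry == e, , drop = FALSE]
    idx[[rows$gene_index[1]]] <- rows$cn_index
    w[[rows$gene_index[1]]] <- rows$weight
  }
  unmatched <- empty_unmatched()
  for (k in seq_len(nrow(pending))) {
    g <- pending$gene_index[k]
    cand <- p$cn_by_chr[[p$ge$chromosome[g]]]
    if (is.null(cand)) {
      unmatched <- record_unmatched(unmatched, g, pending$gene_id[k],
                                    pending$reason[k])
      next
    }
    mid <- p$cn_mid[cand]
    down <- cand[mid < p$ge_mid[g]]
    up <- cand[mid > p$ge_mid[g]]
    if (!length(down) || !length(up)) {
      unmatched <- record_unmatched(unmatched, g, pending$gene_id[k],
                                    "no flanking feature on one side")
      next
    }
    dmid <- p$cn_mid[down]
    umid <- p$cn_mid[up]
    L <- tie_break_first(p$cn, down[dmid == max(dmid)])
    U <- tie_break_first(p$cn, up[umid == min(umid)])
    sL <- seg[L, ]
    sU <- seg[U, ]
    same <- (is.na(sL) & is.na(sU)) |
      (!is.na(sL) & !is.na(sU) & abs(sL - sU) <= tol)
    if (!all(same)) {
      unmatched <- record_unmatched(unmatched, g, pending$gene_id[k],
                                    "breakpoint between flanking features")
      next
    }
    dl <- abs(p$cn_mid[L] - p$ge_mid[g])
    du <- abs(p$cn_mid[U] - p$ge_mid[g])
    best <- if (dl <= du) L else U
    idx[[g]] <- best
    w[[g]] <- 1
  }
  build_map(p$ge, p$cn, idx, w, unmatched,
            list(method = "overlapPlus", tol = tol))
}

#' Label matching via a common descriptor set
#'
#' Maps the manufacturer IDs of both platforms to a common descriptor set
#' (e.g. gene symbols) and matches an expression feature to every copy
#' number feature sharing at least one of its descriptors, with uniform
#' weights. Because it never looks at genomic coordinates, label matching
#' can in principle pair features on different chromosomes; set
#' \code{strict_chromosome = TRUE} (and supply both annotations) to drop
#' such pairs.
#'
#' @param cn_ids,ge_ids character vectors of platform feature IDs.
#' @param cn_to_common,ge_to_common maps from platform IDs to common
#'   descriptors: either a named character vector (names are platform IDs)
#'   or a two-column data.frame \code{(id, common)}; partial and
#'   many-to-one maps are allowed, and a data.frame may list several
#'   descriptors per ID.
#' @param cn_annotation,ge_annotation optional annotation data.frames,
#'   required when \code{strict_chromosome} is \code{TRUE}.
#' @param strict_chromosome drop cross-chromosome pairs.
#' @return a [match_map()]; \code{gene_index}/\code{cn_index} refer to
#'   positions in \code{ge_ids}/\code{cn_ids}.
#' @export
match_label <- function(cn_ids, ge_ids, cn_to_common, ge_to_common,
                        cn_annotation = NULL, ge_annotation = NULL,
                        strict_chromosome = FALSE) {
  cn_map <- as_label_map(cn_to_common)
  ge_map <- as_label_map(ge_to_common)
  if (strict_chromosome && (is.null(cn_annotation) || is.null(ge_annotation))) {
    stop("strict_chromosome = TRUE requires both annotations")
  }
  ge_chr <- cn_chr <- NULL
  if (strict_chromosome) {
    cn_annotation <- validate_annotation(cn_annotation, "copy number annotation")
    ge_annotation <- validate_annotation(ge_annotation, "expression annotation")
    cn_chr <- normalize_chromosome(
      cn_annotation$chromosome[match(cn_ids, cn_annotation$feature_id)])
    ge_chr <- normalize_chromosome(
      ge_annotation$chromosome[match(ge_ids, ge_annotation$feature_id)])
  }
  common_by_cn <- split(cn_map$common, cn_map$id)
  cn_by_common <- split(match(cn_map$id, cn_ids), cn_map$common)
  n <- length(ge_ids)
  idx <- vector("list", n)
  w <- vector("list", n)
  unmatched <- empty_unmatched()
  ge_common <- split(ge_map$common, ge_map$id)
  for (g in seq_len(n)) {
    descr <- unique(unlist(ge_common[ge_ids[g]], use.names = FALSE))
    hits <- sort(unique(unlist(cn_by_common[descr], use.names = FALSE)))
    hits <- hits[!is.na(hits)]
    if (strict_chromosome && length(hits)) {
      hits <- hits[!is.na(cn_chr[hits]) & cn_chr[hits] == ge_chr[g]]
    }
    if (!length(hits)) {
      unmatched <- record_unmatched(unmatched, g, ge_ids[g],
                                    "no shared common descriptor")
      next
    }
    idx[[g]] <- hits
    w[[g]] <- rep(1 / length(hits), length(hits))
  }
  ge_ann <- data.frame(feature_id = ge_ids)
  cn_ann <- data.frame(feature_id = cn_ids)
  build_map(ge_ann, cn_ann, idx, w, unmatched,
            list(method = "label", strict_chromosome = strict_chromosome))
}

as_label_map <- function(m) {
  if (is.data.frame(m)) {
    names(m)[1:2] <- c("id", "common")
    return(data.frame(id = as.character(m$id), common = as.character(m$common)))
  }
  if (is.null(m) || !length(m)) {
    return(data.frame(id = character(), common = character()))
  }
  if (is.null(names(m))) {
    stop("a label map must be a named vector or a two-column data.frame")
  }
  data.frame(id = names(m), common = as.character(m))
}

#' Run a matching procedure by name
#'
#' Thin dispatcher over the individual \code{match_*} functions, used by
#' the command-line interface.
#'
#' @inheritParams matching
#' @param method one of \code{"label"}, \code{"distance"},
#'   \code{"distanceAny"}, \code{"overlap"}, \code{"overlapAny"},
#'   \code{"overlapPlus"}.
#' @param window,offset,min_fraction,warn_distance see the individual
#'   procedures.
#' @param cn_to_common,ge_to_common label maps (label method only).
#' @param strict_chromosome enforce same-chromosome pairs (label only).
#' @return a [match_map()].
#' @export
match_features <- function(cn, ge,
                           method = c("distance", "distanceAny", "overlap",
                                      "overlapAny", "overlapPlus", "label"),
                           window = 1e5, offset = 1, min_fraction = 0,
                           warn_distance = 1e6,
                           cn_to_common = NULL, ge_to_common = NULL,
                           strict_chromosome = FALSE) {
  method <- match.arg(method)
  switch(method,
    distance = match_distance(cn, ge, warn_distance = warn_distance),
    distanceAny = match_distance_any(cn, ge, window = window, offset = offset),
    overlap = match_overlap(cn, ge),
    overlapAny = match_overlap_any(cn, ge, min_fraction = min_fraction),
    overlapPlus = match_overlap_plus(cn, ge),
    label = {
      cn_ann <- get_annotation(cn)
      ge_ann <- get_annotation(ge)
      match_label(cn_ann$feature_id, ge_ann$feature_id,
                  cn_to_common, ge_to_common,
                  cn_annotation = cn_ann, ge_annotation = ge_ann,
                  strict_chromosome = strict_chromosome)
    })
}
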