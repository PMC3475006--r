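# Naive exhaustive reference implementations of the matching procedures,
# written as scalar double loops so they share no code path with the
# package's vectorized per-chromosome scans.

oracle_mid <- function(s, e) (s + e) / 2

# TRUE if feature a precedes feature b under the deterministic tie-break.
oracle_precedes <- function(sa, ea, ida, sb, eb, idb) {
  if (sa != sb) return(sa < sb)
  if (ea != eb) return(ea < eb)
  ida < idb
}

oracle_distance <- function(cn, ge) {
  res <- list()
  for (g in seq_len(nrow(ge))) {
    best <- 0L
    bestd <- Inf
    for (j in seq_len(nrow(cn))) {
      if (cn$chromosome[j] != ge$chromosome[g]) next
      d <- abs(oracle_mid(cn$start[j], cn$end[j]) -
                 oracle_mid(ge$start[g], ge$end[g]))
      if (d < bestd ||
          (d == bestd && oracle_precedes(cn$start[j], cn$end[j],
                                         cn$feature_id[j], cn$start[best],
                                         cn$end[best], cn$feature_id[best]))) {
        best <- j
        bestd <- d
      }
    }
    if (best > 0L) {
      res[[ge$feature_id[g]]] <- data.frame(cn_id = cn$feature_id[best],
                                            weight = 1)
    }
  }
  res
}

oracle_distance_any <- function(cn, ge, window, offset = 1) {
  res <- list()
  for (g in seq_len(nrow(ge))) {
    ids <- character()
    wts <- numeric()
    for (j in seq_len(nrow(cn))) {
      if (cn$chromosome[j] != ge$chromosome[g]) next
      d <- abs(oracle_mid(cn$start[j], cn$end[j]) -
                 oracle_mid(ge$start[g], ge$end[g]))
      if (d < window) {
        ids <- c(ids, cn$feature_id[j])
        wts <- c(wts, 1 / (d + offset))
      }
    }
    if (length(ids)) {
      o <- order(ids)
      res[[ge$feature_id[g]]] <- data.frame(cn_id = ids[o],
                                            weight = wts[o] / sum(wts))
    }
  }
  res
}

oracle_overlap_frac <- function(cn, j, ge, g) {
  if (cn$chromosome[j] != ge$chromosome[g]) return(0)
  ov <- min(cn$end[j], ge$end[g]) - max(cn$start[j], ge$start[g]) + 1
  max(0, ov) / (cn$end[j] - cn$start[j] + 1)
}

oracle_overlap <- function(cn, ge) {
  res <- list()
  for (g in seq_len(nrow(ge))) {
    best <- 0L
    bestf <- 0
    for (j in seq_len(nrow(cn))) {
      f <- oracle_overlap_frac(cn, j, ge, g)
      if (f <= 0) next
      if (f > bestf ||
          (f == bestf && oracle_precedes(cn$start[j], cn$end[j],
                                         cn$feature_id[j], cn$start[best],
                                         cn$end[best], cn$feature_id[best]))) {
        best <- j
        bestf <- f
      }
    }
    if (best > 0L) {
      res[[ge$feature_id[g]]] <- data.frame(cn_id = cn$feature_id[best],
                                            weight = 1)
    }
  }
  res
}

oracle_overlap_any <- function(cn, ge, min_fraction = 0) {
  res <- list()
  for (g in seq_len(nrow(ge))) {
    ids <- character()
    wts <- numeric()
    for (j in seq_len(nrow(cn))) {
      f <- oracle_overlap_frac(cn, j, ge, g)
      if (f > min_fraction) {
        ids <- c(ids, cn$feature_id[j])
        wts <- c(wts, f)
      }
    }
    if (length(ids)) {
      o <- order(ids)
      res[[ge$feature_id[g]]] <- data.frame(cn_id = ids[o],
                                            weight = wts[o] / sum(wts))
    }
  }
  res
}

oracle_overlap_plus <- function(cn_set, ge, tol = 1e-8) {
  cn <- cn_set$annotation
  seg <- cn_set$segmented
  res <- oracle_overlap(cn, ge)
  for (g in seq_len(nrow(ge))) {
    gid <- ge$feature_id[g]
    if (!is.null(res[[gid]])) next
    gmid <- oracle_mid(ge$start[g], ge$end[g])
    L <- U <- 0L
    for (j in seq_len(nrow(cn))) {
      if (cn$chromosome[j] != ge$chromosome[g]) next
      m <- oracle_mid(cn$start[j], cn$end[j])
      if (m < gmid) {
        if (L == 0L || m > oracle_mid(cn$start[L], cn$end[L]) ||
            (m == oracle_mid(cn$start[L], cn$end[L]) &&
               oracle_precedes(cn$start[j], cn$end[j], cn$feature_id[j],
                               cn$start[L], cn$end[L], cn$feature_id[L]))) {
          L <- j
        }
      } else if (m > gmid) {
        if (U == 0L || m < oracle_mid(cn$start[U], cn$end[U]) ||
            (m == oracle_mid(cn$start[U], cn$end[U]) &&
               oracle_precedes(cn$start[j], cn$end[j], cn$feature_id[j],
                               cn$start[U], cn$end[U], cn$feature_id[U]))) {
          U <- j
        }
      }
    }
    if (L == 0L || U == 0L) next
    if (any(abs(seg[L, ] - seg[U, ]) > tol, na.rm = TRUE)) next
    if (any(is.na(seg[L, ]) != is.na(seg[U, ]))) next
    dl <- abs(oracle_mid(cn$start[L], cn$end[L]) - gmid)
    du <- abs(oracle_mid(cn$start[U], cn$end[U]) - gmid)
    pick <- if (dl <= du) L else U
    res[[gid]] <- data.frame(cn_id = cn$feature_id[pick], weight = 1)
  }
  res
}

oracle_label <- function(cn_ids, ge_ids, cn_map_df, ge_map_df) {
  res <- list()
  for (g in seq_along(ge_ids)) {
    descr <- unique(ge_map_df$common[ge_map_df$id == ge_ids[g]])
    hit <- character()
    for (j in seq_along(cn_ids)) {
      commons <- cn_map_df$common[cn_map_df$id == cn_ids[j]]
      if (length(intersect(commons, descr))) hit <- c(hit, cn_ids[j])
    }
    if (length(hit)) {
      hit <- sort(unique(hit))
      res[[ge_ids[g]]] <- data.frame(cn_id = hit,
                                     weight = rep(1 / length(hit),
                                                  length(hit)))
    }
  }
  res
}
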