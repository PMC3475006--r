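#' Construct a match map
#'
#' A match map records, per matched expression feature, the set of copy
#' number features assigned to it and their positive weights (normalized
#' to sum one per entry). It is the common output of all matching
#' procedures and the input of the summarization step. Entries are rows of
#' a data.frame with columns \code{entry} (integer, groups rows belonging
#' to the same assignment), \code{gene_index}, \code{gene_id},
#' \code{cn_index}, \code{cn_id}, \code{weight}. After the
#' splitting/expansion extensions a gene may recur across entries.
#'
#' @param entries data.frame as described above.
#' @param unmatched data.frame with columns \code{gene_index},
#'   \code{gene_id}, \code{reason} for expression features the procedure
#'   could not match.
#' @param params named list of procedure parameters, kept for provenance.
#' @return an object of class \code{match_map}.
#' @export
match_map <- function(entries, unmatched = empty_unmatched(), params = list()) {
  required <- c("entry", "gene_index", "gene_id", "cn_index", "cn_id", "weight")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    stop("match_map entries are missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(entries)) {
    if (any(entries$weight <= 0)) stop("match_map weights must be positive")
    sums <- tapply(entries$weight, entries$entry, sum)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("match_map weights must sum to one per entry (max deviation ",
           format(max(abs(sums - 1))), ")")
    }
  }
  rownames(entries) <- NULL
  structure(entries, class = c("match_map", "data.frame"),
            unmatched = unmatched, params = params)
}

empty_entries <- function() {
  data.frame(entry = integer(), gene_index = integer(),
             gene_id = character(), cn_index = integer(),
             cn_id = character(), weight = numeric())
}

empty_unmatched <- function() {
  data.frame(gene_index = integer(), gene_id = character(),
             reason = character())
}

#' Matched gene IDs of a match map
#'
#' @param map a \code{match_map}.
#' @return character vector of unique matched expression feature IDs.
#' @export
matched_genes <- function(map) {
  unique(map$gene_id)
}

#' Unmatched-feature report of a match map
#'
#' @param map a \code{match_map}.
#' @return data.frame with columns \code{gene_index}, \code{gene_id},
#'   \code{reason}.
#' @export
unmatched_report <- function(map) {
  attr(map, "unmatched")
}

#' @export
print.match_map <- function(x, ...) {
  p <- attr(x, "params")
  cat("Match map (", if (!is.null(p$method)) p$method else "?", "): ",
      length(unique(x$entry)), " entries over ",
      length(unique(x$gene_id)), " expression features, ",
      nrow(attr(x, "unmatched")), " unmatched\n", sep = "")
  invisible(x)
}
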