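#' Normalize chromosome labels
#'
#' Strips an optional "chr" prefix and uppercases the sex/mitochondrial
#' labels, so that "chr14", "14", "chrx" and "X" compare as intended across
#' annotation dialects.
#'
#' @param chromosome character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_chromosome(c("chr14", "chrX", "mt", "2"))
#' @export
normalize_chromosome <- function(chromosome) {
  x <- trimws(as.character(chromosome))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  sex <- toupper(x) %in% c("X", "Y", "MT", "M")
  x[sex] <- toupper(x[sex])
  x[x == "M"] <- "MT"
  x
}

# Ordering key for chromosome labels: autosomes numerically, then X, Y, MT,
# then anything else alphabetically.
chromosome_rank <- function(chromosome) {
  n <- suppressWarnings(as.numeric(chromosome))
  r <- rep(NA_real_, length(chromosome))
  r[!is.na(n)] <- n[!is.na(n)]
  r[chromosome == "X"] <- 1e3
  r[chromosome == "Y"] <- 1e3 + 1
  r[chromosome == "MT"] <- 1e3 + 2
  r[is.na(r)] <- 1e4 + xtfrm(chromosome[is.na(r)])
  r
}

#' Validate a feature annotation table
#'
#' An annotation table describes array features (probes or genes) with one
#' row per feature and columns \code{feature_id}, \code{chromosome},
#' \code{start} and \code{end}. Coordinates are 1-based and inclusive, so a
#' feature of length one has \code{start == end}.
#'
#' @param annotation a data.frame with columns \code{feature_id},
#'   \code{chromosome}, \code{start}, \code{end} (a column named \code{id}
#'   is accepted as an alias for \code{feature_id}).
#' @param context character scalar used in error messages.
#' @return the validated data.frame (invisibly unchanged apart from the
#'   \code{id} alias being renamed).
#' @export
validate_annotation <- function(annotation, context = "annotation") {
  if (!is.data.frame(annotation)) {
    stop(context, ": expected a data.frame, got ", class(annotation)[1])
  }
  names(annotation)[names(annotation) == "id"] <- "feature_id"
  required <- c("feature_id", "chromosome", "start", "end")
  missing <- setdiff(required, names(annotation))
  if (length(missing)) {
    stop(context, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  annotation$feature_id <- as.character(annotation$feature_id)
  if (anyDuplicated(annotation$feature_id)) {
    dup <- unique(annotation$feature_id[duplicated(annotation$feature_id)])
    stop(context, ": duplicated feature_id(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  for (fld in c("start", "end")) {
    v <- annotation[[fld]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop(context, ": row ", if (is.na(bad)) "?" else bad,
           ", field '", fld, "' is not a finite number")
    }
  }
  bad <- which(annotation$start < 1)
  if (length(bad)) {
    stop(context, ": row ", bad[1], ", field 'start' must be >= 1 (got ",
         annotation$start[bad[1]], ")")
  }
  bad <- which(annotation$end < annotation$start)
  if (length(bad)) {
    stop(context, ": row ", bad[1], ", field 'end' (",
         annotation$end[bad[1]], ") is smaller than 'start' (",
         annotation$start[bad[1]], ")")
  }
  annotation
}

#' Canonicalize a feature annotation table
#'
#' Normalizes chromosome labels and sorts features by (chromosome, start,
#' end, feature_id). Canonicalization is idempotent; all matching
#' procedures canonicalize their inputs so results do not depend on input
#' row order.
#'
#' @inheritParams validate_annotation
#' @return the canonicalized data.frame.
#' @export
canonicalize_annotation <- function(annotation, context = "annotation") {
  annotation <- validate_annotation(annotation, context)
  annotation$chromosome <- normalize_chromosome(annotation$chromosome)
  o <- order(chromosome_rank(annotation$chromosome), annotation$start,
             annotation$end, annotation$feature_id)
  annotation <- annotation[o, , drop = FALSE]
  rownames(annotation) <- NULL
  annotation
}

#' Feature midpoints
#'
#' The midpoint of a feature is the average of its start and end base-pair
#' positions; exact half-integers are kept unrounded so distance ties are
#' resolved on the true values.
#'
#' @param annotation annotation data.frame (see [validate_annotation()]).
#' @return numeric vector of midpoints in bp.
#' @export
feature_midpoint <- function(annotation) {
  (as.numeric(annotation$start) + as.numeric(annotation$end)) / 2
}

#' Distance between feature midpoints
#'
#' @param a,b annotation data.frames with the same number of rows (or one
#'   of them a single row, recycled). Callers are expected to compare
#'   features on the same chromosome.
#' @return numeric vector of absolute midpoint distances in bp; symmetric
#'   in its arguments.
#' @export
midpoint_distance <- function(a, b) {
  abs(feature_midpoint(a) - feature_midpoint(b))
}

#' Number of overlapping base pairs between features
#'
#' Closed-interval overlap: features on different chromosomes overlap in 0
#' bp; on the same chromosome the overlap is
#' \code{max(0, min(end) - max(start) + 1)}.
#'
#' @inheritParams midpoint_distance
#' @return integer-valued numeric vector of overlap widths in bp.
#' @export
overlap_bp <- function(a, b) {
  w <- pmin(as.numeric(a$end), as.numeric(b$end)) -
    pmax(as.numeric(a$start), as.numeric(b$start)) + 1
  w <- pmax(0, w)
  same <- normalize_chromosome(a$chromosome) == normalize_chromosome(b$chromosome)
  w * as.numeric(same)
}

#' Fraction of a copy number probe overlapped by a gene
#'
#' The overlap fraction is the number of overlapping base pairs divided by
#' the length of the copy number probe -- never the gene length -- so a
#' probe fully contained in a gene scores exactly 1.
#'
#' @param gene annotation rows for the expression features.
#' @param cn annotation rows for the copy number features.
#' @return numeric vector in [0, 1].
#' @export
overlap_fraction <- function(gene, cn) {
  overlap_bp(gene, cn) / (as.numeric(cn$end) - as.numeric(cn$start) + 1)
}

# First index among candidates under the deterministic tie-break:
# smallest start, then smallest end, then lexicographic feature_id.
tie_break_first <- function(annotation, candidates) {
  a <- annotation[candidates, , drop = FALSE]
  candidates[order(a$start, a$end, a$feature_id)[1]]
}
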