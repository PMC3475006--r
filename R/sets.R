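#' Construct a copy number set
#'
#' Bundles the annotation of an aCGH platform with its three aligned
#' feature-by-sample matrices: normalized log2 ratios, segmented values
#' (piecewise constant along the genome), and discrete calls in
#' \{-2, -1, 0, 1, 2\} (double loss ... amplification). Matrix rows are
#' aligned to the annotation by feature ID (row names) when present, and
#' the whole object is canonicalized: features sorted by chromosome, start,
#' end, ID.
#'
#' @param annotation annotation data.frame (see [validate_annotation()]).
#' @param normalized,segmented,calls numeric matrices, one row per feature.
#'   Row names, when present, must equal the annotation feature IDs (any
#'   order); column names are the sample labels and must agree across the
#'   three matrices.
#' @return an object of class \code{cn_set}: a list with elements
#'   \code{annotation}, \code{normalized}, \code{segmented}, \code{calls},
#'   \code{samples}.
#' @export
copy_number_set <- function(annotation, normalized, segmented, calls) {
  annotation <- canonicalize_annotation(annotation, "copy number annotation")
  normalized <- align_matrix(normalized, annotation$feature_id, "normalized")
  segmented <- align_matrix(segmented, annotation$feature_id, "segmented")
  calls <- align_matrix(calls, annotation$feature_id, "calls")
  samples <- colnames(normalized)
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(ncol(normalized)))
    colnames(normalized) <- colnames(segmented) <- colnames(calls) <- samples
  }
  for (nm in c("segmented", "calls")) {
    m <- get(nm)
    if (!identical(dim(m), dim(normalized))) {
      stop("copy number matrices disagree in dimension: normalized is ",
           nrow(normalized), "x", ncol(normalized), ", ", nm, " is ",
           nrow(m), "x", ncol(m))
    }
    if (is.null(colnames(m))) {
      colnames(m) <- samples
      assign(nm, m)
    } else if (!identical(colnames(m), samples)) {
      stop("sample labels of '", nm, "' disagree with 'normalized'")
    }
  }
  bad <- calls[!is.na(calls) & !(calls %in% (-2):2)]
  if (length(bad)) {
    stop("calls must lie in {-2,-1,0,1,2}; found ", bad[1])
  }
  structure(list(annotation = annotation, normalized = normalized,
                 segmented = segmented, calls = calls, samples = samples),
            class = "cn_set")
}

#' Construct an expression set
#'
#' Bundles the annotation of an expression platform (mRNA or microRNA)
#' with its feature-by-sample expression matrix, aligned and canonicalized
#' as for [copy_number_set()].
#'
#' @param annotation annotation data.frame.
#' @param expression numeric matrix, one row per feature.
#' @return an object of class \code{ge_set} with elements
#'   \code{annotation}, \code{expression}, \code{samples}.
#' @export
expression_set <- function(annotation, expression) {
  annotation <- canonicalize_annotation(annotation, "expression annotation")
  expression <- align_matrix(expression, annotation$feature_id, "expression")
  samples <- colnames(expression)
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(ncol(expression)))
    colnames(expression) <- samples
  }
  structure(list(annotation = annotation, expression = expression,
                 samples = samples), class = "ge_set")
}

# Reorder matrix rows to the given feature IDs; matrices without row names
# are accepted as already aligned if the row count matches.
align_matrix <- function(m, feature_ids, what) {
  if (!is.matrix(m)) m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != length(feature_ids)) {
    stop("'", what, "' has ", nrow(m), " rows but the annotation has ",
         length(feature_ids), " features")
  }
  if (!is.null(rownames(m))) {
    idx <- match(feature_ids, rownames(m))
    if (anyNA(idx)) {
      stop("'", what, "' is missing feature(s): ",
           paste(utils::head(feature_ids[is.na(idx)], 5), collapse = ", "))
    }
    m <- m[idx, , drop = FALSE]
  }
  rownames(m) <- feature_ids
  m
}

# Extract the annotation data.frame from a set or pass a data.frame through.
get_annotation <- function(x) {
  if (inherits(x, "cn_set") || inherits(x, "ge_set")) return(x$annotation)
  if (is.data.frame(x)) return(x)
  stop("expected a cn_set, ge_set or annotation data.frame")
}

#' @export
print.cn_set <- function(x, ...) {
  cat("Copy number set:", nrow(x$annotation), "features x",
      length(x$samples), "samples on chromosome(s)",
      paste(unique(x$annotation$chromosome), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ge_set <- function(x, ...) {
  cat("Expression set:", nrow(x$annotation), "features x",
      length(x$samples), "samples on chromosome(s)",
      paste(unique(x$annotation$chromosome), collapse = ", "), "\n")
  invisible(x)
}
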