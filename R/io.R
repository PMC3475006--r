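#' Read a feature annotation table
#'
#' TSV input requires a header with columns \code{id} (or
#' \code{feature_id}), \code{chromosome}, \code{start}, \code{end}, with
#' 1-based inclusive coordinates. BED input (no header; columns chrom,
#' start, end and optionally name) uses the 0-based half-open convention
#' and is converted to 1-based inclusive at this boundary
#' (\code{start + 1}, \code{end} unchanged). The result is validated and
#' canonicalized; malformed rows raise an error naming the file, line and
#' field.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"bed"}.
#' @return canonicalized annotation data.frame.
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    names(df)[names(df) == "id"] <- "feature_id"
    required <- c("feature_id", "chromosome", "start", "end")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
    }
    df <- df[, required]
    for (fld in c("start", "end")) {
      v <- suppressWarnings(as.numeric(df[[fld]]))
      bad <- which(!is.finite(v))
      if (length(bad)) {
        stop(path, ": line ", bad[1] + 1, ", field '", fld,
             "': not a number ('", df[[fld]][bad[1]], "')")
      }
      df[[fld]] <- v
    }
  } else {
    df <- utils::read.table(path, sep = "", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = paste0("V", 1:6), fill = TRUE)[, 1:4]
    names(df) <- c("chromosome", "start", "end", "feature_id")
    if (all(is.na(df$feature_id)) || all(df$feature_id == "")) {
      df$feature_id <- sprintf("feature%05d", seq_len(nrow(df)))
    }
    for (fld in c("start", "end")) {
      v <- suppressWarnings(as.numeric(df[[fld]]))
      bad <- which(!is.finite(v))
      if (length(bad)) {
        stop(path, ": line ", bad[1], ", field '", fld,
             "': not a number ('", df[[fld]][bad[1]], "')")
      }
      df[[fld]] <- v
    }
    df$start <- df$start + 1  # 0-based half-open -> 1-based inclusive
    df <- df[, c("feature_id", "chromosome", "start", "end")]
  }
  bad <- which(df$end < df$start)
  if (length(bad)) {
    stop(path, ": line ", bad[1] + (format == "tsv"),
         ", field 'end': end (", df$end[bad[1]],
         ") is smaller than start (", df$start[bad[1]], ")")
  }
  canonicalize_annotation(df, path)
}

#' Write a feature annotation table as TSV
#'
#' @param annotation annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(
    annotation[, c("feature_id", "chromosome", "start", "end")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#'
#' The first column holds feature IDs, the header row sample IDs; empty
#' fields and \code{NA} are read as missing. Row order is immaterial:
#' alignment to the annotation happens by ID in the set constructors.
#'
#' @param path file path.
#' @return numeric matrix with feature IDs as row names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!ncol(df)) stop(path, ": empty file")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicated feature ID(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m numeric matrix with row names.
#' @param path output path.
#' @param id_column header of the feature ID column.
#' @export
write_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy number TSV bundle
#'
#' @param annotation_path annotation TSV (or BED, with \code{format}).
#' @param normalized_path,segmented_path,calls_path matrix TSVs.
#' @param format annotation format.
#' @return a \code{cn_set}.
#' @export
read_copy_number <- function(annotation_path, normalized_path,
                             segmented_path, calls_path,
                             format = c("tsv", "bed")) {
  ann <- read_annotation(annotation_path, format)
  copy_number_set(ann, read_matrix(normalized_path),
                  read_matrix(segmented_path), read_matrix(calls_path))
}

#' Read an expression TSV bundle
#'
#' @param annotation_path annotation TSV (or BED).
#' @param expression_path matrix TSV.
#' @param format annotation format.
#' @return a \code{ge_set}.
#' @export
read_expression <- function(annotation_path, expression_path,
                            format = c("tsv", "bed")) {
  expression_set(read_annotation(annotation_path, format),
                 read_matrix(expression_path))
}

#' Write a matched data set to a directory
#'
#' Writes the row-aligned bundle: \code{cn_normalized.tsv},
#' \code{cn_segmented.tsv}, \code{cn_calls.tsv}, \code{expression.tsv},
#' \code{provenance.tsv}, \code{annotation.tsv}, plus
#' \code{run_info.yaml} recording the method, its parameters and the
#' unmatched-feature report. An empty matched pair produces headers-only
#' files with a warning.
#'
#' @param pair a \code{matched_pair}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_matched <- function(pair, dir) {
  stopifnot(inherits(pair, "matched_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!nrow(pair$annotation)) {
    warning("matched pair is empty; writing headers-only files")
  }
  write_matrix(pair$normalized, file.path(dir, "cn_normalized.tsv"),
               id_column = "entry_id")
  write_matrix(pair$segmented, file.path(dir, "cn_segmented.tsv"),
               id_column = "entry_id")
  write_matrix(pair$calls, file.path(dir, "cn_calls.tsv"),
               id_column = "entry_id")
  write_matrix(pair$expression, file.path(dir, "expression.tsv"),
               id_column = "entry_id")
  utils::write.table(pair$provenance, file.path(dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pair$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  info <- list(params = pair$params,
               n_entries = nrow(pair$annotation),
               n_genes = length(unique(pair$annotation$gene_id)),
               n_samples = length(pair$samples),
               unmatched = if (nrow(pair$unmatched))
                 as.list(stats::setNames(pair$unmatched$reason,
                                         pair$unmatched$gene_id))
               else list())
  yaml::write_yaml(info, file.path(dir, "run_info.yaml"))
  invisible(dir)
}

#' Read back a matched data set written by [write_matched()]
#'
#' @param dir directory written by [write_matched()].
#' @return a \code{matched_pair}.
#' @export
read_matched <- function(dir) {
  ann <- utils::read.delim(file.path(dir, "annotation.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(entry_id = "character",
                                          gene_id = "character",
                                          chromosome = "character"))
  prov <- utils::read.delim(file.path(dir, "provenance.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  if (nrow(prov)) prov$entry <- as.integer(prov$entry)
  info <- yaml::read_yaml(file.path(dir, "run_info.yaml"))
  norm <- read_matrix(file.path(dir, "cn_normalized.tsv"))
  un <- info$unmatched
  structure(list(annotation = ann,
                 normalized = norm,
                 segmented = read_matrix(file.path(dir, "cn_segmented.tsv")),
                 calls = read_matrix(file.path(dir, "cn_calls.tsv")),
                 expression = read_matrix(file.path(dir, "expression.tsv")),
                 samples = colnames(norm),
                 provenance = prov,
                 params = info$params,
                 unmatched = data.frame(
                   gene_index = rep(NA_integer_, length(un)),
                   gene_id = names(un) %||% character(),
                   reason = unlist(un, use.names = FALSE) %||% character())),
            class = "matched_pair")
}
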