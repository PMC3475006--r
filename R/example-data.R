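#' Worked-example annotations: one gene and 25 nearby aCGH probes
#'
#' A small packaged example on which every coordinate-based procedure can
#' be run by hand: a single Agilent expression probe on chromosome 14
#' (spanning 38570874-38642188, about 71 kb) together with 25 oligo copy
#' number probes from a 244K aCGH design tiling the surrounding region.
#' Ten of the probes fall inside the gene; the others flank it on either
#' side. Useful for seeing how the procedures differ in which probes they
#' select and how they spread their weights.
#'
#' @return a list with elements \code{cn} and \code{ge}, both
#'   canonicalized annotation data.frames.
#' @examples
#' ann <- example_annotations()
#' match_distance(ann$cn, ann$ge)
#' match_overlap_any(ann$cn, ann$ge)
#' @export
example_annotations <- function() {
  dir <- system.file("extdata", package = "cnmatch", mustWork = TRUE)
  list(cn = read_annotation(file.path(dir, "example_cn_annotation.tsv")),
       ge = read_annotation(file.path(dir, "example_ge_annotation.tsv")))
}
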