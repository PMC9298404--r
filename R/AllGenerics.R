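#' @include AllClasses.R
NULL

#' Accessors for aboseq S4 classes
#'
#' Slot access goes through these generics; the slots themselves are
#' internal representation.
#'
#' @param object an aboseq S4 object.
#' @param x an aboseq S4 object.
#' @param name allele name (for \code{markerSet}).
#' @return \code{sampleId}: character scalar. \code{calls}: the calls
#'   data.frame. \code{profileMetadata}: list. \code{exonSpans}: data.frame
#'   with \code{exon}, \code{start}, \code{end} (cDNA, 1-based inclusive).
#'   \code{contigName}: character. \code{alleleNames}: character vector.
#'   \code{markerSet}: character vector of HGVS labels.
#'   \code{markerProvenance}: data.frame. \code{breakpointInterval}:
#'   character of length 2.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))
#' @rdname accessors
#' @export
setGeneric("profileMetadata", function(object) standardGeneric("profileMetadata"))
#' @rdname accessors
#' @export
setGeneric("exonSpans", function(object) standardGeneric("exonSpans"))
#' @rdname accessors
#' @export
setGeneric("contigName", function(object) standardGeneric("contigName"))
#' @rdname accessors
#' @export
setGeneric("alleleNames", function(object) standardGeneric("alleleNames"))
#' @rdname accessors
#' @export
setGeneric("markerSet", function(object, name) standardGeneric("markerSet"))
#' @rdname accessors
#' @export
setGeneric("markerProvenance", function(object) standardGeneric("markerProvenance"))
#' @rdname accessors
#' @export
setGeneric("breakpointInterval", function(object) standardGeneric("breakpointInterval"))

#' @rdname accessors
setMethod("sampleId", "SampleProfile", function(object) object@sampleId)
#' @rdname accessors
setMethod("calls", "SampleProfile", function(object) object@calls)
#' @rdname accessors
setMethod("profileMetadata", "SampleProfile", function(object) object@metadata)

#' @rdname accessors
setMethod("exonSpans", "GeneModel", function(object) {
  e <- object@exonEnds
  data.frame(exon = seq_along(e),
             start = c(1L, head(e, -1L) + 1L),
             end = e)
})
#' @rdname accessors
setMethod("contigName", "GeneModel", function(object) object@contig)

#' @rdname accessors
setMethod("alleleNames", "AlleleTable", function(object) names(object@alleles))

#' @rdname accessors
setMethod("markerSet", "MarkerCatalog", function(object, name) {
  if (missing(name)) return(object@markers)
  if (!name %in% names(object@markers))
    stop("no marker set for allele '", name, "'")
  object@markers[[name]]
})
#' @rdname accessors
setMethod("markerProvenance", "MarkerCatalog", function(object) object@provenance)

#' @rdname accessors
setMethod("breakpointInterval", "RecombinationEvent",
          function(object) object@breakpointInterval)
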